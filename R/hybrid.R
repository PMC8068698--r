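#' Dendrograms for hybrid hierarchical clustering
#'
#' The package represents a binary merge tree over `n` leaves as a
#' `phasemap_dendrogram`: a `merge` matrix in *creation order* (top-down;
#' the root is row 1, and every parent row precedes its children), a
#' `height` per internal node (the weighted within-node sum of squared
#' deviations from the node centroid, capped by the parent height so that
#' heights are monotone along every root-leaf path), leaf labels and leaf
#' weights. Negative entries of `merge` are leaf indices, positive entries
#' internal-node row numbers.
#'
#' @name phasemap_dendrogram
NULL

# flatten a nested node (list(h=, kids=list(a, b)) or negative leaf code)
# into pre-order merge/height vectors
flatten_tree <- function(root, n_leaves) {
  merge <- matrix(0L, n_leaves - 1, 2)
  height <- numeric(n_leaves - 1)
  counter <- 0L
  rec <- function(node) {
    if (!is.list(node)) return(as.integer(node))  # leaf code (negative)
    counter <<- counter + 1L
    row <- counter
    height[row] <<- node$h
    a <- rec(node$kids[[1]])
    b <- rec(node$kids[[2]])
    merge[row, ] <<- c(a, b)
    row
  }
  rec(root)
  list(merge = merge, height = height)
}

new_dendrogram <- function(merge, height, labels, leaf_weights = NULL) {
  n <- nrow(merge) + 1L
  structure(list(merge = merge, height = height,
                 labels = labels,
                 leaf_weights = leaf_weights %||% rep(1, n),
                 n_leaves = n),
            class = "phasemap_dendrogram")
}

#' @export
print.phasemap_dendrogram <- function(x, ...) {
  cat(sprintf("<phasemap_dendrogram> %d leaves, root height %.4g\n",
              x$n_leaves, x$height[1]))
  invisible(x)
}

# leaf sets per internal node; exploits pre-order (children rows follow
# their parent), so a reverse sweep fills all nodes in one pass
node_members <- function(tree) {
  n_nodes <- nrow(tree$merge)
  members <- vector("list", n_nodes)
  for (i in n_nodes:1) {
    kids <- tree$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
  }
  members
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` internal nodes with the greatest heights (ties
#' broken by node creation order, i.e. top-down order, so ancestors go
#' first); the connected components that remain are the clusters. Because
#' heights are monotone and creation order is top-down, this is equivalent
#' to thresholding heights between the (k-1)-th and k-th largest node
#' heights. Clusters are numbered by their lowest contained leaf index.
#'
#' @param tree a `phasemap_dendrogram`.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return a `partition`: integer cluster labels (1..k) named by leaf
#'   label, with attribute `k`.
#' @export
cut_tree <- function(tree, k) {
  n <- tree$n_leaves
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  labels <- integer(n)
  if (k == n) {
    labels <- seq_len(n)
  } else {
    ord <- order(-tree$height, seq_along(tree$height))
    removed <- rep(FALSE, n - 1)
    removed[ord[seq_len(k - 1)]] <- TRUE
    # parent of each internal node (0 for the root)
    parent <- integer(n - 1)
    for (i in seq_len(n - 1)) for (kid in tree$merge[i, ])
      if (kid > 0) parent[kid] <- i
    # monotone heights + top-down creation order make the removed set
    # upward-closed, so a single pre-order sweep assigns cluster roots:
    # croot = 0 for removed nodes, else the subtree root of its cluster
    croot <- integer(n - 1)
    for (i in seq_len(n - 1)) {
      if (removed[i]) { croot[i] <- 0L; next }
      inherited <- if (parent[i] == 0L) 0L else croot[parent[i]]
      croot[i] <- if (inherited == 0L) i else inherited
    }
    next_id <- 0L
    ids <- new.env()
    for (i in seq_len(n - 1)) for (kid in tree$merge[i, ]) {
      if (kid < 0) {
        root <- if (removed[i]) paste0("L", -kid) else paste0("N", croot[i])
        if (is.null(ids[[root]])) {
          next_id <- next_id + 1L
          ids[[root]] <- next_id
        }
        labels[-kid] <- ids[[root]]
      }
    }
  }
  # renumber by lowest leaf index for a stable, reproducible labelling
  first_leaf <- tapply(seq_len(n), labels, min)
  remap <- integer(max(labels))
  remap[as.integer(names(sort(first_leaf)))] <- seq_along(first_leaf)
  out <- remap[labels]
  names(out) <- tree$labels
  structure(out, k = length(unique(out)), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d subjects in %d clusters: %s\n", length(x),
              attr(x, "k"),
              paste(table(unclass(x)), collapse = "/")))
  invisible(x)
}

#' Find all mutual clusters of a distance matrix
#'
#' A mutual cluster is a set `S` of points (with `2 <= |S| < n`) whose
#' largest within-set distance is strictly smaller than the smallest
#' distance from `S` to any point outside it. Mutual clusters are nested,
#' and no agglomerative linkage (single, average or complete) ever breaks
#' one, so every mutual cluster appears as a node of a preliminary
#' average-linkage tree; the function scans those nodes and verifies the
#' definition directly, which guarantees completeness. All qualifying sets
#' are returned, including proper subsets of larger mutual clusters;
#' maximal sets are marked.
#'
#' @param dist a `dist` object or symmetric matrix with zero diagonal.
#' @return list of integer index vectors, each with attribute `maximal`;
#'   the list itself carries attribute `maximal_sets` (the maximal ones
#'   only).
#' @export
mutual_clusters <- function(dist) {
  D <- as.matrix(dist)
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("dist must be symmetric with zero diagonal")
  n <- nrow(D)
  if (n < 3) return(structure(list(), maximal_sets = list()))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # member sets of all hclust nodes
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
  }
  found <- list()
  for (S in members) {
    if (length(S) < 2 || length(S) >= n) next
    within <- max(D[S, S])
    between <- min(D[S, -S, drop = FALSE])
    if (within < between) found[[length(found) + 1L]] <- sort(S)
  }
  if (!length(found)) return(structure(list(), maximal_sets = list()))
  sizes <- vapply(found, length, integer(1))
  maximal <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      j != i && sizes[j] > sizes[i] && all(found[[i]] %in% found[[j]])
    }, logical(1)))
  }, logical(1))
  for (i in seq_along(found)) attr(found[[i]], "maximal") <- maximal[i]
  structure(found, maximal_sets = found[maximal])
}

# weighted 2-means with k-means++-style seeding and fixed tie-breaks;
# consumes the current RNG stream
weighted_2means <- function(x, w, n_restarts = 10) {
  n <- nrow(x)
  best <- NULL
  best_sse <- Inf
  for (r in seq_len(n_restarts)) {
    i1 <- sample.int(n, 1, prob = w)
    d2 <- rowSums(sweep(x, 2, x[i1, ])^2)
    if (all(d2 * w == 0)) { i2 <- if (i1 == 1L) 2L else 1L }
    else i2 <- sample.int(n, 1, prob = w * d2)
    centers <- x[c(i1, i2), , drop = FALSE]
    assign_old <- integer(n)
    for (it in seq_len(100)) {
      d1 <- rowSums(sweep(x, 2, centers[1, ])^2)
      d2b <- rowSums(sweep(x, 2, centers[2, ])^2)
      a <- ifelse(d2b < d1, 2L, 1L)           # ties toward centre 1
      if (all(a == 1L)) a[which.max(d1)] <- 2L
      if (all(a == 2L)) a[which.max(d2b)] <- 1L
      if (identical(a, assign_old)) break
      assign_old <- a
      centers[1, ] <- wcolMeans(x[a == 1L, , drop = FALSE], w[a == 1L])
      centers[2, ] <- wcolMeans(x[a == 2L, , drop = FALSE], w[a == 2L])
    }
    sse <- sum(w * ifelse(a == 1L, d1, d2b))
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- a }
  }
  best
}

# weighted within-node SSE about the weighted centroid
node_sse <- function(x, w) {
  ctr <- wcolMeans(x, w)
  sum(w * rowSums(sweep(x, 2, ctr)^2))
}

# recursive TSVQ construction on a point set; returns a nested node or a
# negative leaf code; heights are capped by the parent height
tsvq_build <- function(x, w, idx, parent_h, n_restarts) {
  if (length(idx) == 1) return(-idx)
  xs <- x[idx, , drop = FALSE]
  ws <- w[idx]
  h <- min(node_sse(xs, ws), parent_h)
  if (length(idx) == 2) {
    split <- c(1L, 2L)
  } else if (all(rowSums(sweep(xs, 2, xs[1, ])^2) == 0)) {
    # zero-variance node: split arbitrarily by index, height 0
    h <- 0
    split <- c(1L, rep(2L, length(idx) - 1))
  } else {
    split <- weighted_2means(xs, ws, n_restarts)
  }
  a <- idx[split == 1L]; b <- idx[split == 2L]
  list(h = h,
       kids = list(tsvq_build(x, w, a, h, n_restarts),
                   tsvq_build(x, w, b, h, n_restarts)))
}

#' Divisive clustering tree by tree-structured vector quantisation
#'
#' Builds a top-down binary tree by recursive weighted 2-means: at each
#' node the points are split in two (k-means++-style initialisation,
#' `n_restarts` restarts, best split by weighted within-cluster sum of
#' squares, assignment ties broken toward the first centre) until leaves
#' are singletons. Node heights are the weighted within-node sum of
#' squared deviations from the node centroid, capped by the parent height
#' so the dendrogram is monotone. Zero-variance nodes (duplicate points)
#' are split by index with height 0. Deterministic given `seed`.
#'
#' @param points subject x dimension numeric matrix.
#' @param weights per-point weights (counts when points are collapsed
#'   centroids).
#' @param seed integer seed.
#' @param n_restarts restarts of the 2-means split per node.
#' @return a `phasemap_dendrogram`.
#' @export
tsvq_tree <- function(points, weights = NULL, seed = 1L, n_restarts = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  weights <- weights %||% rep(1, n)
  set.seed(seed)
  root <- tsvq_build(points, weights, seq_len(n), Inf, n_restarts)
  fl <- flatten_tree(root, n)
  new_dendrogram(fl$merge, fl$height,
                 labels = rownames(points) %||% as.character(seq_len(n)),
                 leaf_weights = weights)
}

# cap all heights of a nested tree at h_cap (monotone grafting)
cap_tree <- function(node, h_cap) {
  if (!is.list(node)) return(node)
  node$h <- min(node$h, h_cap)
  node$kids <- lapply(node$kids, cap_tree, h_cap = node$h)
  node
}

# re-index leaf codes of a nested tree via map[old] = new
remap_leaves <- function(node, map) {
  if (!is.list(node)) return(-map[-node])
  node$kids <- lapply(node$kids, remap_leaves, map = map)
  node
}

#' Hybrid hierarchical clustering tree
#'
#' The hybrid scheme combines the strengths of agglomerative and divisive
#' clustering: (1) find the maximal [mutual_clusters()] of the Euclidean
#' distances; (2) collapse each to its centroid, weighted by its size;
#' (3) build a divisive [tsvq_tree()] on the collapsed set; (4) grow a
#' separate TSVQ tree inside each mutual cluster and graft it at the
#' corresponding leaf, with heights capped at the graft point. Every
#' maximal mutual cluster is therefore a contiguous subtree of the result.
#' With no mutual clusters present the output equals `tsvq_tree(points,
#' seed = seed)`.
#'
#' @param points subject x factor numeric matrix (typically standardized
#'   factor scores).
#' @param seed integer seed; the collapsed tree uses `seed`, the subtree
#'   inside mutual cluster `i` uses `seed + i`.
#' @param n_restarts restarts of each 2-means split.
#' @return a `phasemap_dendrogram` over all subjects.
#' @export
hybrid_tree <- function(points, seed = 1L, n_restarts = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  labels <- rownames(points) %||% as.character(seq_len(n))
  mc <- attr(mutual_clusters(stats::dist(points)), "maximal_sets")
  if (!length(mc)) return(tsvq_tree(points, seed = seed,
                                    n_restarts = n_restarts))
  in_mc <- integer(n)                          # 0 = singleton
  for (i in seq_along(mc)) in_mc[mc[[i]]] <- i
  singletons <- which(in_mc == 0L)
  n_coll <- length(mc) + length(singletons)
  coll_pts <- matrix(0, n_coll, ncol(points))
  coll_w <- numeric(n_coll)
  # collapsed index layout: mutual clusters first, then singletons
  for (i in seq_along(mc)) {
    coll_pts[i, ] <- colMeans(points[mc[[i]], , drop = FALSE])
    coll_w[i] <- length(mc[[i]])
  }
  if (length(singletons)) {
    coll_pts[length(mc) + seq_along(singletons), ] <-
      points[singletons, , drop = FALSE]
    coll_w[length(mc) + seq_along(singletons)] <- 1
  }
  set.seed(seed)
  top <- tsvq_build(coll_pts, coll_w, seq_len(n_coll), Inf, n_restarts)
  # graft: replace each collapsed leaf by the subject leaf or a capped
  # TSVQ subtree over the mutual cluster's own members
  graft <- function(node, parent_h) {
    if (!is.list(node)) {
      ci <- -node
      if (ci > length(mc)) return(-singletons[ci - length(mc)])
      S <- mc[[ci]]
      if (length(S) == 1) return(-S)
      set.seed(stage_seed(seed, ci))
      sub <- tsvq_build(points[S, , drop = FALSE], rep(1, length(S)),
                        seq_along(S), parent_h, n_restarts)
      sub <- remap_leaves(sub, S)
      cap_tree(sub, parent_h)
    } else {
      node$kids <- lapply(node$kids, graft, parent_h = node$h)
      node
    }
  }
  root <- graft(top, Inf)
  fl <- flatten_tree(root, n)
  new_dendrogram(fl$merge, fl$height, labels = labels)
}

#' Convert to a base-R hclust object
#'
#' Reorders the internal nodes by increasing height (merge order) so the
#' tree can be plotted and exported with the standard tools. Heights tied
#' by parent-capping keep their relative (reverse creation) order.
#'
#' @param x a `phasemap_dendrogram`.
#' @param ... unused.
#' @return an `hclust` object.
#' @export
as.hclust.phasemap_dendrogram <- function(x, ...) {
  n <- x$n_leaves
  ord <- order(x$height, -seq_along(x$height))  # ascending; children first
  rank <- integer(n - 1)
  rank[ord] <- seq_len(n - 1)
  merge <- x$merge
  merge[merge > 0] <- rank[merge[merge > 0]]
  merge <- merge[ord, , drop = FALSE]
  hc <- list(merge = merge, height = x$height[ord],
             order = leaf_order(x), labels = x$labels,
             method = "hybrid", call = match.call(),
             dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

leaf_order <- function(tree) {
  # iterative pre-order over leaves
  stack <- c(1L)
  out <- integer(0)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0) out <- c(out, -node)
    else stack <- c(stack, tree$merge[node, 2], tree$merge[node, 1])
  }
  out
}

#' Serialise a dendrogram
#'
#' Writes the merge structure, node heights, leaf labels and weights as
#' JSON, together with a linkage-matrix CSV (`node`, `child1`, `child2`,
#' `height`; negative children are leaves).
#'
#' @param tree a `phasemap_dendrogram`.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @export
write_dendrogram <- function(tree, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(merge = tree$merge, height = tree$height,
                              labels = tree$labels,
                              leaf_weights = tree$leaf_weights),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(data.frame(node = seq_along(tree$height),
                                child1 = tree$merge[, 1],
                                child2 = tree$merge[, 2],
                                height = tree$height),
                     path_csv, row.names = FALSE)
  }
  invisible(tree)
}
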