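#' Calinski-Harabasz index of a partition
#'
#' `CH(k) = [between-cluster SS / (k - 1)] / [within-cluster SS / (n - k)]`
#' on Euclidean coordinates.
#'
#' @param points subject x dimension matrix.
#' @param labels integer cluster labels.
#' @return the index (Inf, flagged via attribute `zero_within`, when the
#'   within-cluster sum of squares is 0).
#' @export
ch_index <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- length(unique(labels))
  if (k < 2 || k > n - 1) stop("need 2 <= k <= n - 1")
  grand <- colMeans(points)
  within <- 0; between <- 0
  for (g in unique(labels)) {
    xg <- points[labels == g, , drop = FALSE]
    ctr <- colMeans(xg)
    within <- within + sum(sweep(xg, 2, ctr)^2)
    between <- between + nrow(xg) * sum((ctr - grand)^2)
  }
  if (within == 0) {
    return(structure(Inf, zero_within = TRUE))
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Calinski-Harabasz profile over cluster numbers
#'
#' Cuts the tree at each `k` in `k_range`, computes [ch_index()], the
#' percent change from `k` to `k + 1`, and flags local extrema of the
#' profile (both maxima and minima, labelled), leaving the choice of an
#' "optimal" k to the analyst.
#'
#' @param points subject x dimension matrix.
#' @param tree a `phasemap_dendrogram` over the same subjects.
#' @param k_range integer vector of cluster numbers within `[2, n - 1]`.
#' @return data frame with columns `k`, `ch`, `pct_change`, `extremum`
#'   (`""`, `"max"` or `"min"`).
#' @export
ch_profile <- function(points, tree, k_range) {
  n <- nrow(as.matrix(points))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n - 1]")
  k_range <- sort(unique(as.integer(k_range)))
  ch <- vapply(k_range, function(k)
    as.numeric(ch_index(points, cut_tree(tree, k))), numeric(1))
  m <- length(ch)
  pct <- c(100 * diff(ch) / ch[-m], NA_real_)
  extremum <- character(m)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (ch[i] > ch[i - 1] && ch[i] > ch[i + 1]) extremum[i] <- "max"
      if (ch[i] < ch[i - 1] && ch[i] < ch[i + 1]) extremum[i] <- "min"
    }
  }
  data.frame(k = k_range, ch = ch, pct_change = pct, extremum = extremum,
             stringsAsFactors = FALSE)
}

#' Silhouette coefficients of a partition
#'
#' Per-subject silhouette `s(i) = (b - a) / max(a, b)` where `a` is the
#' mean distance to the subject's own cluster (excluding itself) and `b`
#' the smallest mean distance to any other cluster; members of singleton
#' clusters get `s = 0`. Computed via [cluster::silhouette()].
#'
#' @param dist a `dist` object or symmetric distance matrix.
#' @param labels integer cluster labels (k >= 2).
#' @return list with `widths` (per subject), `cluster_means`, `mean`.
#' @export
silhouette_scores <- function(dist, labels) {
  labels <- as.integer(unclass(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  sil <- cluster::silhouette(labels, dist = stats::as.dist(as.matrix(dist)))
  widths <- sil[, "sil_width"]
  list(widths = widths,
       cluster_means = tapply(widths, labels, mean),
       mean = mean(widths))
}

#' Per-cluster factor-score profiles with effect sizes
#'
#' For each cluster and factor: the cluster mean, Cohen's d relative to
#' the whole sample (`(cluster mean - sample mean) / sample SD`), and the
#' conventional star label (`*** |d| > 0.8`, `** > 0.5`, `* > 0.2`,
#' strict). Cluster size and share are included.
#'
#' @param scores a `factor_scores` object or numeric subject x factor
#'   matrix.
#' @param partition integer cluster labels over the scored subjects.
#' @return data frame with one row per cluster x factor.
#' @export
cluster_profiles <- function(scores, partition) {
  x <- if (inherits(scores, "factor_scores")) scores$scores else
    as.matrix(scores)
  labels <- as.integer(unclass(partition))
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  out <- list()
  for (g in sort(unique(labels))) {
    xg <- x[labels == g, , drop = FALSE]
    d <- (colMeans(xg) - mu) / sds
    out[[length(out) + 1L]] <- data.frame(
      cluster = g, size = nrow(xg), share = nrow(xg) / nrow(x),
      factor = colnames(x) %||% sprintf("F%d", seq_len(ncol(x))),
      mean = colMeans(xg), cohens_d = d, stars = star_label(d),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fowlkes-Mallows index of two partitions
#'
#' Pair-counting similarity: with contingency table `M` over the two
#' labelings, `T = sum(M^2) - n`, `P = sum(rowSums(M)^2) - n`,
#' `Q = sum(colSums(M)^2) - n`, and `B = T / sqrt(P Q)` (0 when `T = 0`).
#' `B` is the geometric mean of the pairwise precision and recall and is
#' symmetric in its arguments.
#'
#' @param part_a,part_b cluster label vectors over the same subjects (if
#'   named, they are matched on the shared names first).
#' @return `B` in \[0, 1\].
#' @export
fowlkes_mallows <- function(part_a, part_b) {
  m <- match_partitions(part_a, part_b)
  M <- table(m$a, m$b)
  n <- sum(M)
  Tt <- sum(M^2) - n
  P <- sum(rowSums(M)^2) - n
  Q <- sum(colSums(M)^2) - n
  if (Tt == 0 || P == 0 || Q == 0) return(0)
  Tt / sqrt(P * Q)
}

match_partitions <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    if (!length(shared)) stop("partitions share no subjects")
    list(a = unclass(a)[shared], b = unclass(b)[shared])
  } else {
    if (length(a) != length(b))
      stop("unnamed partitions must have equal length")
    list(a = unclass(a), b = unclass(b))
  }
}

#' Permutation test of cross-wave clustering similarity
#'
#' Cuts the two dendrograms at `k_a` and `k_b`, computes the observed
#' Fowlkes-Mallows index on the shared subjects, and builds its null
#' distribution by randomly permuting the subject-to-leaf assignment of
#' the first clustering `n_perm` times (for a fixed cut this equals
#' permuting the partition labels). The two-sided p-value is
#' `2 * min(r_low + 1, r_high + 1) / (n_perm + 1)`, capped at 1, where
#' `r_low`/`r_high` count permutations with an index at most/at least the
#' observed one.
#'
#' @param tree_a,tree_b `phasemap_dendrogram`s (or precomputed label
#'   vectors, in which case `k_a`/`k_b` are ignored).
#' @param k_a,k_b cut levels.
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param seed integer seed.
#' @return an `fm_result` list: `b_index`, `k_a`, `k_b`, `null_mean`,
#'   `null_var`, `p_value`, `n_permutations`, `n_shared`, `seed`.
#' @export
fm_permutation_test <- function(tree_a, k_a = NULL, tree_b = NULL,
                                k_b = NULL, n_perm = 1000, seed = 1L) {
  part_a <- if (inherits(tree_a, "phasemap_dendrogram"))
    cut_tree(tree_a, k_a) else tree_a
  part_b <- if (inherits(tree_b, "phasemap_dendrogram"))
    cut_tree(tree_b, k_b) else tree_b
  m <- match_partitions(part_a, part_b)
  if (length(m$a) < 10) stop("need at least 10 shared subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  a <- unname(m$a); b <- unname(m$b)   # already aligned; drop names so
  obs <- fowlkes_mallows(a, b)         # permuting is not undone by re-matching
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    fowlkes_mallows(sample(a), b), numeric(1))
  r_low <- sum(null <= obs)
  r_high <- sum(null >= obs)
  p <- min(1, 2 * min(r_low + 1, r_high + 1) / (n_perm + 1))
  structure(list(b_index = obs, k_a = k_a %||% NA, k_b = k_b %||% NA,
                 null_mean = mean(null), null_var = stats::var(null),
                 p_value = p, n_permutations = n_perm,
                 n_shared = length(m$a), seed = seed,
                 null_sample = null),
            class = "fm_result")
}

#' @export
print.fm_result <- function(x, ...) {
  cat(sprintf(
    "<fm_result> B = %.4f (null mean %.4f, var %.3g), two-sided p = %.4g (%d permutations, %d shared subjects)\n",
    x$b_index, x$null_mean, x$null_var, x$p_value, x$n_permutations,
    x$n_shared))
  invisible(x)
}
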