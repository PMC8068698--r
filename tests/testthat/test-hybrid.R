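test_that("mutual clusters match the defining examples", {
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  mc <- mutual_clusters(D)
  expect_setequal(set_key(mc), c("1,2", "3,4"))

  # all pairwise distances equal: the strict inequality fails everywhere
  D2 <- matrix(1, 4, 4); diag(D2) <- 0
  expect_length(mutual_clusters(D2), 0)

  expect_error(mutual_clusters(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("mutual clusters equal exhaustive subset enumeration", {
  set.seed(80)
  for (r in 1:50) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(x))
    expect_identical(set_key(mutual_clusters(D)),
                     set_key(brute_mutual_clusters(D)))
  }
})

test_that("mutual clusters are pairwise disjoint or nested", {
  set.seed(81)
  for (r in 1:10) {
    x <- matrix(rnorm(30 * 3), 30)
    mc <- mutual_clusters(as.matrix(dist(x)))
    for (i in seq_along(mc)) for (j in seq_along(mc)) {
      if (i >= j) next
      ov <- length(intersect(mc[[i]], mc[[j]]))
      nested <- ov == min(length(mc[[i]]), length(mc[[j]]))
      expect_true(ov == 0 || nested)
    }
  }
})

test_that("tsvq separates well-separated groups and is deterministic", {
  x <- matrix(c(0, 1, 10, 11), 4)
  tr <- tsvq_tree(x, seed = 1)
  p <- cut_tree(tr, 2)
  expect_equal(as.integer(p), c(1, 1, 2, 2))

  blobs <- make_blobs(100, rbind(c(0, 0), c(5, 0), c(0, 5)), seed = 82)
  tr3 <- tsvq_tree(blobs$x, seed = 2)
  expect_equal(ari_oracle(unclass(cut_tree(tr3, 3)), blobs$labels), 1)

  tr3b <- tsvq_tree(blobs$x, seed = 2)
  expect_identical(tr3$merge, tr3b$merge)
  expect_identical(tr3$height, tr3b$height)
})

test_that("tsvq handles duplicate points", {
  x <- matrix(c(1, 1, 1, 1, 5, 5), ncol = 1)
  tr <- tsvq_tree(x, seed = 3)
  p <- cut_tree(tr, 2)
  expect_equal(length(unique(unclass(p)[1:4])), 1)
  expect_true(all(tr$height >= 0))
})

test_that("hybrid tree keeps maximal mutual clusters contiguous", {
  set.seed(83)
  for (r in 1:50) {
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 3), n)
    tr <- hybrid_tree(x, seed = r)
    mc <- attr(mutual_clusters(as.matrix(dist(x))), "maximal_sets")
    members <- phasemap:::node_members(tr)
    keys <- vapply(members, function(s) paste(sort(s), collapse = ","),
                   "")
    for (S in mc) {
      if (length(S) >= 2)
        expect_true(paste(sort(S), collapse = ",") %in% keys)
    }
  }
})

test_that("hybrid tree reduces to tsvq when no mutual clusters exist", {
  D2 <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 4))
  # equilateral-ish triplet plus far points spaced equally has no mutual
  # clusters only in contrived settings; construct one directly instead
  x <- matrix(c(0, 1, 2, 3, 4, 5), ncol = 1)  # equal chain spacing
  mc <- attr(mutual_clusters(as.matrix(dist(x))), "maximal_sets")
  expect_length(mc, 0)
  t_hybrid <- hybrid_tree(x, seed = 5)
  t_plain <- tsvq_tree(x, seed = 5)
  expect_identical(t_hybrid$merge, t_plain$merge)
  expect_identical(t_hybrid$height, t_plain$height)
})

test_that("hybrid clustering recovers four planted blobs", {
  ctr <- rbind(c(0, 0, 0, 0, 0, 0), c(4, 0, 0, 0, 0, 0),
               c(0, 4, 0, 0, 0, 0), c(0, 0, 4, 0, 0, 0))
  blobs <- make_blobs(100, ctr, sd = 0.5, seed = 84)
  tr <- hybrid_tree(blobs$x, seed = 6)
  p <- cut_tree(tr, 4)
  expect_gte(ari_oracle(unclass(p), blobs$labels), 0.95)
})

test_that("cut_tree spans k = 1 to k = n and nests across k", {
  set.seed(85)
  x <- matrix(rnorm(40 * 2), 40)
  tr <- hybrid_tree(x, seed = 7)
  expect_equal(length(unique(unclass(cut_tree(tr, 1)))), 1)
  expect_equal(length(unique(unclass(cut_tree(tr, 40)))), 40)
  expect_error(cut_tree(tr, 0), "k must")
  expect_error(cut_tree(tr, 41), "k must")
  for (k in 2:10) {
    fine <- unclass(cut_tree(tr, k))
    coarse <- unclass(cut_tree(tr, k - 1))
    # each fine cluster lies inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("cutting equals thresholding heights between order statistics", {
  set.seed(86)
  x <- matrix(rnorm(50 * 2), 50)
  tr <- hybrid_tree(x, seed = 8)
  k <- 5
  hs <- sort(tr$height, decreasing = TRUE)
  if (hs[k - 1] > hs[k]) {                  # no tie at the boundary
    thresh <- (hs[k - 1] + hs[k]) / 2
    removed_by_height <- which(tr$height > thresh)
    ord <- order(-tr$height, seq_along(tr$height))
    expect_setequal(removed_by_height, ord[seq_len(k - 1)])
  }
  expect_equal(attr(cut_tree(tr, k), "k"), k)
})

test_that("Calinski-Harabasz matches the worked example and finds k", {
  pts <- matrix(c(0, 1, 10, 11), 4)
  expect_equal(ch_index(pts, c(1, 1, 2, 2)), 200)
  expect_error(ch_index(pts, rep(1, 4)), "k")
  expect_error(ch_index(pts, 1:4), "k")

  ctr <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  blobs <- make_blobs(60, ctr, sd = 0.4, seed = 87)
  tr <- hybrid_tree(blobs$x, seed = 9)
  prof <- ch_profile(blobs$x, tr, 2:8)
  expect_equal(prof$k[which.max(prof$ch)], 4)
  expect_error(ch_profile(blobs$x, tr, 1:4), "k_range")
})

test_that("silhouette matches hand computation and brute force", {
  pts <- matrix(c(0, 1, 10, 11), 4)
  sil <- silhouette_scores(dist(pts), c(1, 1, 2, 2))
  expect_equal(sil$widths[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  expect_true(all(sil$widths >= -1 & sil$widths <= 1))

  set.seed(88)
  x <- matrix(rnorm(20 * 2), 20)
  labels <- sample(1:3, 20, replace = TRUE)
  D <- as.matrix(dist(x))
  sil2 <- silhouette_scores(D, labels)
  expect_equal(unname(sil2$widths), brute_silhouette(D, labels),
               tolerance = 1e-12)
})

test_that("cluster profiles report effect sizes with star labels", {
  set.seed(89)
  x <- matrix(rnorm(4000 * 3), 4000, 3)
  colnames(x) <- c("F1", "F2", "F3")
  # the cluster covering the whole sample has d = 0 and no stars
  whole <- cluster_profiles(x, rep(1, 4000))
  expect_true(all(abs(whole$cohens_d) < 1e-12))
  expect_true(all(whole$stars == ""))
  expect_equal(whole$share, rep(1, 3))

  expect_identical(star_label(0.6), "**")
  expect_identical(star_label(c(-0.85, 0.3, 0.1)), c("***", "*", ""))

  # prototype shifted +1 SD on one factor for a 200-subject cluster
  x2 <- x
  x2[1:200, 1] <- x2[1:200, 1] + 1
  labels <- rep(c(1, 2), c(200, 3800))
  prof2 <- cluster_profiles(x2, labels)
  d_hat <- prof2$cohens_d[prof2$cluster == 1 & prof2$factor == "F1"]
  expect_lt(abs(d_hat - 1), 0.2)
})
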