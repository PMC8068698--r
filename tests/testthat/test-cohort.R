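test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(n_subjects = 100), "cohort_config")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(
    cluster_weights_w1 = c(0.5, 0.5, 0.1, 0.1, 0.1, 0.1, 0.1)), "sum to 1")
  tm <- default_transition_matrix()
  tm[1, 1] <- tm[1, 1] + 0.1
  expect_error(cohort_config(transition_matrix = tm), "row")
  expect_error(cohort_config(
    cluster_prototypes_w1 = matrix(0, 7, 4)), "n_factors")
  expect_error(cohort_config(n_subjects = 10, n_uni_outliers = 8,
                             n_multi_outliers = 8), "outliers")
})

test_that("planted loadings imply a unit-diagonal correlation matrix", {
  L <- phasemap:::planted_loadings(40, 6, 0.7)
  psi <- 1 - rowSums(L^2)
  expect_equal(unname(diag(tcrossprod(L)) + psi), rep(1, 40))
})

test_that("degenerate noise reproduces the prototypes exactly", {
  cfg <- cohort_config(n_subjects = 50, noise_sd = 0, loading_strength = 1,
                       missing_rate = 0, n_uni_outliers = 0,
                       n_multi_outliers = 0, seed = 5)
  sim <- generate_cohort(cfg)
  expected <- cfg$cluster_prototypes_w1[sim$truth$labels_w1, ]
  expect_equal(unname(sim$truth$latent_scores_w1), unname(expected))
})

test_that("orthogonal planted factors give near-identity latent correlations", {
  cfg <- cohort_config(
    n_subjects = 5000,
    cluster_prototypes_w1 = matrix(0, 7, 6),
    cluster_prototypes_w2 = matrix(0, 6, 6),
    noise_sd = 1, missing_rate = 0,
    n_uni_outliers = 0, n_multi_outliers = 0, seed = 11)
  sim <- generate_cohort(cfg)
  cs <- cor(sim$truth$latent_scores_w1)
  expect_lt(max(abs(cs[upper.tri(cs)])), 0.05)
})

test_that("clean configs return no missing cells and no outliers", {
  sim <- generate_cohort(cohort_config(n_subjects = 80, missing_rate = 0,
                                       n_uni_outliers = 0,
                                       n_multi_outliers = 0, seed = 2))
  expect_false(any(missing_mask(sim$wave1)))
  expect_false(any(missing_mask(sim$wave2)))
  expect_length(sim$truth$outlier_ids, 0)
})

test_that("plant_missingness hits the target rate and is deterministic", {
  rm0 <- rating_matrix(matrix(rnorm(5000 * 40, 50, 10), 5000, 40),
                       analogue_items(40))
  expect_identical(plant_missingness(rm0, 0, seed = 1)$scores, rm0$scores)
  m1 <- plant_missingness(rm0, 0.1, seed = 7)
  expect_lt(abs(mean(is.na(m1$scores)) - 0.1), 0.01)
  m2 <- plant_missingness(rm0, 0.1, seed = 7)
  expect_identical(is.na(m1$scores), is.na(m2$scores))
  expect_error(plant_missingness(rm0, 1, seed = 1), "rate")
})

test_that("plant_outliers places univariate and multivariate outliers", {
  set.seed(31)
  x <- matrix(rnorm(500 * 7), 500, 7)
  pl0 <- plant_outliers(x, 0, 0, seed = 1)
  expect_identical(pl0$matrix, x)

  pl1 <- plant_outliers(x, 1, 0, seed = 2)
  changed <- which(pl1$matrix != x, arr.ind = TRUE)
  expect_equal(nrow(changed), 1)
  z <- scale(pl1$matrix)
  expect_gt(abs(z[changed]), 3)

  pl2 <- plant_outliers(x, 0, 2, seed = 3)
  d2 <- mahalanobis(pl2$matrix, colMeans(pl2$matrix), cov(pl2$matrix))
  idx <- as.integer(pl2$multi_ids)
  expect_true(all(d2[idx] > mahalanobis_cutoff(7, 0.001)))
  # every coordinate stays within 3 SD
  z2 <- scale(pl2$matrix)
  expect_true(all(abs(z2[idx, ]) < 3))

  expect_error(plant_outliers(x[1:5, ], 3, 3, seed = 1), "exceed")
})

test_that("cross-wave labels follow the planted transition matrix", {
  cfg <- cohort_config(n_subjects = 10000, missing_rate = 0,
                       n_uni_outliers = 0, n_multi_outliers = 0, seed = 13)
  sim <- generate_cohort(cfg)
  tm <- cfg$transition_matrix
  emp <- prop.table(table(sim$truth$labels_w1, sim$truth$labels_w2),
                    margin = 1)
  n_row <- as.numeric(table(sim$truth$labels_w1))
  se <- sqrt(tm * (1 - tm) / n_row)
  expect_true(all(abs(emp - tm) < 3 * pmax(se, 1e-3)))
})

test_that("item correlations converge to the model-implied matrix", {
  L <- phasemap:::planted_loadings(40, 6, 0.7)
  target <- tcrossprod(L); diag(target) <- 1
  frob <- sapply(c(500, 5000), function(n) {
    cfg <- cohort_config(
      n_subjects = n, cluster_prototypes_w1 = matrix(0, 7, 6),
      cluster_prototypes_w2 = matrix(0, 6, 6), noise_sd = 1,
      missing_rate = 0, n_uni_outliers = 0, n_multi_outliers = 0,
      seed = 17)
    sim <- generate_cohort(cfg)
    norm(cor(sim$wave1$scores) - target, "F")
  })
  expect_lt(frob[2], frob[1])
  expect_lt(frob[2], 1.0)
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(n_subjects = 60, seed = 3))
  b <- generate_cohort(cohort_config(n_subjects = 60, seed = 3))
  expect_identical(a$wave1$scores, b$wave1$scores)
  expect_identical(a$wave2$scores, b$wave2$scores)
  expect_identical(a$truth$labels_w2, b$truth$labels_w2)
})
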