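test_that("efa on an identity matrix explains nothing", {
  fit <- efa(diag(6), 2)
  expect_lt(max(abs(fit$loadings)), 1e-4)
  expect_lt(fit$total_variance, 1e-6)
})

test_that("efa recovers planted loadings from the exact model matrix", {
  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.7, 0.6, 0.5))
  R <- tcrossprod(L); diag(R) <- 1
  fit <- efa(R, 2)
  # match columns up to permutation/sign
  cong <- abs(outer(1:2, 1:2, Vectorize(function(i, j)
    tucker_congruence(L[, i], fit$loadings[, j]))))
  expect_gt(min(apply(cong, 1, max)), 0.98)
  # communality + uniqueness = 1
  expect_equal(unname(rowSums(fit$loadings^2) + fit$uniquenesses),
               rep(1, 6), tolerance = 1e-4)
})

test_that("minres objective decreases monotonically", {
  set.seed(70)
  dat <- make_ordinal_factor_data(800, simple_loadings(3, 4, 0.7),
                                  seed = 70)
  R <- polychoric_matrix(dat$x)
  fit <- efa(R, 3)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("total communality is invariant under rotation", {
  L <- cbind(c(0.8, 0.7, 0.6, 0.1, 0, 0), c(0.1, 0, 0, 0.7, 0.6, 0.5))
  R <- tcrossprod(L); diag(R) <- 1
  fit <- efa(R, 2)
  unrot <- fit$loadings %*% solve(fit$rotation_matrix)
  expect_equal(sum(unrot^2), sum(fit$loadings^2), tolerance = 1e-8)
  # rotation matrix is orthogonal
  expect_equal(crossprod(fit$rotation_matrix), diag(2),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("varimax recovers simple structure rotated away by 30 degrees", {
  L0 <- rbind(c(0.8, 0), c(0.8, 0), c(0, 0.8), c(0, 0.8))
  th <- 30 * pi / 180
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  L <- L0 %*% Rm
  out <- varimax_rotate(L)
  crit <- phasemap:::varimax_criterion(out$loadings)
  # brute force over rotation angles
  grid <- seq(0, pi / 2, by = 1e-4)
  best <- max(vapply(grid, function(a) {
    G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    phasemap:::varimax_criterion(L %*% G)
  }, numeric(1)))
  expect_gt(crit, best - 1e-4)
  expect_lt(max(abs(abs(out$loadings) - abs(L0))), 1e-3)
})

test_that("varimax leaves a single factor unchanged", {
  L <- matrix(c(0.8, 0.5, 0.3), 3, 1)
  expect_identical(varimax_rotate(L)$loadings, L)
})

test_that("varimax criterion does not decrease", {
  set.seed(71)
  L <- matrix(rnorm(12), 6, 2)
  out <- varimax_rotate(L)
  expect_gte(phasemap:::varimax_criterion(out$loadings),
             phasemap:::varimax_criterion(L) - 1e-10)
})

test_that("parallel analysis stays at zero for pure noise", {
  set.seed(72)
  hits <- vapply(1:20, function(r) {
    x <- matrix(sample(1:4, 300 * 6, replace = TRUE), 300, 6)
    parallel_analysis(x, n_sim = 30, seed = 100 + r)$n_factors
  }, numeric(1))
  expect_true(all(hits <= 1))
  expect_lte(sum(hits >= 1), 2)
})

test_that("parallel analysis recovers a planted 3-factor structure", {
  dat <- make_ordinal_factor_data(1000, simple_loadings(3, 6, 0.7),
                                  seed = 73)
  pa <- parallel_analysis(dat$x, n_sim = 40, seed = 7)
  expect_equal(pa$n_factors, 3)
  # stable under more simulations
  pa2 <- parallel_analysis(dat$x, n_sim = 80, seed = 7)
  expect_equal(pa2$n_factors, 3)
  # invariant to item order permutation
  set.seed(8)
  perm <- sample(ncol(dat$x))
  pa3 <- parallel_analysis(dat$x[, perm], n_sim = 40, seed = 7)
  expect_equal(pa3$n_factors, 3)
})

test_that("bootstrap stability separates stable from unstable k", {
  dat <- make_ordinal_factor_data(600, simple_loadings(3, 4, 0.7),
                                  seed = 74)
  bs <- bootstrap_stability(dat$x, k_candidates = c(3, 5), n_boot = 30,
                            seed = 9)
  expect_true(bs$table$stable[bs$table$k == 3])
  expect_false(bs$table$stable[bs$table$k == 5])
  expect_equal(bs$best_k, 3)
  # deterministic given the seed
  bs2 <- bootstrap_stability(dat$x, k_candidates = c(3, 5), n_boot = 30,
                             seed = 9)
  expect_identical(bs$table, bs2$table)
})

test_that("one dominant factor is stable at k = 1", {
  dat <- make_ordinal_factor_data(600, simple_loadings(1, 8, 0.75),
                                  seed = 75)
  bs <- bootstrap_stability(dat$x, k_candidates = 1, n_boot = 20, seed = 10)
  expect_true(bs$table$stable)
  expect_gt(bs$table$min_lower, 0.97)
})

test_that("factor scores are standardized and recover the latent scores", {
  L <- simple_loadings(3, 6, 0.7)
  dat <- make_ordinal_factor_data(2000, L, seed = 76)
  R <- polychoric_matrix(dat$x)
  fit <- efa(R, 3)
  fs <- factor_scores(dat$x, R, fit)
  expect_lt(max(abs(colMeans(fs$scores))), 1e-8)
  expect_equal(unname(apply(fs$scores, 2, sd)), rep(1, 3),
               tolerance = 1e-6)
  # each latent factor is tracked by some estimated factor
  cors <- abs(cor(fs$scores, dat$scores))
  expect_gt(min(apply(cors, 2, max)), 0.8)
  # orthogonal planted factors give nearly uncorrelated scores
  cc <- cor(fs$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})
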