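test_that("rm_anova agrees with an independent mixed-ANOVA implementation", {
  skip_if_not_installed("car")
  set.seed(110)
  n <- 60; m <- 4
  grp <- factor(rep(1:3, each = 20))
  x <- matrix(rnorm(n * m), n, m) %*%
    chol(0.4 + diag(0.6, m)) + outer(as.numeric(grp), seq_len(m) / 2)
  res <- rm_anova(x, grp)
  mod <- lm(x ~ grp)
  A <- car::Anova(mod, idata = data.frame(domain = factor(1:m)),
                  idesign = ~domain, type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(res$effects$F[res$effects$effect == "group"],
               unname(ut["grp", "F value"]), tolerance = 1e-10)
  expect_equal(res$effects$F[res$effects$effect == "group:domain"],
               unname(ut["grp:domain", "F value"]), tolerance = 1e-10)
  expect_equal(res$mauchly_w,
               unname(s$sphericity.tests["domain", "Test statistic"]),
               tolerance = 1e-10)
  expect_equal(res$mauchly_p,
               unname(s$sphericity.tests["domain", "p-value"]),
               tolerance = 1e-3)
  expect_equal(res$epsilon, unname(s$pval.adjustments["domain", "GG eps"]),
               tolerance = 1e-10)
})

test_that("epsilon is near 1 under compound symmetry, within bounds always", {
  set.seed(111)
  nonsig <- 0
  eps_vals <- numeric(20)
  for (r in 1:20) {
    x <- MASS::mvrnorm(500, rep(0, 4), 0.5 + diag(0.5, 4))
    grp <- rep(1:2, each = 250)
    res <- rm_anova(x, grp)
    eps_vals[r] <- res$epsilon
    if (res$mauchly_p > 0.05) nonsig <- nonsig + 1
  }
  expect_true(all(abs(eps_vals - 1) < 0.02))
  expect_gte(nonsig / 20, 0.9)

  # bounds hold even under strong violation
  set.seed(112)
  S <- diag(c(4, 1, 0.25, 0.1))
  x <- MASS::mvrnorm(100, rep(0, 4), S)
  res <- rm_anova(x, rep(1:2, each = 50))
  expect_gte(res$epsilon, 1 / 3)
  expect_lte(res$epsilon, 1)
})

test_that("GG correction calibrates the interaction test under violation", {
  set.seed(113)
  S <- diag(c(6, 2, 0.5, 0.1))   # strong sphericity violation
  n_rep <- 1000
  rej_gg <- 0
  for (r in seq_len(n_rep)) {
    x <- MASS::mvrnorm(60, rep(0, 4), S)
    res <- rm_anova(x, rep(1:2, each = 30))
    p <- res$effects$p_gg[res$effects$effect == "group:domain"]
    if (p < 0.05) rej_gg <- rej_gg + 1
  }
  expect_gte(rej_gg / n_rep, 0.03)
  expect_lte(rej_gg / n_rep, 0.07)
})

test_that("rm_anova with epsilon 1 reproduces uncorrected dfs", {
  set.seed(114)
  x <- MASS::mvrnorm(200, rep(0, 3), diag(3))
  res <- rm_anova(x, rep(1:2, each = 100))
  expect_equal(res$effects$df1_gg, res$effects$df1 * c(1, res$epsilon,
                                                       res$epsilon))
  # p and p_gg coincide as epsilon -> 1
  expect_equal(res$effects$p, res$effects$p_gg,
               tolerance = 10 * (1 - res$epsilon) + 1e-8)
})

test_that("contrasts against the whole sample behave as designed", {
  set.seed(115)
  x <- matrix(rnorm(2000 * 6), 2000, 6)
  colnames(x) <- paste0("F", 1:6)
  labels <- rep(1, 2000)
  res <- contrast_vs_sample(x, labels)
  expect_true(all(abs(res$t) < 1e-8))
  expect_true(all(abs(res$cohens_d) < 1e-12))
  expect_equal(res$p_adj, pmin(1, res$p_raw * 6))

  # planted +0.8 SD cluster of 150
  x2 <- x
  x2[1:150, 1] <- x2[1:150, 1] + 0.8
  labels2 <- rep(c(1, 2), c(150, 1850))
  res2 <- contrast_vs_sample(x2, labels2)
  d <- res2$cohens_d[res2$cluster == 1 & res2$factor == "F1"]
  expect_lt(abs(d - 0.8), 0.2)
  expect_true(res2$stars[res2$cluster == 1 & res2$factor == "F1"]
              %in% c("**", "***"))
  # singleton clusters flagged
  res3 <- contrast_vs_sample(x, rep(c(1, 2), c(1, 1999)))
  expect_true(res3$singleton[res3$cluster == 1][1])
  expect_true(is.na(res3$t[res3$cluster == 1][1]))
})

test_that("paired t-test satisfies its algebraic identities", {
  expect_error(paired_ttest(1:10, 1:10), "zero-variance")
  set.seed(116)
  x1 <- rnorm(300); x2 <- rnorm(300)
  res <- paired_ttest(x1, x2)
  expect_equal(res$df, 299)
  expect_equal(res$cohens_d, res$t / sqrt(300), tolerance = 1e-10)
  ref <- t.test(x1, x2, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # planted 0.15 SD mean difference at n = 5792
  ts <- vapply(1:10, function(r) {
    set.seed(200 + r)
    d <- rnorm(5792, 0.15, 1)
    paired_ttest(d, rep(0, 5792))$t
  }, numeric(1))
  expect_true(all(abs(ts - 0.15 * sqrt(5792)) < 3))
})

test_that("chi-squared independence matches hand computation", {
  outer_tab <- outer(c(10, 20), c(5, 15)) / 50
  expect_lt(chi2_independence(outer_tab * 50)$statistic, 1e-10)
  res <- chi2_independence(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  res2 <- chi2_independence(matrix(c(1, 2, 0, 3, 4, 0), 2, byrow = TRUE))
  expect_true(res2$dropped)
  expect_equal(res2$df, 1)
})

test_that("chi-squared survival function reproduces reported p-values", {
  expect_equal(round(chi2_sf(56, 49), 3), 0.229)
  expect_equal(round(chi2_sf(30, 25), 3), 0.224)
  expect_equal(chi2_sf(0, 5), 1)
  expect_error(chi2_sf(-1, 5), "value")
})

test_that("ANOVA power analysis reproduces the design triplet", {
  expect_equal(anova_min_n(0.1, 6, 0.05, 0.95), 2093)
  expect_equal(round(anova_detectable_f(12134, 6, 0.05, 0.95), 2), 0.04)
  expect_equal(round(anova_detectable_f(6744, 6, 0.05, 0.95), 2), 0.06)
})

test_that("power computations are monotone and self-consistent", {
  ns <- sapply(c(0.05, 0.1, 0.2, 0.4), anova_min_n, domains = 6)
  expect_true(all(diff(ns) < 0))
  # bracketing: power(N) >= target > power(N - 1)
  N <- anova_min_n(0.1, 6, 0.05, 0.95)
  expect_gte(phasemap:::anova_power(N, 0.1, 6, 0.05), 0.95)
  expect_lt(phasemap:::anova_power(N - 1, 0.1, 6, 0.05), 0.95)
  # round trip
  f <- anova_detectable_f(5000, 6)
  expect_lte(anova_min_n(f, 6), 5000)
  # noncentral-F power increases with the noncentrality parameter
  pows <- vapply(seq(0.02, 0.2, by = 0.02), function(f)
    phasemap:::anova_power(3000, f, 6, 0.05), numeric(1))
  expect_true(all(diff(pows) > 0))
})
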