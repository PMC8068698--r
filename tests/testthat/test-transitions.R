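test_that("transition tables cross-tabulate and row-normalise", {
  lab <- setNames(sample(1:3, 60, replace = TRUE), paste0("S", 1:60))
  tt <- transition_table(lab, lab, k_w1 = 3, k_w2 = 3)
  expect_true(all(tt$counts[upper.tri(tt$counts)] == 0))
  expect_true(all(tt$counts[lower.tri(tt$counts)] == 0))
  expect_equal(unname(rowSums(tt$proportions)), rep(1, 3))
  expect_equal(tt$n, 60)
  expect_error(transition_table(setNames(1, "A"), setNames(1, "B")),
               "share")
})

test_that("empirical transitions track a planted matrix within 3 SE", {
  set.seed(100)
  tm <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6), c(1 / 3, 1 / 3, 1 / 3))
  w1 <- sample(1:3, 5000, replace = TRUE)
  w2 <- vapply(w1, function(g) sample.int(3, 1, prob = tm[g, ]),
               integer(1))
  tt <- transition_table(w1, w2)
  n_row <- rowSums(tt$counts)
  se <- sqrt(tm * (1 - tm) / n_row)
  expect_true(all(abs(tt$proportions - tm) <= 3 * se))
})

test_that("equal-split chi-squared matches hand computation", {
  uniform <- equal_split_chi2(c(25, 25, 25, 25))
  expect_equal(uniform$statistic, 0)
  expect_equal(uniform$p_value, 1)

  res <- equal_split_chi2(c(30, 10, 10, 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 3)
  res_perm <- equal_split_chi2(c(10, 30, 10, 10))
  expect_equal(res$statistic, res_perm$statistic)

  expect_true(equal_split_chi2(c(3, 2, 1))$low_expected)
  expect_error(equal_split_chi2(c(0, 0)), "positive")
})

test_that("cellwise z-tests match hand computation and flag directions", {
  counts <- matrix(0, 7, 6)
  counts[1, ] <- c(100, 60, 60, 60, 60, 60)  # row n = 400, phat1 = 0.25
  counts[2:7, ] <- 50
  tt <- structure(list(counts = counts,
                       proportions = counts / rowSums(counts),
                       n = sum(counts)), class = "transition_table")
  out <- cellwise_ztests(tt)
  expect_equal(out$z[1, 1], (0.25 - 1 / 6) / sqrt((1 / 6) * (5 / 6) / 400),
               tolerance = 1e-12)
  expect_equal(round(out$z[1, 1], 2), 4.47)
  expect_equal(out$family_size, 42)
  expect_identical(out$flags[1, 1], "over")
  # exact equal split gives z = 0 and no flag
  expect_equal(out$z[3, 1], 0)
  expect_identical(out$flags[3, 1], "")
})

test_that("family-wise error under the uniform null stays controlled", {
  set.seed(101)
  n_rep <- 1000
  any_flag <- 0
  for (r in seq_len(n_rep)) {
    counts <- t(rmultinom(7, 500, rep(1 / 6, 6)))
    tt <- structure(list(counts = counts,
                         proportions = counts / rowSums(counts),
                         n = sum(counts)), class = "transition_table")
    out <- cellwise_ztests(tt)
    if (any(out$flags != "", na.rm = TRUE)) any_flag <- any_flag + 1
  }
  expect_lte(any_flag / n_rep, 0.07)
})

test_that("chi-squared equals the sum of squared z statistics at K = 2", {
  counts <- matrix(c(37, 63, 52, 48), 2, 2, byrow = TRUE)
  tt <- structure(list(counts = counts,
                       proportions = counts / rowSums(counts),
                       n = sum(counts)), class = "transition_table")
  out <- cellwise_ztests(tt)
  for (i in 1:2) {
    chi <- equal_split_chi2(counts[i, ])$statistic
    # z is identical (up to sign) across the two cells of a binary row
    expect_equal(chi, out$z[i, 1]^2, tolerance = 1e-10)
  }
})

test_that("a planted enriched transition is flagged reliably", {
  set.seed(102)
  n_rep <- 100
  flagged <- 0
  for (r in seq_len(n_rep)) {
    probs <- c(0.35, rep(0.65 / 5, 5))      # enriched vs p0 = 1/6
    enriched_row <- rmultinom(1, 700, probs)[, 1]
    counts <- rbind(enriched_row,
                    t(rmultinom(6, 700, rep(1 / 6, 6))))
    tt <- structure(list(counts = counts,
                         proportions = counts / rowSums(counts),
                         n = sum(counts)), class = "transition_table")
    out <- cellwise_ztests(tt)
    if (unname(out$flags[1, 1]) == "over") flagged <- flagged + 1
  }
  expect_gte(flagged / n_rep, 0.95)
})

test_that("predictor contrasts use pooled-variance t with correct df", {
  set.seed(103)
  v <- rnorm(500)
  g <- rep(c(TRUE, FALSE), c(200, 300))
  res <- predictor_contrast(v, g)
  expect_equal(res$df, 498)
  ref <- t.test(v[g], v[!g], var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)

  # Bonferroni across covariates in one call
  df <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  res3 <- predictor_contrast(df, g)
  expect_equal(res3$p_adj, pmin(1, res3$p_raw * 3))
  expect_error(predictor_contrast(rep(1, 10), rep(c(TRUE, FALSE), 5)),
               "pooled variance")
})

test_that("predictor contrasts are calibrated and powered as expected", {
  set.seed(104)
  n_rep <- 500
  p_vals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    v <- rnorm(200)
    g <- sample(c(rep(TRUE, 80), rep(FALSE, 120)))
    p_vals[r] <- predictor_contrast(v, g)$p_raw
  }
  expect_gt(mean(p_vals < 0.05), 0.02)
  expect_lt(mean(p_vals < 0.05), 0.08)

  # planted 0.2 SD shift, n = 2000 vs 3000: analytic power ~ 1
  hits <- 0
  for (r in 1:50) {
    v <- c(rnorm(2000, 0.2), rnorm(3000, 0))
    g <- rep(c(TRUE, FALSE), c(2000, 3000))
    if (predictor_contrast(v, g)$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})
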