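#' Mixed-design (split-plot) ANOVA on factor-score profiles
#'
#' Two-way ANOVA with one between-subject factor (cluster/group) and one
#' within-subject factor (the score domain): group effect, domain effect
#' and the group x domain interaction. Sphericity of the within-subject
#' covariance is assessed with Mauchly's W (pooled within-group covariance
#' of the domain scores, chi-squared approximation), and the
#' Greenhouse-Geisser epsilon `(sum lambda)^2 / ((m - 1) sum lambda^2)` is
#' computed from the eigenvalues of the double-centred pooled covariance;
#' corrected degrees of freedom are the raw ones multiplied by epsilon.
#'
#' @param scores subject x domain numeric matrix (complete rows).
#' @param group group label per subject (>= 2 groups).
#' @return an `anova_result` list: per-effect `F`, raw and
#'   Greenhouse-Geisser-corrected df pairs and p-values, `mauchly_w`,
#'   `mauchly_chisq`, `mauchly_df`, `mauchly_p`, `epsilon`.
#' @export
rm_anova <- function(scores, group) {
  x <- as.matrix(scores)
  group <- as.factor(group)
  n <- nrow(x); m <- ncol(x); k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  if (m < 2) stop("need at least 2 within-subject levels")
  if (anyNA(x)) stop("scores must be complete")
  grand <- mean(x)
  subj_mean <- rowMeans(x)
  grp_mean <- tapply(subj_mean, group, mean)          # per-group mean
  dom_mean <- colMeans(x)
  cell_mean <- apply(x, 2, function(col) tapply(col, group, mean))
  if (k == 1) cell_mean <- matrix(cell_mean, 1, m)
  n_g <- as.numeric(table(group))

  ss_group <- m * sum(n_g * (grp_mean - grand)^2)
  ss_subj <- m * sum((subj_mean - grp_mean[group])^2)
  ss_domain <- n * sum((dom_mean - grand)^2)
  inter_dev <- cell_mean - outer(as.numeric(grp_mean), rep(1, m)) -
    outer(rep(1, k), dom_mean) + grand
  ss_inter <- sum(n_g * inter_dev^2)
  resid <- x - subj_mean - cell_mean[group, , drop = FALSE] +
    as.numeric(grp_mean[group])
  ss_err <- sum(resid^2)

  df_group <- k - 1; df_subj <- n - k
  df_domain <- m - 1; df_inter <- (k - 1) * (m - 1)
  df_err <- (n - k) * (m - 1)
  F_group <- (ss_group / df_group) / (ss_subj / df_subj)
  F_domain <- (ss_domain / df_domain) / (ss_err / df_err)
  F_inter <- (ss_inter / df_inter) / (ss_err / df_err)

  # pooled within-group covariance of the domain scores, df = n - k
  Sp <- matrix(0, m, m)
  for (g in levels(group)) {
    xg <- x[group == g, , drop = FALSE]
    if (nrow(xg) > 1) Sp <- Sp + stats::cov(xg) * (nrow(xg) - 1)
  }
  Sp <- Sp / (n - k)
  # orthonormal contrasts of the m domains
  C <- qr.Q(qr(cbind(1, contr.helmert_m(m))))[, -1, drop = FALSE]
  Tm <- t(C) %*% Sp %*% C
  lam <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (all(lam == 0)) lam <- rep(1e-12, m - 1)        # degenerate; flag below
  eps <- sum(lam)^2 / ((m - 1) * sum(lam^2))
  eps <- min(max(eps, 1 / (m - 1)), 1)
  W <- det(Tm) / (mean(diag(Tm)))^(m - 1)
  pdim <- m - 1
  d <- n - k                                          # error df behind Sp
  mult <- d - (2 * pdim^2 + pdim + 2) / (6 * pdim)
  chisq <- -mult * log(max(W, .Machine$double.xmin))
  mdf <- pdim * (pdim + 1) / 2 - 1
  mauchly_p <- if (mdf > 0) stats::pchisq(chisq, mdf, lower.tail = FALSE)
               else NA_real_

  effects <- data.frame(
    effect = c("group", "domain", "group:domain"),
    F = c(F_group, F_domain, F_inter),
    df1 = c(df_group, df_domain, df_inter),
    df2 = c(df_subj, df_err, df_err),
    stringsAsFactors = FALSE)
  effects$p <- stats::pf(effects$F, effects$df1, effects$df2,
                         lower.tail = FALSE)
  # GG correction applies to the within-subject effects only
  effects$df1_gg <- effects$df1 * c(1, eps, eps)
  effects$df2_gg <- effects$df2 * c(1, eps, eps)
  effects$p_gg <- stats::pf(effects$F, effects$df1_gg, effects$df2_gg,
                            lower.tail = FALSE)
  structure(list(effects = effects, epsilon = eps, mauchly_w = W,
                 mauchly_chisq = chisq, mauchly_df = mdf,
                 mauchly_p = mauchly_p, n = n, m = m, k = k),
            class = "anova_result")
}

contr.helmert_m <- function(m) stats::contr.helmert(m)

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> n = %d subjects, %d domains, %d groups\n",
              x$n, x$m, x$k))
  print(transform(x$effects, F = round(F, 2), p = signif(p, 3),
                  p_gg = signif(p_gg, 3)), row.names = FALSE)
  cat(sprintf("Mauchly W = %.4f, chisq(%d) = %.2f, p = %.4g; GG epsilon = %.4f\n",
              x$mauchly_w, x$mauchly_df, x$mauchly_chisq, x$mauchly_p,
              x$epsilon))
  invisible(x)
}

#' Per-cluster contrasts against the whole sample
#'
#' One-sample t-tests of each cluster's scores against the whole-sample
#' mean, per factor, with Cohen's d relative to the whole-sample SD and
#' Bonferroni adjustment over the factors. Singleton clusters get an
#' undefined t and are flagged.
#'
#' @param scores subject x factor matrix (or `factor_scores`).
#' @param partition cluster labels.
#' @param factor_index optional: restrict to one factor column.
#' @return data frame with one row per cluster x factor: `t`, `df`,
#'   `p_raw`, `p_adj`, `cohens_d`, `stars`, `singleton`.
#' @export
contrast_vs_sample <- function(scores, partition, factor_index = NULL) {
  x <- if (inherits(scores, "factor_scores")) scores$scores else
    as.matrix(scores)
  cols <- factor_index %||% seq_len(ncol(x))
  labels <- as.integer(unclass(partition))
  mu <- colMeans(x); sds <- apply(x, 2, stats::sd)
  n_tests <- length(cols)
  out <- list()
  for (g in sort(unique(labels))) {
    for (j in cols) {
      v <- x[labels == g, j]
      singleton <- length(v) < 2
      if (singleton || stats::sd(v) == 0) {
        t <- NA_real_; p <- NA_real_
      } else {
        tt <- stats::t.test(v, mu = mu[j])
        t <- unname(tt$statistic); p <- tt$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        cluster = g, factor = colnames(x)[j] %||% paste0("F", j),
        n = length(v), t = t, df = length(v) - 1, p_raw = p,
        p_adj = min(1, p * n_tests),
        cohens_d = (mean(v) - mu[j]) / sds[j], singleton = singleton,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$stars <- star_label(out$cohens_d)
  out
}

#' Paired t-test with Cohen's d
#'
#' t-test on within-subject differences across waves; `df = n - 1` and
#' `d = mean(diff) / sd(diff)`, which satisfies `d = t / sqrt(n)`.
#'
#' @param x_w1,x_w2 matched numeric vectors (>= 3 pairs).
#' @return list with `t`, `df`, `p_value`, `cohens_d`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(x_w1, x_w2) {
  ok <- !is.na(x_w1) & !is.na(x_w2)
  d <- x_w1[ok] - x_w2[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 matched pairs")
  if (stats::sd(d) == 0) stop("zero-variance differences")
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * stats::pt(-abs(t), n - 1),
       cohens_d = mean(d) / stats::sd(d), mean_diff = mean(d), n = n)
}

#' Pearson chi-squared test of independence
#'
#' Standard contingency-table test with `df = (r - 1)(c - 1)` and no
#' continuity correction; empty rows and columns are dropped (flagged).
#'
#' @param table r x c matrix of counts.
#' @return list with `statistic`, `df`, `p_value`, `dropped` flag.
#' @export
chi2_independence <- function(table) {
  tab <- as.matrix(table)
  if (sum(tab) <= 0) stop("grand total must be positive")
  dropped <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(test$statistic),
       df = unname(test$parameter), p_value = unname(test$p.value),
       dropped = dropped)
}

#' Chi-squared survival function
#'
#' Upper-tail probability of the chi-squared distribution, e.g.
#' `chi2_sf(56, 49) = 0.229`.
#'
#' @param value non-negative statistic.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_sf <- function(value, df) {
  if (any(value < 0) || any(df < 1)) stop("value >= 0 and df >= 1 required")
  stats::pchisq(value, df, lower.tail = FALSE)
}

# Power of the fixed-effects ANOVA convention used throughout: the tested
# effect spans m = `domains` numerator df (m + 1 cells), denominator
# df = N - m - 1, noncentrality lambda = f^2 * N.
anova_power <- function(n, f, domains, alpha) {
  df1 <- domains
  df2 <- n - domains - 1
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = f^2 * n, lower.tail = FALSE)
}

#' Minimum sample size for an ANOVA effect
#'
#' Smallest total `N` whose noncentral-F power reaches `power` for an
#' effect of size Cohen's `f` spanning `domains` numerator degrees of
#' freedom, with denominator df `N - domains - 1` and noncentrality
#' `f^2 N`. With `f = 0.1`, 6 domains, `alpha = 0.05` and power 0.95 this
#' gives N = 2093. Solved by bisection; power is monotone in `N`.
#'
#' @param f Cohen's f (> 0).
#' @param domains numerator degrees of freedom of the tested effect.
#' @param alpha significance level.
#' @param power target power.
#' @return integer minimum total sample size.
#' @export
anova_min_n <- function(f, domains = 6, alpha = 0.05, power = 0.95) {
  if (f <= 0) stop("f must be positive")
  if (domains < 2) stop("domains must be >= 2")
  power <- power - 1e-9    # absorb root-finding error in round trips
  lo <- domains + 2
  hi <- lo
  while (anova_power(hi, f, domains, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e9) stop("target power unreachable")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (anova_power(mid, f, domains, alpha) >= power) hi <- mid else lo <- mid
  }
  if (anova_power(lo, f, domains, alpha) >= power) lo else hi
}

#' Minimal detectable ANOVA effect size at a given sample size
#'
#' Solves for the Cohen's f that attains exactly the target power at fixed
#' total `n` under the same convention as [anova_min_n()]; e.g. `n =
#' 12134` resolves f = 0.04 and `n = 6744` resolves f = 0.06 (2 dp).
#'
#' @param n total sample size (> domains + 1).
#' @param domains numerator degrees of freedom of the tested effect.
#' @param alpha significance level.
#' @param power target power.
#' @return Cohen's f (unrounded).
#' @export
anova_detectable_f <- function(n, domains = 6, alpha = 0.05,
                               power = 0.95) {
  if (n <= domains + 1) stop("n must exceed domains + 1")
  stats::uniroot(function(f) anova_power(n, f, domains, alpha) - power,
                 c(1e-6, 10), tol = 1e-10)$root
}
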