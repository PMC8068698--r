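#' Exploratory factor analysis by minimum residuals with varimax rotation
#'
#' Fits an orthogonal common-factor model to a correlation matrix by
#' minimum-residual (minres/ULS) extraction: the loadings and uniquenesses
#' are chosen to minimise the squared off-diagonal residuals of
#' `corr - loadings %*% t(loadings)`. The fit alternates two exact steps --
#' loadings as the top-`n_factors` eigenstructure of `corr - diag(psi)`,
#' uniquenesses as the residual diagonal -- each of which cannot increase
#' the objective, so the recorded off-diagonal mean squared residual is
#' non-increasing across iterations. Loadings are then varimax-rotated
#' (Kaiser-normalised), factors are ordered by explained variance and
#' sign-aligned so each column's largest loading is positive.
#'
#' Heywood cases (uniqueness below 0) are clamped at 0.001 and flagged.
#'
#' @param corr symmetric positive semi-definite correlation matrix.
#' @param n_factors number of factors, `< ncol(corr)`.
#' @param n_obs number of observations behind `corr` (recorded, not used in
#'   the fit).
#' @param tol convergence tolerance on the uniquenesses.
#' @param max_iter iteration cap.
#' @return a `factor_model` list: `loadings` (rotated), `uniquenesses`,
#'   `rotation_matrix`, `proportion_variance` (per factor),
#'   `total_variance`, `objective_trace` (off-diagonal MSE per iteration),
#'   `heywood`, `extraction = "minres"`, `rotation = "varimax"`, `n_obs`.
#' @export
efa <- function(corr, n_factors, n_obs = NULL, tol = 1e-8, max_iter = 500) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n_factors >= p) stop("n_factors must be smaller than the item count")
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  offdiag <- function(M) { diag(M) <- 0; M }
  # start from squared multiple correlations
  smc <- tryCatch(1 - 1 / diag(solve(corr)), error = function(e) rep(0.5, p))
  psi <- pmin(pmax(1 - smc, 0.001), 1)
  trace <- numeric(0)
  heywood <- FALSE
  for (iter in seq_len(max_iter)) {
    ev <- eigen(corr - diag(psi, p), symmetric = TRUE)
    k <- seq_len(n_factors)
    L <- ev$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[k], 0)), n_factors)
    resid <- offdiag(corr - tcrossprod(L))
    trace <- c(trace, mean(resid[upper.tri(resid)]^2))
    psi_new <- diag(corr) - rowSums(L^2)
    if (any(psi_new < 0)) heywood <- TRUE
    psi_new <- pmin(pmax(psi_new, 0.001), 1)
    if (max(abs(psi_new - psi)) < tol) { psi <- psi_new; break }
    psi <- psi_new
  }
  rownames(L) <- colnames(corr)
  rot <- varimax_rotate(L)
  L <- rot$loadings
  # order factors by explained variance, sign-align
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rotmat <- rot$rotation_matrix[, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]; rotmat[, j] <- -rotmat[, j]
    }
  }
  colnames(L) <- sprintf("F%d", seq_len(n_factors))
  structure(list(
    loadings = L, uniquenesses = stats::setNames(psi, colnames(corr)),
    rotation_matrix = rotmat,
    proportion_variance = colSums(L^2) / p,
    total_variance = sum(L^2) / p,
    objective_trace = trace, heywood = heywood,
    extraction = "minres", rotation = "varimax",
    n_obs = n_obs, n_iter = length(trace)), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d items, %d factors (%s + %s)\n",
              nrow(x$loadings), ncol(x$loadings), x$extraction, x$rotation))
  cat(sprintf("  variance explained: %.1f%% (per factor: %s)\n",
              100 * x$total_variance,
              paste(sprintf("%.1f%%", 100 * x$proportion_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Varimax rotation
#'
#' Orthogonal rotation maximising the Kaiser-normalised varimax criterion
#' (the variance of the squared loadings within each factor) by successive
#' pairwise planar rotations, each solved in closed form (Kaiser's
#' formula); sweeps repeat until no pair moves. A single factor, or an
#' all-zero loading matrix, is returned unchanged. The returned rotation
#' matrix is orthogonal to within 1e-10.
#'
#' @param loadings items x factors matrix.
#' @param tol convergence tolerance passed to the rotation.
#' @return list with `loadings` (rotated) and `rotation_matrix`.
#' @export
varimax_rotate <- function(loadings, tol = 1e-8) {
  L <- as.matrix(loadings)
  k <- ncol(L); p <- nrow(L)
  if (k < 2 || max(abs(L)) < 1e-10) {
    return(list(loadings = L, rotation_matrix = diag(1, k)))
  }
  # Kaiser normalisation: rotate unit-communality rows
  h <- sqrt(rowSums(L^2))
  nz <- h > 1e-12
  Z <- L
  Z[nz, ] <- L[nz, , drop = FALSE] / h[nz]
  R <- diag(1, k)
  for (sweep in seq_len(200)) {
    max_phi <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        x <- Z[, i]; y <- Z[, j]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- -0.25 * atan2(num, den)  # sign matches the G convention below
        if (abs(phi) > 1e-12) {
          G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2)
          Z[, c(i, j)] <- Z[, c(i, j)] %*% G
          R[, c(i, j)] <- R[, c(i, j)] %*% G
        }
        max_phi <- max(max_phi, abs(phi))
      }
    }
    if (max_phi < sqrt(tol)) break
  }
  list(loadings = L %*% R, rotation_matrix = R)
}

# varimax criterion (Kaiser-normalised), used in tests and diagnostics
varimax_criterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed polychoric correlation matrix
#' against the chosen quantile of eigenvalues obtained from `n_sim`
#' simulated datasets of the same shape. Because the observed data are
#' ordinal, the null datasets are independent Normal deviates discretised
#' to each item's observed marginal category proportions before the
#' polychoric matrix is computed. The suggested factor count is the length
#' of the leading run of observed eigenvalues exceeding their rank-matched
#' simulated quantile (retention stops at the first eigenvalue that fails,
#' as in Horn's rule; counting non-leading exceedances would suggest
#' spurious factors on pure noise).
#'
#' @param matrix ordinal [rating_matrix()] or integer-coded matrix,
#'   complete (no `NA`).
#' @param n_sim number of simulated null datasets.
#' @param quantile quantile of the null eigenvalue distribution.
#' @param seed integer seed.
#' @return list with `n_factors`, `observed` (eigenvalues),
#'   `null_quantiles`.
#' @export
parallel_analysis <- function(matrix, n_sim = 100, quantile = 0.95,
                              seed = 1L) {
  x <- if (inherits(matrix, "rating_matrix")) matrix$scores else
    as.matrix(matrix)
  n <- nrow(x); p <- ncol(x)
  obs_eig <- eigen(polychoric_matrix(x), symmetric = TRUE,
                   only.values = TRUE)$values
  # observed marginal category proportions per item
  margins <- lapply(seq_len(p), function(j) {
    tab <- table(x[, j])
    list(levels = as.numeric(names(tab)),
         cuts = stats::qnorm(cumsum(as.numeric(tab) / n)))
  })
  set.seed(seed)
  sim_eig <- matrix(0, n_sim, p)
  for (s in seq_len(n_sim)) {
    z <- matrix(stats::rnorm(n * p), n, p)
    xs <- vapply(seq_len(p), function(j) {
      m <- margins[[j]]
      m$levels[findInterval(z[, j], m$cuts[-length(m$cuts)]) + 1L]
    }, numeric(n))
    sim_eig[s, ] <- eigen(polychoric_matrix(xs), symmetric = TRUE,
                          only.values = TRUE)$values
  }
  qs <- apply(sim_eig, 2, stats::quantile, probs = quantile)
  # leading run: retain factors while the observed eigenvalue beats its
  # rank-matched null quantile, stopping at the first failure (Horn)
  exceeds <- obs_eig > qs
  n_fac <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  list(n_factors = n_fac, observed = obs_eig, null_quantiles = qs)
}

# align the columns of boot loadings B to reference R by greedy best match
# on absolute Tucker congruence, with sign alignment; returns per-reference-
# factor congruence
align_congruence <- function(R, B) {
  k <- ncol(R)
  cong <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cong[i, j] <- tucker_congruence(R[, i], B[, j])
  out <- numeric(k)
  used <- rep(FALSE, k)
  a <- abs(cong)
  for (step in seq_len(k)) {
    a_masked <- a
    a_masked[, used] <- -Inf
    idx <- which(a_masked == max(a_masked), arr.ind = TRUE)[1, ]
    out[idx[1]] <- a[idx[1], idx[2]]
    used[idx[2]] <- TRUE
    a[idx[1], ] <- -Inf
  }
  out
}

#' Bootstrap stability of a factor solution
#'
#' For each candidate factor count `k`, refits the polychoric EFA on
#' `n_boot` row-resamples and aligns each bootstrap solution to the
#' full-sample solution by greedy best match on absolute Tucker congruence
#' (with sign alignment). A solution is called stable when the lower bound
#' of every factor's 95% percentile congruence interval is at least
#' `threshold` (default 0.90). The verdict column reports this per `k`;
#' `best_k` is the largest stable candidate.
#'
#' @param matrix complete ordinal rating matrix.
#' @param k_candidates integer vector of candidate factor counts.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param threshold stability bound on the lower congruence limit.
#' @return list with `table` (per-k data frame: k, min_lower, stable,
#'   dropped), `per_factor` (list of per-factor congruence intervals),
#'   `best_k`.
#' @export
bootstrap_stability <- function(matrix, k_candidates, n_boot = 100,
                                seed = 1L, threshold = 0.90) {
  x <- if (inherits(matrix, "rating_matrix")) matrix$scores else
    as.matrix(matrix)
  n <- nrow(x); p <- ncol(x)
  if (any(k_candidates >= p)) stop("all k_candidates must be < n_items")
  R_full <- polychoric_matrix(x)
  set.seed(seed)
  rows <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  # one polychoric matrix per resample, shared across candidate k
  R_boot <- lapply(seq_len(n_boot), function(b)
    tryCatch(polychoric_matrix(x[rows[, b], , drop = FALSE]),
             error = function(e) NULL))
  res <- list(); per_factor <- list()
  for (k in k_candidates) {
    ref <- efa(R_full, k, n_obs = n)$loadings
    cong <- matrix(NA_real_, n_boot, k)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      fit <- if (is.null(R_boot[[b]])) NULL else
        tryCatch(efa(R_boot[[b]], k, n_obs = n)$loadings,
                 error = function(e) NULL)
      if (is.null(fit)) { dropped <- dropped + 1L; next }
      cong[b, ] <- align_congruence(ref, fit)
    }
    ci <- apply(cong, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    stable <- all(ci[1, ] >= threshold)
    res[[as.character(k)]] <- data.frame(
      k = k, min_lower = min(ci[1, ]), stable = stable, dropped = dropped,
      high_drop = dropped > 0.1 * n_boot)
    per_factor[[as.character(k)]] <- ci
  }
  tab <- do.call(rbind, res)
  stable_k <- tab$k[tab$stable]
  list(table = tab, per_factor = per_factor,
       best_k = if (length(stable_k)) max(stable_k) else NA_integer_)
}

#' Regression (Thurstone) factor scores
#'
#' Computes standardized factor scores: item scores are standardized, then
#' multiplied by `solve(corr) %*% loadings`, and each factor column is
#' re-standardized to mean 0, SD 1 -- the scale on which cluster prototypes
#' and outlier screens operate. A singular correlation matrix is
#' ridge-stabilised (`1e-8 * trace/p` on the diagonal) and flagged.
#'
#' @param matrix rating matrix (items treated as numeric).
#' @param corr the correlation matrix the model was fitted on.
#' @param model a `factor_model` from [efa()].
#' @return a `factor_scores` list: `scores` (subject x factor, standardized),
#'   `method = "regression"`, `ridged`.
#' @export
factor_scores <- function(matrix, corr, model) {
  x <- if (inherits(matrix, "rating_matrix")) matrix$scores else
    as.matrix(matrix)
  Z <- scale(x)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  ridged <- FALSE
  W <- tryCatch(solve(corr, model$loadings), error = function(e) NULL)
  if (is.null(W)) {
    ridged <- TRUE
    p <- ncol(corr)
    W <- solve(corr + diag(1e-8 * sum(diag(corr)) / p, p), model$loadings)
  }
  S <- Z %*% W
  S <- scale(S)
  scores <- matrix(as.numeric(S), nrow(S), ncol(S))
  dimnames(scores) <- list(rownames(x), colnames(model$loadings))
  structure(list(scores = scores, method = "regression", ridged = ridged),
            class = "factor_scores")
}

#' Write a factor loading table
#'
#' Item x factor loadings with uniquenesses as CSV, the tabular analogue
#' of a loading heat-map.
#'
#' @param model a `factor_model`.
#' @param path output path.
#' @export
write_loading_table <- function(model, path) {
  df <- data.frame(item = rownames(model$loadings),
                   round(model$loadings, 6),
                   uniqueness = round(unname(model$uniquenesses), 6),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
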