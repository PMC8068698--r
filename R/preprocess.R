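#' Discretise visual-analogue scores by kernel density estimation
#'
#' Converts continuous analogue ratings (millimetres) to an ordinal scale
#' with `n_levels` categories so that both waves of a cohort can be
#' analysed on a common discrete scale. A Gaussian kernel density is fitted
#' to the observed values on a 512-point grid spanning the scale range, and
#' the `n_levels - 1` cut points are placed at the deepest interior local
#' minima of the density (ranked by the density value at the minimum). If
#' the density has fewer interior minima than needed -- in particular for a
#' unimodal density -- the remaining cut points fall back to
#' equal-probability quantiles of the observed values, so the mapping then
#' reproduces quantile binning. Level assignment is monotone in the raw
#' score.
#'
#' @param values numeric vector of analogue scores; `NA`s are carried
#'   through.
#' @param n_levels target number of ordinal categories (>= 2).
#' @param bandwidth_rule `"silverman"` (default, `stats::bw.nrd0`) or
#'   `"scott"` (`stats::bw.nrd`).
#' @param range scale range over which the density grid is laid; defaults
#'   to the observed range.
#' @return list with `levels` (integer vector, 1..n_levels), `cutpoints`,
#'   `degenerate` flag (all observed values equal), and `density` (the
#'   fitted `stats::density` object, `NULL` when degenerate).
#' @export
kde_discretise <- function(values, n_levels,
                           bandwidth_rule = c("silverman", "scott"),
                           range = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (n_levels < 2) stop("n_levels must be >= 2")
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("no observed values")
  if (length(unique(obs)) == 1) {
    lev <- ifelse(is.na(values), NA_integer_, 1L)
    return(list(levels = lev, cutpoints = numeric(0),
                degenerate = TRUE, density = NULL))
  }
  if (is.null(range)) range <- base::range(obs)
  bw <- switch(bandwidth_rule,
               silverman = stats::bw.nrd0(obs),
               scott = stats::bw.nrd(obs))
  den <- stats::density(obs, bw = bw, n = 512,
                        from = range[1], to = range[2])
  y <- den$y
  i <- 2:(length(y) - 1)
  is_min <- y[i] < y[i - 1] & y[i] < y[i + 1]
  minima_x <- den$x[i][is_min]
  minima_y <- y[i][is_min]
  ord <- order(minima_y)                      # deepest (lowest density) first
  take <- min(length(minima_x), n_levels - 1)
  cut <- minima_x[ord][seq_len(take)]
  need <- n_levels - 1 - length(cut)
  if (need > 0) {
    qs <- unname(stats::quantile(obs, seq_len(n_levels - 1) / n_levels))
    if (length(cut) == 0) cut <- qs[seq_len(need)] else {
      # greedily add the quantile cut points farthest from existing ones
      for (r in seq_len(need)) {
        dists <- vapply(qs, function(q) min(abs(q - cut)), numeric(1))
        cut <- c(cut, qs[which.max(dists)])
      }
    }
  }
  cut <- sort(unique(cut))
  lev <- findInterval(values, cut) + 1L
  lev[is.na(values)] <- NA_integer_
  list(levels = lev, cutpoints = cut, degenerate = FALSE, density = den)
}

#' Screen subjects for excessive missing items
#'
#' Excludes subjects with strictly more than `max_missing` missing items
#' (the default 5 corresponds to roughly 15% of a 40-item questionnaire).
#' Optionally also excludes subjects flagged as missing required metadata
#' (for example exact age or gender), mirroring a CONSORT-style exclusion
#' cascade.
#'
#' @param matrix a [rating_matrix()].
#' @param max_missing maximum tolerated number of missing items.
#' @param missing_metadata optional logical vector (or character ids):
#'   subjects to exclude for missing required metadata.
#' @return list with `matrix` (screened) and `report` (a
#'   [screening_report()]).
#' @export
screen_missing <- function(matrix, max_missing = 5, missing_metadata = NULL) {
  n_miss <- rowSums(is.na(matrix$scores))
  excl_meta <- rep(FALSE, nrow(matrix$scores))
  if (!is.null(missing_metadata)) {
    excl_meta <- if (is.character(missing_metadata))
      matrix$subject_ids %in% missing_metadata else as.logical(missing_metadata)
  }
  excl <- n_miss > max_missing | excl_meta
  report <- screening_report(
    kept_ids = matrix$subject_ids[!excl],
    excluded_missing_ids = matrix$subject_ids[excl],
    thresholds = list(max_missing = max_missing))
  list(matrix = subset_subjects(matrix, which(!excl)), report = report)
}

#' Screening report
#'
#' Records the outcome of an exclusion pass. The four id sets always
#' partition the input ids.
#'
#' @param kept_ids,excluded_missing_ids,excluded_univariate_ids,excluded_multivariate_ids
#'   character id vectors.
#' @param thresholds named list of the thresholds applied.
#' @return a `screening_report` list.
#' @export
screening_report <- function(kept_ids,
                             excluded_missing_ids = character(0),
                             excluded_univariate_ids = character(0),
                             excluded_multivariate_ids = character(0),
                             thresholds = list()) {
  structure(list(kept_ids = kept_ids,
                 excluded_missing_ids = excluded_missing_ids,
                 excluded_univariate_ids = excluded_univariate_ids,
                 excluded_multivariate_ids = excluded_multivariate_ids,
                 thresholds = thresholds),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat("  kept:                 ", length(x$kept_ids), "\n")
  cat("  excluded (missing):   ", length(x$excluded_missing_ids), "\n")
  cat("  excluded (univariate):", length(x$excluded_univariate_ids), "\n")
  cat("  excluded (multivar.): ", length(x$excluded_multivariate_ids), "\n")
  invisible(x)
}

#' Impute missing cells by multivariate-normal expectation maximisation
#'
#' Fits a multivariate Normal to the item scores by EM: the E-step fills
#' the conditional expectations (and second moments) of the missing cells
#' given the observed cells under the current mean and covariance, the
#' M-step re-estimates both. This preserves means, variances and
#' covariances rather than shrinking them the way mean substitution does.
#' Missing cells are returned as their final conditional means; cells of
#' ordinal items are then rounded to the nearest valid level and clamped,
#' because downstream polychoric estimation requires categories.
#'
#' Rows are grouped by missingness pattern, so the per-iteration cost is
#' linear in the number of distinct patterns. A singular observed-block
#' covariance is ridge-stabilised with the constant `1e-8 * trace/p` and
#' flagged.
#'
#' @param matrix a [rating_matrix()] or plain numeric matrix with `NA`s;
#'   should already have passed [screen_missing()].
#' @param tol convergence tolerance on the maximum absolute change of any
#'   mean or covariance entry.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return list with `matrix` (completed, same class as the input), `mu`,
#'   `sigma`, `n_iter`, `converged`, `ridged`.
#' @export
em_impute <- function(matrix, tol = 1e-6, max_iter = 200) {
  is_rm <- inherits(matrix, "rating_matrix")
  x <- if (is_rm) matrix$scores else as.matrix(matrix)
  n <- nrow(x); p <- ncol(x)
  if (any(colSums(!is.na(x)) < 2))
    stop("every item needs at least 2 observed values")
  miss <- is.na(x)
  if (!any(miss)) {
    mu <- colMeans(x)
    sigma <- stats::cov(x) * (n - 1) / n
    return(list(matrix = matrix, mu = mu, sigma = sigma,
                n_iter = 0L, converged = TRUE, ridged = FALSE))
  }
  # starting values: available-case moments
  mu <- colMeans(x, na.rm = TRUE)
  x0 <- x
  x0[miss] <- rep(mu, each = n)[miss]
  sigma <- stats::cov(x0) * (n - 1) / n
  patterns <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), patterns)
  ridged <- FALSE
  converged <- FALSE
  iter <- 0L
  xfill <- x
  repeat {
    iter <- iter + 1L
    cross <- matrix(0, p, p)                  # sum of E[x_i x_i^T]
    for (g in groups) {
      mi <- which(miss[g[1], ])
      oi <- which(!miss[g[1], ])
      xg <- x[g, , drop = FALSE]
      if (length(mi)) {
        Soo <- sigma[oi, oi, drop = FALSE]
        sol <- tryCatch(solve(Soo, rbind(t(sigma[mi, oi, drop = FALSE]))),
                        error = function(e) NULL)
        if (is.null(sol)) {
          ridged <- TRUE
          Soo <- Soo + diag(1e-8 * sum(diag(sigma)) / p, length(oi))
          sol <- solve(Soo, t(sigma[mi, oi, drop = FALSE]))
        }
        beta <- t(sol)                        # mi x oi regression weights
        resid <- sweep(xg[, oi, drop = FALSE], 2, mu[oi])
        cond_mean <- matrix(mu[mi], length(g), length(mi), byrow = TRUE) +
          resid %*% t(beta)
        xg[, mi] <- cond_mean
        cond_cov <- sigma[mi, mi, drop = FALSE] -
          beta %*% sigma[oi, mi, drop = FALSE]
        cross_g <- crossprod(xg)
        cross_g[mi, mi] <- cross_g[mi, mi] + length(g) * cond_cov
        cross <- cross + cross_g
        xfill[g, ] <- xg
      } else {
        cross <- cross + crossprod(xg)
        xfill[g, ] <- xg
      }
    }
    mu_new <- colMeans(xfill)
    sigma_new <- cross / n - tcrossprod(mu_new)
    delta <- max(max(abs(mu_new - mu)), max(abs(sigma_new - sigma)))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  names(mu) <- colnames(x)
  dimnames(sigma) <- list(colnames(x), colnames(x))
  out <- xfill
  if (is_rm) {
    for (j in seq_len(p)) {
      m <- matrix$item_meta[j, ]
      if (m$type == "ordinal")
        out[, j] <- pmin(pmax(round(out[, j]), 1), m$levels)
      else
        out[, j] <- pmin(pmax(out[, j], m$lower), m$upper)
    }
    out <- rating_matrix(out, matrix$item_meta, matrix$subject_ids)
  }
  list(matrix = out, mu = mu, sigma = sigma, n_iter = iter,
       converged = converged, ridged = ridged)
}

#' Chi-squared cut-off for squared Mahalanobis distances
#'
#' The screening threshold for multivariate outliers: the upper-`alpha`
#' quantile of the chi-squared distribution with `n_dims` degrees of
#' freedom. At the conventional `alpha = 0.001` and 7 dimensions this is
#' 24.32.
#'
#' @param n_dims number of score dimensions.
#' @param alpha upper-tail probability.
#' @return the cut-off applied to squared Mahalanobis distances.
#' @export
mahalanobis_cutoff <- function(n_dims, alpha = 0.001) {
  if (n_dims < 1) stop("n_dims must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qchisq(1 - alpha, df = n_dims)
}

#' Flag univariate and multivariate outliers
#'
#' Implements the single-pass outlier screen used on item scores and on
#' factor scores: a subject is a univariate outlier if any of its scores
#' lies more than `z_thresh` standard deviations from the column mean
#' (computed on the full pre-removal sample), and a multivariate outlier if
#' its squared Mahalanobis distance from the sample mean and covariance
#' exceeds [mahalanobis_cutoff()]`(ncol(x), alpha)`. Both passes use the
#' same pre-removal moments; there is no re-estimation loop. Subjects
#' caught by both rules are reported as univariate, so the report's id
#' sets partition the input.
#'
#' @param x numeric subject x dimension matrix (complete).
#' @param z_thresh univariate z cut-off.
#' @param alpha Mahalanobis tail probability.
#' @return list with `keep` (logical mask), `report` (a
#'   [screening_report()]), `d2` (squared Mahalanobis distances), and
#'   `singular` flag (pseudo-inverse used).
#' @export
remove_outliers <- function(x, z_thresh = 3, alpha = 0.001) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < p + 2) stop("need at least n_dims + 2 subjects")
  ids <- rownames(x) %||% as.character(seq_len(n))
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1                          # constant column: z = 0
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  uni <- rowSums(abs(z) > z_thresh) > 0
  S <- stats::cov(x)
  singular <- FALSE
  d2 <- tryCatch(stats::mahalanobis(x, mu, S),
                 error = function(e) NULL)
  if (is.null(d2)) {
    singular <- TRUE
    d2 <- stats::mahalanobis(x, mu, MASS::ginv(S), inverted = TRUE)
  }
  cutoff <- mahalanobis_cutoff(p, alpha)
  multi <- d2 > cutoff & !uni
  keep <- !uni & !multi
  report <- screening_report(
    kept_ids = ids[keep],
    excluded_univariate_ids = ids[uni],
    excluded_multivariate_ids = ids[multi],
    thresholds = list(z_thresh = z_thresh, alpha = alpha,
                      mahalanobis_cutoff = cutoff))
  list(keep = keep, report = report, d2 = d2, singular = singular)
}
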