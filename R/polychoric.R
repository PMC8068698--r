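# Bivariate standard-Normal CDF, vectorised over (h, k) for scalar rho.
#
# Uses the single-integral representation
#   Phi2(h, k; rho) = Phi(h) Phi(k)
#     + 1/(2 pi) int_0^{asin(rho)} exp(-(h^2 + k^2 - 2 h k sin t)
#                                      / (2 cos^2 t)) dt
# evaluated by Gauss-Legendre quadrature (Drezner & Wesolowsky). For
# |rho| <= 0.925 a single 24-point rule is accurate to ~1e-10; for larger
# |rho| the integrand peaks near the endpoint, so the interval is split at
# asin(0.925) and the outer part gets a 48-point rule. Infinite arguments
# reduce to the marginal Normal CDF.
gl_nodes <- function(m) {
  # Golub-Welsch: nodes/weights on [-1, 1]
  i <- seq_len(m - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, m)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}
.gl24 <- gl_nodes(24)
.gl48 <- gl_nodes(48)

bvn_segment <- function(h, k, a, b, rule) {
  # int_a^b of the Drezner-Wesolowsky integrand, vectorised over (h, k)
  mid <- (a + b) / 2; half <- (b - a) / 2
  out <- numeric(length(h))
  for (i in seq_along(rule$x)) {
    t <- mid + half * rule$x[i]
    st <- sin(t); ct2 <- cos(t)^2
    out <- out + rule$w[i] * exp(-(h^2 + k^2 - 2 * h * k * st) / (2 * ct2))
  }
  out * half
}

#' Bivariate standard-Normal rectangle probability
#'
#' `pbvnorm(h, k, rho)` is `P(X <= h, Y <= k)` for standard bivariate
#' Normal `(X, Y)` with correlation `rho`, vectorised over `h` and `k`.
#' Used by the polychoric likelihood; accurate to roughly 1e-10 for
#' `|rho| <= 0.925` and better than 1e-7 up to `|rho| = 0.999`.
#'
#' @param h,k numeric vectors (recycled to a common length); `Inf` and
#'   `-Inf` are allowed.
#' @param rho scalar correlation in (-1, 1).
#' @return numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn); k <- rep_len(k, nn)
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  out <- numeric(nn)
  inf_h <- is.infinite(h); inf_k <- is.infinite(k)
  special <- inf_h | inf_k
  out[inf_h & h < 0] <- 0
  out[inf_k & k < 0] <- 0
  idx <- which(special & !(inf_h & h < 0) & !(inf_k & k < 0))
  if (length(idx)) {
    # at least one argument is +Inf: reduces to a marginal
    out[idx] <- ifelse(is.infinite(h[idx]),
                       ifelse(is.infinite(k[idx]), 1, stats::pnorm(k[idx])),
                       stats::pnorm(h[idx]))
  }
  fin <- which(!special)
  if (length(fin)) {
    hf <- h[fin]; kf <- k[fin]
    base <- stats::pnorm(hf) * stats::pnorm(kf)
    if (rho == 0) {
      out[fin] <- base
    } else {
      asr <- asin(rho)
      brk <- asin(0.925)
      if (abs(rho) <= 0.925) {
        integral <- bvn_segment(hf, kf, 0, asr, .gl24)
      } else {
        s <- sign(asr)
        integral <- bvn_segment(hf, kf, 0, s * brk, .gl24) +
          bvn_segment(hf, kf, s * brk, asr, .gl48)
      }
      out[fin] <- base + integral / (2 * pi)
    }
  }
  pmin(pmax(out, 0), 1)
}

# cell probabilities of the ordinal contingency table under latent
# bivariate normality: thresholds a (K1-1), b (K2-1), correlation rho
polychoric_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf); bb <- c(-Inf, b, Inf)
  G <- outer(aa, bb, function(x, y) x)       # grid rows
  H <- outer(aa, bb, function(x, y) y)
  P <- matrix(pbvnorm(as.numeric(G), as.numeric(H), rho), nrow = length(aa))
  # rectangle probabilities by double differencing
  P[-1, -1] - P[-nrow(P), -1] - P[-1, -ncol(P)] + P[-nrow(P), -ncol(P)]
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum-likelihood estimator of the correlation of the latent
#' bivariate Normal assumed to underlie two ordinal ratings. Thresholds are
#' set from the inverse-Normal cumulative marginal proportions; the
#' correlation is then estimated by maximising the multinomial likelihood
#' of the observed contingency table over `rho` alone (bounded 1-D
#' optimisation, with cell probabilities from [pbvnorm()]). Zero-count
#' cells enter the likelihood directly; no continuity correction is
#' applied. Perfect monotone association drives the optimum to the
#' boundary, where the estimate is clamped at +-0.999 and flagged.
#'
#' @param x,y integer-coded ordinal vectors; pairs with any `NA` are
#'   dropped. Each variable needs at least 2 observed categories.
#' @param rho_max boundary clamp for `|rho|`.
#' @return list with `rho`, `thresholds_x`, `thresholds_y`,
#'   `log_likelihood`, `converged`, `clamped`.
#' @export
polychoric_corr <- function(x, y, rho_max = 0.999) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("each variable needs at least 2 observed categories")
  n <- sum(tab)
  a <- stats::qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  b <- stats::qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  counts <- as.numeric(tab)
  negll <- function(rho) {
    pr <- as.numeric(polychoric_cell_probs(a, b, rho))
    -sum(counts * log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-rho_max, rho_max), tol = 1e-6)
  rho <- opt$minimum
  clamped <- FALSE
  # detect a boundary solution (perfect monotone association)
  if (rho_max - abs(rho) < 1e-4) {
    boundary <- sign(rho) * rho_max
    if (negll(boundary) <= opt$objective + 1e-8) {
      rho <- boundary
      clamped <- TRUE
    }
  }
  list(rho = rho, thresholds_x = unname(a), thresholds_y = unname(b),
       log_likelihood = -negll(rho), converged = TRUE, clamped = clamped)
}

#' Polychoric correlation matrix of an ordinal rating matrix
#'
#' Pairwise [polychoric_corr()] over all item pairs, with unit diagonal.
#' If the assembled matrix is not positive semi-definite (possible because
#' the entries are estimated pairwise), it is repaired by clipping
#' eigenvalues at `1e-6`, reconstructing, and rescaling to unit diagonal;
#' the repair is flagged in the `"repaired"` attribute.
#'
#' @param matrix a [rating_matrix()] with ordinal items, or a plain
#'   integer-coded matrix.
#' @return correlation matrix with attributes `repaired` (logical) and
#'   `n_obs` (number of rows used).
#' @export
polychoric_matrix <- function(matrix) {
  x <- if (inherits(matrix, "rating_matrix")) matrix$scores else
    as.matrix(matrix)
  p <- ncol(x)
  R <- diag(1, p)
  dimnames(R) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      est <- tryCatch(polychoric_corr(x[, i], x[, j]),
                      error = function(e)
                        stop(sprintf("polychoric failed for items %d and %d: %s",
                                     i, j, conditionMessage(e)), call. = FALSE))
      R[i, j] <- R[j, i] <- est$rho
    }
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals, p) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    diag(R) <- 1
    dimnames(R) <- list(colnames(x), colnames(x))
  }
  attr(R, "repaired") <- repaired
  attr(R, "n_obs") <- nrow(x)
  R
}
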