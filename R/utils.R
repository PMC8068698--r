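# internal helpers shared across modules

#' Derive a stage-specific random seed
#'
#' All randomised stages draw their seed from a single cohort/pipeline seed
#' through this rule, so each stage is independently reproducible.
#' The rule is `(seed * 101 + stage) mod (2^31 - 1)`.
#'
#' @param seed integer master seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 101 + stage) %% 2147483647)
}

#' Effect-size star label
#'
#' Maps an absolute Cohen's d to the conventional label used in cluster
#' profile plots: `***` if |d| > 0.8, `**` if |d| > 0.5, `*` if |d| > 0.2
#' (strict inequalities), empty otherwise.
#'
#' @param d numeric vector of Cohen's d values.
#' @return character vector of labels.
#' @export
star_label <- function(d) {
  a <- abs(d)
  out <- character(length(d))
  out[a > 0.2] <- "*"
  out[a > 0.5] <- "**"
  out[a > 0.8] <- "***"
  out[is.na(d)] <- NA_character_
  out
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors, used to match factors
#' across fits and to quantify bootstrap stability of a factor solution.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# weighted column means
wcolMeans <- function(x, w) {
  colSums(x * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
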