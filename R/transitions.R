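#' Cross-wave cluster transition table
#'
#' Cross-tabulates cluster membership at the first wave (rows) against the
#' second (columns) over the subjects present in both, and row-normalises
#' to transition proportions. Use [cellwise_ztests()] to fill the per-cell
#' significance flags.
#'
#' @param labels_w1,labels_w2 cluster label vectors; matched on names when
#'   both are named (inner join), otherwise positionally.
#' @param k_w1,k_w2 optional cluster counts (defaults: observed maxima),
#'   so empty clusters keep their rows/columns.
#' @return a `transition_table` list: `counts`, `proportions`, `n`, and
#'   empty slots for the z-test results.
#' @export
transition_table <- function(labels_w1, labels_w2,
                             k_w1 = NULL, k_w2 = NULL) {
  m <- match_partitions(labels_w1, labels_w2)
  if (!length(m$a)) stop("no overlapping subjects")
  k1 <- k_w1 %||% max(m$a)
  k2 <- k_w2 %||% max(m$b)
  counts <- table(factor(m$a, levels = seq_len(k1)),
                  factor(m$b, levels = seq_len(k2)))
  counts <- unclass(counts)
  dimnames(counts) <- list(w1 = paste0("C", seq_len(k1)),
                           w2 = paste0("A", seq_len(k2)))
  props <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, proportions = props, n = sum(counts),
                 z = NULL, p_raw = NULL, p_adj = NULL, flags = NULL,
                 family_size = NULL),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %d matched subjects, %d x %d clusters\n",
              x$n, nrow(x$counts), ncol(x$counts)))
  print(round(x$proportions, 3))
  if (!is.null(x$flags)) {
    cat("flags (Bonferroni over", x$family_size, "cells):\n")
    print(x$flags, quote = FALSE)
  }
  invisible(x)
}

#' Goodness-of-fit test of one transition row against an equal split
#'
#' Pearson chi-squared test of the destination counts of one origin
#' cluster against the null that each destination cluster is equally
#' likely (for `K` clusters, 1/K each); `df = K - 1`. A warning flag is
#' set when any expected count falls below 5.
#'
#' @param row_counts integer vector of destination counts.
#' @return list with `statistic`, `df`, `p_value`, `low_expected`.
#' @export
equal_split_chi2 <- function(row_counts) {
  row_counts <- as.numeric(row_counts)
  K <- length(row_counts)
  n <- sum(row_counts)
  if (n <= 0) stop("row total must be positive")
  expected <- n / K
  test <- suppressWarnings(
    stats::chisq.test(row_counts, p = rep(1 / K, K)))
  list(statistic = unname(test$statistic), df = unname(test$parameter),
       p_value = unname(test$p.value), low_expected = expected < 5)
}

#' Cellwise proportion z-tests against an equal split
#'
#' For every cell of a [transition_table()], tests the observed transition
#' proportion against the equal-split null `p0 = 1/K_w2` with a
#' one-proportion z statistic, `z = (phat - p0) / sqrt(p0 (1 - p0) /
#' n_row)`, two-sided Normal p-values, and Bonferroni correction over all
#' `K_w1 * K_w2` cells. Cells of empty origin rows are flagged missing.
#'
#' @param table a `transition_table`.
#' @param alpha family-wise significance level.
#' @return the table with `z`, `p_raw`, `p_adj`, `flags` (`"over"`,
#'   `"under"` or `""`) and `family_size` filled.
#' @export
cellwise_ztests <- function(table, alpha = 0.05) {
  counts <- table$counts
  K2 <- ncol(counts)
  p0 <- 1 / K2
  n_row <- rowSums(counts)
  phat <- table$proportions
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / pmax(n_row, 1))
  z[n_row == 0, ] <- NA_real_
  p_raw <- 2 * stats::pnorm(-abs(z))
  fam <- length(counts)
  p_adj <- pmin(p_raw * fam, 1)   # matrix first: pmin keeps its dim
  flags <- matrix("", nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
  flags[!is.na(p_adj) & p_adj < alpha & z > 0] <- "over"
  flags[!is.na(p_adj) & p_adj < alpha & z < 0] <- "under"
  flags[is.na(z)] <- NA_character_
  table$z <- z; table$p_raw <- p_raw; table$p_adj <- p_adj
  table$flags <- flags; table$family_size <- fam
  table
}

#' Covariate contrasts for specific transitions
#'
#' Compares childhood covariates between subjects who made a given
#' transition and the rest of the sample with two-sample pooled-variance
#' t-tests (`df = n1 + n2 - 2`) and Cohen's d with the pooled SD.
#' P-values are Bonferroni-adjusted across the covariates tested in one
#' call. Missing covariate values are dropped per covariate.
#'
#' @param values numeric vector, or data frame / matrix of covariates
#'   (one column per covariate).
#' @param in_group logical membership mask (TRUE = made the transition).
#' @return data frame with one row per covariate: group means, SEs, `t`,
#'   `df`, `p_raw`, `p_adj`, `cohens_d`.
#' @export
predictor_contrast <- function(values, in_group) {
  if (is.null(dim(values)))
    values <- stats::setNames(data.frame(values), "covariate")
  values <- as.data.frame(values)
  in_group <- as.logical(in_group)
  out <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    ok <- !is.na(v)
    x1 <- v[ok & in_group]; x2 <- v[ok & !in_group]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    if (sp2 <= 0) stop("zero pooled variance for covariate ", nm)
    t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(covariate = nm,
               mean_in = mean(x1), se_in = stats::sd(x1) / sqrt(n1),
               mean_out = mean(x2), se_out = stats::sd(x2) / sqrt(n2),
               t = t, df = df, p_raw = p,
               cohens_d = (mean(x1) - mean(x2)) / sqrt(sp2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Export a transition table
#'
#' Writes counts, proportions, z statistics, adjusted p-values and flags
#' as CSV (long format), and optionally a JSON edge list suitable for
#' Sankey-style plotting.
#'
#' @param table a `transition_table` (after [cellwise_ztests()] for the
#'   test columns).
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @export
write_transition_table <- function(table, path_csv = NULL,
                                   path_json = NULL) {
  long <- expand.grid(from = rownames(table$counts),
                      to = colnames(table$counts),
                      stringsAsFactors = FALSE)
  idx <- cbind(match(long$from, rownames(table$counts)),
               match(long$to, colnames(table$counts)))
  long$count <- table$counts[idx]
  long$proportion <- table$proportions[idx]
  if (!is.null(table$z)) {
    long$z <- table$z[idx]
    long$p_adj <- table$p_adj[idx]
    long$flag <- table$flags[idx]
  }
  if (!is.null(path_csv)) utils::write.csv(long, path_csv,
                                           row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(long, path_json, auto_unbox = TRUE, digits = NA)
  invisible(long)
}
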