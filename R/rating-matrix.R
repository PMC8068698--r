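#' Rating matrices: subject-by-item questionnaire scores
#'
#' A `rating_matrix` holds one wave of questionnaire ratings: a numeric
#' subject x item matrix (missing cells stored as `NA`), per-item scale
#' metadata, and subject identifiers. Two item scale types are supported:
#'
#' * `"analogue"`: continuous visual-analogue scores, in millimetres on a
#'   declared range (typically 0--100 mm from "does not apply" to
#'   "certainly applies");
#' * `"ordinal"`: discrete ratings coded as integers `1..levels`.
#'
#' @param scores numeric matrix, subjects in rows, items in columns.
#' @param item_meta data frame describing the items, as produced by
#'   [analogue_items()] or [ordinal_items()]; one row per column of
#'   `scores`, columns `item`, `type`, `lower`, `upper`, `levels`.
#' @param subject_ids character vector of subject identifiers; defaults to
#'   `rownames(scores)` or `S0001`-style ids.
#' @return an object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, item_meta, subject_ids = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(item_meta) != ncol(scores))
    stop("item_meta must have one row per item column")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(scores) %||%
      sprintf("S%04d", seq_len(nrow(scores)))
  }
  rownames(scores) <- subject_ids
  colnames(scores) <- item_meta$item
  x <- structure(
    list(scores = scores, item_meta = item_meta,
         subject_ids = as.character(subject_ids)),
    class = "rating_matrix")
  validate_rating_matrix(x)
  x
}

#' @rdname rating_matrix
#' @param n_items number of items.
#' @param range length-2 numeric range of the analogue scale (mm).
#' @export
analogue_items <- function(n_items, range = c(0, 100)) {
  data.frame(item = sprintf("item_%03d", seq_len(n_items)),
             type = "analogue", lower = range[1], upper = range[2],
             levels = NA_integer_, stringsAsFactors = FALSE)
}

#' @rdname rating_matrix
#' @param levels number of ordinal categories.
#' @export
ordinal_items <- function(n_items, levels = 4) {
  data.frame(item = sprintf("item_%03d", seq_len(n_items)),
             type = "ordinal", lower = 1, upper = levels,
             levels = as.integer(levels), stringsAsFactors = FALSE)
}

validate_rating_matrix <- function(x) {
  sc <- x$scores
  for (j in seq_len(ncol(sc))) {
    m <- x$item_meta[j, ]
    v <- sc[, j]
    v <- v[!is.na(v)]
    if (m$type == "ordinal") {
      bad <- which(v != round(v) | v < 1 | v > m$levels)
      if (length(bad))
        stop(sprintf("item %s: ordinal values outside 1..%d (e.g. %g)",
                     m$item, m$levels, v[bad[1]]))
    } else {
      bad <- which(v < m$lower | v > m$upper)
      if (length(bad))
        stop(sprintf("item %s: analogue values outside [%g, %g] (e.g. %g)",
                     m$item, m$lower, m$upper, v[bad[1]]))
    }
  }
  invisible(x)
}

#' @export
print.rating_matrix <- function(x, ...) {
  sc <- x$scores
  cat(sprintf("<rating_matrix> %d subjects x %d items (%s), %.1f%% missing\n",
              nrow(sc), ncol(sc), paste(unique(x$item_meta$type), collapse = "+"),
              100 * mean(is.na(sc))))
  invisible(x)
}

#' @export
dim.rating_matrix <- function(x) dim(x$scores)

#' Missingness mask of a rating matrix
#'
#' @param x a `rating_matrix`.
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(x) is.na(x$scores)

#' Read and write wave tables
#'
#' Wave tables are plain CSV files with a header row: a `subject_id` column
#' followed by one column per item. Empty cells and the token `NA` are read
#' as missing. Values are validated against the declared item metadata;
#' out-of-range cells are reported with their coordinates.
#'
#' @param path file path.
#' @param item_meta item metadata (see [rating_matrix()]); item columns in
#'   the file must match `item_meta$item`.
#' @param na_tokens character vector of tokens treated as missing.
#' @return `read_wave_table()` returns a `rating_matrix`;
#'   `write_wave_table()` returns `path` invisibly.
#' @export
read_wave_table <- function(path, item_meta, na_tokens = c("", "NA")) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = na_tokens)
  if (!"subject_id" %in% names(df))
    stop("wave table must contain a subject_id column")
  items <- item_meta$item
  missing_cols <- setdiff(items, names(df))
  if (length(missing_cols))
    stop("wave table is missing item columns: ",
         paste(missing_cols, collapse = ", "))
  sc <- suppressWarnings(
    vapply(items, function(it) as.numeric(df[[it]]), numeric(nrow(df))))
  if (nrow(df) == 1L) sc <- matrix(sc, nrow = 1, dimnames = list(NULL, items))
  # non-numeric tokens other than declared NA tokens are malformed
  for (it in items) {
    raw <- df[[it]]
    bad <- which(!is.na(raw) & is.na(suppressWarnings(as.numeric(raw))))
    if (length(bad))
      stop(sprintf("malformed value '%s' at line %d, column %s",
                   raw[bad[1]], bad[1] + 1L, it))
  }
  tryCatch(
    rating_matrix(sc, item_meta, subject_ids = df$subject_id),
    error = function(e) stop("wave table validation failed: ",
                             conditionMessage(e), call. = FALSE))
}

#' @rdname read_wave_table
#' @param x a `rating_matrix`.
#' @param covariates optional data frame of per-subject covariates appended
#'   as extra columns.
#' @export
write_wave_table <- function(x, path, covariates = NULL) {
  df <- data.frame(subject_id = x$subject_ids, x$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# subset a rating matrix by subject index or id
subset_subjects <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$subject_ids)
  rating_matrix(x$scores[keep, , drop = FALSE], x$item_meta,
                subject_ids = x$subject_ids[keep])
}
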