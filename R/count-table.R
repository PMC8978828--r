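#' Construct and validate a taxa count table
#'
#' A count table is an `n x d` matrix of nonnegative integers with samples in
#' rows and taxa in columns.  Every sample must have at least one nonzero
#' count and both sample ids and taxon names must be unique.
#'
#' @param counts numeric matrix of nonnegative integers (samples x taxa).
#' @param sample_ids optional character vector of sample ids; defaults to the
#'   row names of `counts` (or `sample_1..n`).
#' @param taxon_names optional character vector of taxon names; defaults to the
#'   column names of `counts` (or `taxon_1..d`).
#' @return an integer matrix of class `count_table`.
#' @examples
#' m <- count_table(matrix(c(1, 0, 2, 3, 4, 0), 2, 3))
#' prevalence_filter(m, 0.5)
#' @export
count_table <- function(counts, sample_ids = NULL, taxon_names = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(counts)))
  }
  if (is.null(taxon_names)) {
    taxon_names <- colnames(counts)
    if (is.null(taxon_names)) taxon_names <- paste0("taxon_", seq_len(ncol(counts)))
  }
  dimnames(counts) <- list(as.character(sample_ids), as.character(taxon_names))
  validate_count_table(counts)
  structure(counts, class = c("count_table", "matrix", "array"))
}

validate_count_table <- function(counts) {
  if (ncol(counts) < 2L) stop("count table needs at least 2 taxa")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(counts)[zero_rows], collapse = ", "))
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("taxon names must be unique")
  invisible(counts)
}

#' Remove rare taxa by prevalence
#'
#' Retains exactly the taxa with nonzero counts in at least
#' `ceiling(threshold * n)` samples, preserving column order.  The default 10%
#' threshold is the conventional rare-taxa filter for 16S/WGS tables.
#'
#' @param table a [count_table()] (or coercible matrix).
#' @param threshold fraction of samples in `(0, 1]` a taxon must appear in.
#' @return the filtered `count_table`.
#' @export
prevalence_filter <- function(table, threshold = 0.10) {
  check_scalar_number(threshold, "threshold", lower = 1e-12, upper = 1)
  if (!inherits(table, "count_table")) table <- count_table(table)
  need <- ceiling(threshold * nrow(table))
  keep <- colSums(table >= 1) >= need
  if (sum(keep) < 2L)
    stop("fewer than 2 taxa present in >= ", round(100 * threshold, 3),
         "% of samples; lower the prevalence threshold")
  count_table(table[, keep, drop = FALSE])
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x), "samples x", ncol(x), "taxa;",
      round(100 * mean(x == 0), 1), "% zeros\n")
  invisible(x)
}
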