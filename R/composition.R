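#' Closure: map counts onto the unit-sum simplex
#'
#' Divides every row by its total so rows sum to 1, turning a count table into
#' relative abundances (a composition).
#'
#' @param table numeric matrix with nonnegative entries; every row must have a
#'   positive sum.
#' @return an `n x d` matrix of class `composition` whose rows sum to 1; the
#'   `strictly_positive` attribute records whether all entries are > 0.
#' @examples
#' closure(matrix(c(1, 1, 2), 1, 3))
#' @export
closure <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m) || any(m < 0)) stop("entries must be nonnegative and non-missing")
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- rownames(m)[rs <= 0]
    if (is.null(bad)) bad <- which(rs <= 0)
    stop("sample(s) with zero total: ", paste(bad, collapse = ", "))
  }
  as_composition(m / rs)
}

as_composition <- function(values, check = TRUE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("taxon_", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (check) {
    if (anyNA(values) || any(values < 0)) stop("composition entries must be nonnegative")
    if (any(abs(rowSums(values) - 1) > 1e-9))
      stop("composition rows must sum to 1 within 1e-9")
  }
  structure(values,
            strictly_positive = all(values > 0),
            class = c("composition", "matrix", "array"))
}

is_composition_like <- function(m) {
  is.numeric(m) && all(m >= 0) && all(abs(rowSums(m) - 1) < 1e-9)
}

#' Multiplicative zero replacement
#'
#' Imputes zeros in a composition with the multiplicative strategy: delta is
#' the smallest nonzero value across the whole matrix, zeros become delta, and
#' every nonzero entry x in a row with z zeros becomes `x * (1 - z * delta)`,
#' which preserves unit sums exactly and leaves within-row ratios among
#' nonzero parts unchanged.
#'
#' @param comp a [closure()] output (rows summing to 1).
#' @return a strictly positive `composition`.
#' @export
multiplicative_replacement <- function(comp) {
  if (!inherits(comp, "composition")) comp <- as_composition(comp)
  if (all(comp > 0)) return(comp)
  delta <- min(comp[comp > 0])
  z <- rowSums(comp == 0)
  if (any(delta * z >= 1))
    stop("zero replacement would remove all mass in row(s): ",
         paste(rownames(comp)[delta * z >= 1], collapse = ", "),
         " (delta = ", signif(delta, 4), ")")
  out <- comp * (1 - z * delta)
  out[comp == 0] <- delta
  as_composition(unclass(out), check = FALSE)
}

#' Full pairwise-logratio frame
#'
#' Computes all `d(d-1)/2` pairwise logratios of a strictly positive
#' composition.  Pairs follow the lower-off-diagonal convention: for
#' denominator index `k < j` the column is `log(r_j / r_k)`, named
#' `"taxon_j/taxon_k"`, enumerated k-major (`(2,1), (3,1), ..., (3,2), ...`).
#' Only one orientation per taxon pair is stored since the reverse ratio is
#' its negation.
#'
#' @param comp strictly positive `composition` (after
#'   [multiplicative_replacement()] if the data contained zeros).
#' @return an `n x d(d-1)/2` matrix of class `logratio_frame`; the `ratios`
#'   attribute is a data.frame with `num` and `den` taxon names per column.
#' @examples
#' z <- pairwise_logratios(closure(matrix(1:6 + 0, 2, 3)))
#' ncol(z)  # choose(3, 2)
#' @export
pairwise_logratios <- function(comp) {
  if (!inherits(comp, "composition")) comp <- as_composition(comp)
  if (any(comp <= 0)) stop("composition must be strictly positive; impute zeros first")
  d <- ncol(comp)
  if (d < 2L) stop("need at least 2 taxa")
  taxa <- colnames(comp)
  kk <- rep.int(seq_len(d - 1L), times = (d - 1L):1L)
  jj <- sequence((d - 1L):1L) + kk
  logr <- log(unclass(comp))
  Z <- logr[, jj, drop = FALSE] - logr[, kk, drop = FALSE]
  ratios <- data.frame(num = taxa[jj], den = taxa[kk], stringsAsFactors = FALSE)
  new_logratio_frame(Z, ratios, rownames(comp))
}

new_logratio_frame <- function(values, ratios, sample_ids = NULL) {
  values <- matrix(as.numeric(values), nrow = if (is.matrix(values)) nrow(values) else 1)
  colnames(values) <- ratio_name(ratios$num, ratios$den)
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  structure(values, ratios = ratios, class = c("logratio_frame", "matrix", "array"))
}

#' Extract a sub-frame of logratios by ratio label
#'
#' Order-stable, lossless extraction of columns from a logratio frame.  A
#' requested ratio stored in the opposite orientation (`"b/a"` instead of
#' `"a/b"`) is returned sign-flipped under the requested name.
#'
#' @param Z a `logratio_frame`.
#' @param ratios character vector of `"num/den"` labels, or a data.frame with
#'   `num`/`den` columns (e.g. the `edges` of a [maximum_spanning_tree()]).
#' @return a `logratio_frame` with one column per requested ratio.
#' @export
plr_subset <- function(Z, ratios) {
  stopifnot(inherits(Z, "logratio_frame"))
  if (is.data.frame(ratios)) {
    req <- data.frame(num = as.character(ratios$num), den = as.character(ratios$den),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(as.character(ratios), "/", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("ratio labels must look like 'num/den'")
    req <- data.frame(num = vapply(parts, `[`, "", 1L),
                      den = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  have <- colnames(Z)
  fwd <- match(ratio_name(req$num, req$den), have)
  rev <- match(ratio_name(req$den, req$num), have)
  missing <- is.na(fwd) & is.na(rev)
  if (any(missing))
    stop("ratio(s) not present in frame: ",
         paste(ratio_name(req$num, req$den)[missing], collapse = ", "))
  cols <- ifelse(is.na(fwd), rev, fwd)
  sign <- ifelse(is.na(fwd), -1, 1)
  vals <- Z[, cols, drop = FALSE] * rep(sign, each = nrow(Z))
  new_logratio_frame(vals, req, rownames(Z))
}

#' Additive logratio transform and its inverse
#'
#' `alr()` maps a strictly positive composition to `(d-1)`-dimensional real
#' coordinates relative to a reference part (by default the last taxon);
#' `inverse_alr()` appends the implicit zero coordinate, exponentiates, and
#' closes.  A row-wise maximum is subtracted before exponentiation; the
#' closure makes the result invariant to that guard.
#'
#' @param comp strictly positive `composition`.
#' @param ref reference column (index or taxon name); default: last column.
#' @return `alr()`: an `n x (d-1)` numeric matrix. `inverse_alr()`: a
#'   `composition` with `ncol(S) + 1` parts.
#' @export
alr <- function(comp, ref = ncol(comp)) {
  if (!inherits(comp, "composition")) comp <- as_composition(comp)
  if (any(comp <= 0)) stop("composition must be strictly positive")
  if (is.character(ref)) ref <- match(ref, colnames(comp))
  logr <- log(unclass(comp))
  out <- logr[, -ref, drop = FALSE] - logr[, ref]
  attr(out, "ref") <- colnames(comp)[ref]
  out
}

#' @param S numeric matrix of ALR coordinates (`n x (d-1)`).
#' @param taxon_names optional `d` taxon names for the output composition.
#' @rdname alr
#' @export
inverse_alr <- function(S, taxon_names = NULL) {
  S <- as.matrix(S)
  if (anyNA(S) || any(!is.finite(S))) stop("ALR coordinates must be finite")
  E <- cbind(S, 0)
  E <- exp(E - apply(E, 1L, max))
  comp <- E / rowSums(E)
  if (is.null(taxon_names)) taxon_names <- paste0("taxon_", seq_len(ncol(comp)))
  colnames(comp) <- taxon_names
  rownames(comp) <- rownames(S)
  as_composition(comp, check = FALSE)
}

#' @export
print.composition <- function(x, ...) {
  cat("composition:", nrow(x), "samples x", ncol(x), "parts",
      if (isTRUE(attr(x, "strictly_positive"))) "(strictly positive)\n" else "(contains zeros)\n")
  invisible(x)
}

#' @export
print.logratio_frame <- function(x, ...) {
  cat("logratio_frame:", nrow(x), "samples x", ncol(x), "logratios\n")
  invisible(x)
}
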