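#' Differential compositional variation (DCV) components
#'
#' Scores each pairwise logratio with five two-class statistics:
#' \describe{
#'   \item{welch_t}{absolute Welch t statistic (difference of class means
#'     scaled by unpooled standard errors); the absolute value makes the score
#'     invariant to the arbitrary orientation of each ratio.}
#'   \item{mean_f}{a mean-difference F ratio whose denominator is the sum of
#'     the two class variances (not the classical pooled mean square).}
#'   \item{bf_f}{Brown-Forsythe F on absolute deviations from class medians,
#'     sensitive to heterogeneity of variances.}
#'   \item{ks_d}{two-sample Kolmogorov-Smirnov sup distance between class
#'     empirical distribution functions.}
#'   \item{info_gain}{natural-log information gain of the class labels after
#'     supervised MDL (Fayyad-Irani) discretization of the logratio, with a
#'     median-split fallback when MDL accepts no cut.}
#' }
#' Degenerate denominators are floored at 1e-12 and a component with an
#' exactly zero numerator is 0, so a logratio constant across samples scores
#' 0 on every component.
#'
#' @param Z a [pairwise_logratios()] frame (or any `logratio_frame`).
#' @param y two-class labels, one per row of `Z`; each class needs >= 2
#'   samples.
#' @return a `p x 5` numeric matrix, rows named by ratio.
#' @export
dcv_components <- function(Z, y) {
  stopifnot(inherits(Z, "logratio_frame"))
  if (any(!is.finite(Z))) stop("logratio frame contains non-finite values")
  code <- binary_codes(y)
  if (length(code) != nrow(Z)) stop("length(y) must equal nrow(Z)")
  V <- .dcv_components_cpp(unclass(Z), code)
  dimnames(V) <- list(colnames(Z), c("welch_t", "mean_f", "bf_f", "ks_d", "info_gain"))
  V
}

#' Aggregate DCV components into per-ratio scores
#'
#' Each component column is z-score standardized over the `p` logratios
#' (columns with zero variance contribute 0, as does every column when
#' `p == 1`, with a warning) and the standardized components are summed row
#' wise into a single DCV score per logratio.
#'
#' @param V a [dcv_components()] matrix, or a `logratio_frame` together with
#'   `y` for convenience.
#' @param y group labels, only used when `V` is a `logratio_frame`.
#' @return an object of class `dcv_scores`: list with `scores` (named numeric,
#'   one per ratio), `standardized` and `components` matrices, and the ratio
#'   `num`/`den` table.
#' @export
dcv_scores <- function(V, y = NULL) {
  if (inherits(V, "logratio_frame")) {
    ratios <- attr(V, "ratios")
    V <- dcv_components(V, y)
  } else {
    ratios <- ratio_table_from_names(rownames(V))
  }
  if (!is.matrix(V) || ncol(V) != 5L) stop("V must be a p x 5 component matrix")
  if (any(!is.finite(V))) stop("component matrix must be finite")
  p <- nrow(V)
  if (p == 1L) {
    warning("only one logratio: standardized components are undefined and set to 0")
    Vhat <- V * 0
  } else {
    mu <- colMeans(V)
    sdv <- apply(V, 2L, sd)
    Vhat <- sweep(V, 2L, mu, "-")
    Vhat <- sweep(Vhat, 2L, ifelse(sdv > 0, sdv, Inf), "/")
  }
  structure(list(scores = setNames(rowSums(Vhat), rownames(V)),
                 standardized = Vhat,
                 components = V,
                 ratios = ratios),
            class = "dcv_scores")
}

ratio_table_from_names <- function(nm) {
  parts <- strsplit(nm, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("ratio labels must look like 'num/den'")
  data.frame(num = vapply(parts, `[`, "", 1L),
             den = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' @export
print.dcv_scores <- function(x, ...) {
  cat("dcv_scores:", length(x$scores), "logratios; top ratios:\n")
  ord <- order(-x$scores, names(x$scores))
  print(round(head(x$scores[ord], 5L), 4))
  invisible(x)
}

#' Write a per-ratio DCV report
#'
#' One row per logratio with the raw and standardized components and the
#' total score, sorted by descending score with the ratio name as the stable
#' tie-break.
#'
#' @param scores a [dcv_scores()] object.
#' @param path output TSV path.
#' @return the report data.frame, invisibly.
#' @export
write_dcv_report <- function(scores, path) {
  stopifnot(inherits(scores, "dcv_scores"))
  df <- data.frame(ratio = names(scores$scores),
                   numerator = scores$ratios$num,
                   denominator = scores$ratios$den,
                   scores$components,
                   setNames(as.data.frame(scores$standardized),
                            paste0("z_", colnames(scores$standardized))),
                   score = unname(scores$scores),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- df[order(-df$score, df$ratio), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
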