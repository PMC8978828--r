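#' Inter-sample Euclidean distance matrix
#'
#' @param Z numeric matrix (e.g. a logratio sub-frame), samples in rows.
#' @return an object of class `distance_matrix`: symmetric `n x n` matrix with
#'   zero diagonal and sample ids as dimnames.
#' @export
euclidean_distances <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("need at least 2 samples")
  D <- as.matrix(dist(Z))
  structure(D, class = c("distance_matrix", "matrix", "array"))
}

as_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric within 1e-12")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(D < 0)) stop("distances must be nonnegative")
  structure(D, class = c("distance_matrix", "matrix", "array"))
}

new_association_stat <- function(kind, value, parts, ...) {
  structure(c(list(kind = kind, value = value, parts = parts), list(...)),
            class = "association_stat")
}

#' @export
print.association_stat <- function(x, ...) {
  cat("association_stat [", x$kind, "]: ", signif(x$value, 6), "\n", sep = "")
  invisible(x)
}

#' DISCO F ratio (energy partition of dispersion)
#'
#' Partitions the total dispersion of a distance matrix, with distances raised
#' to the exponent `alpha` in `(0, 2]`, into a between-group energy component
#' `S` and a within-group component `W` (with `S + W` equal to the total
#' dispersion), and returns the F-like ratio `S / (W / (n - 2))` for two
#' groups.  Unlike the classical ANOVA F this statistic does not follow an F
#' distribution; significance comes from permutation.
#'
#' @param D a `distance_matrix` (or symmetric matrix / `dist`).
#' @param y two-class labels, each class with >= 2 samples.
#' @param alpha exponent on the distances, in `(0, 2]`; 1 is the energy
#'   statistic convention.
#' @return an `association_stat` with parts `S`, `W`, and `total`.
#' @export
disco_f <- function(D, y, alpha = 1) {
  D <- as_distance_matrix(D)
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 2)
  code <- binary_codes(y)
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 samples")
  Da <- if (alpha == 1) unclass(D) else unclass(D)^alpha
  parts <- .disco_parts_cpp(Da, code)
  value <- if (parts$W <= 0) Inf else parts$S / (parts$W / (n - 2))
  new_association_stat("discoF", value, parts, alpha_exponent = alpha)
}

#' Two-sample energy statistic
#'
#' `(n1 n2 / n) * (2 * mean(between) - mean(within 1) - mean(within 2))` on
#' raw distances; nonnegative for any metric.  Singleton groups are allowed
#' (their within-group mean is 0), matching the bare formula.
#'
#' @inheritParams disco_f
#' @return an `association_stat`.
#' @export
energy_statistic <- function(D, y) {
  D <- as_distance_matrix(D)
  code <- as.integer(as_group_labels(y, min_per_class = 1L)) - 1L
  if (max(code) != 1L) stop("exactly 2 classes required")
  value <- .energy_stat_cpp(unclass(D), code)
  new_association_stat("energy", value, list())
}

#' PERMANOVA pseudo-F
#'
#' Distance-based multivariate analysis of variance: the total sum of squares
#' of the squared inter-sample distances is partitioned into among-group and
#' within-group components, and `F = (SS_A / (a - 1)) / (SS_W / (n - a))`.
#' When `SS_W` is exactly 0 the statistic is reported as `+Inf` with
#' `infinite = TRUE`, ordered above every finite value.
#'
#' @inheritParams disco_f
#' @param y labels over >= 2 groups, each with >= 2 samples.
#' @return an `association_stat` with parts `SS_T`, `SS_A`, `SS_W`.
#' @export
permanova_f <- function(D, y) {
  D <- as_distance_matrix(D)
  y <- as_group_labels(y)
  a <- nlevels(y)
  n <- nrow(D)
  parts <- .permanova_parts_cpp(unclass(D)^2, as.integer(y) - 1L, a)
  den <- parts$SS_W / (n - a)
  value <- if (den <= 0) Inf else (parts$SS_A / (a - 1)) / den
  new_association_stat("permanovaF", value, parts, infinite = !is.finite(value))
}

#' Spatial median (geometric median) of a point cloud
#'
#' Weiszfeld iteration with tolerance 1e-8 and at most 1000 iterations;
#' errors on non-convergence.
#'
#' @param X numeric matrix, points in rows.
#' @return numeric vector of length `ncol(X)`.
#' @export
spatial_median <- function(X) {
  X <- as.matrix(X)
  res <- .spatial_median_cpp(X, 1e-8, 1000L)
  if (!res$converged)
    stop("Weiszfeld iteration failed to converge within 1000 iterations")
  setNames(res$median, colnames(X))
}

#' PERMDISP F with spatial medians
#'
#' Homogeneity-of-dispersion statistic: each group's spatial median is
#' computed directly in the coordinate space (equivalent, for Euclidean
#' distances, to the usual principal-coordinate embedding), residuals are the
#' Euclidean distances of each sample to its group median, and the statistic
#' is the one-way ANOVA F on those residuals.
#'
#' @param Zp numeric matrix of coordinates (e.g. a logratio sub-frame).
#' @param y two-class labels, each class with >= 2 samples.
#' @return an `association_stat` with the residual ANOVA F.
#' @export
permdisp_f <- function(Zp, y) {
  Zp <- as.matrix(Zp)
  y <- as_group_labels(y)
  res <- .permdisp_f_cpp(Zp, as.integer(y) - 1L, nlevels(y), 1e-8, 1000L)
  if (!res$converged)
    stop("Weiszfeld iteration failed to converge within ", res$maxit, " iterations")
  new_association_stat("permdispF", res$F, list())
}

#' Raw combined-F statistic
#'
#' Sum of the PERMANOVA F (location) on Euclidean distances of `Zp` and the
#' PERMDISP F (dispersion), jointly sensitive to location and scale
#' differences between groups.
#'
#' @inheritParams permdisp_f
#' @return an `association_stat` with parts `F_location` and `F_dispersion`.
#' @export
combined_f <- function(Zp, y) {
  floc <- permanova_f(euclidean_distances(Zp), y)
  fdisp <- permdisp_f(Zp, y)
  new_association_stat("cF_raw", floc$value + fdisp$value,
                       list(F_location = floc$value, F_dispersion = fdisp$value,
                            permanova = floc$parts))
}

#' Permutation-scaled combined-F statistic
#'
#' Each combined-F component is z-scored against its own permutation null
#' (mean and standard deviation of the statistic over the supplied label
#' permutations) before summing, so location and dispersion contributions are
#' on a common scale.  The statistic is stochastic up to the permutation set;
#' reuse one set across calls for comparability.
#'
#' @inheritParams permdisp_f
#' @param perm_labels list of >= 30 permuted label vectors (see
#'   [generate_permutations()]), or an integer 0/1 matrix with one permutation
#'   per row.
#' @return an `association_stat` with parts `F_location`, `F_dispersion`,
#'   `F_hat_location`, `F_hat_dispersion` and the null moments.
#' @export
scaled_combined_f <- function(Zp, y, perm_labels) {
  Zp <- as.matrix(Zp)
  P <- as_perm_matrix(perm_labels, y)
  if (nrow(P) < 30L) stop("need at least 30 permuted label vectors, got ", nrow(P))
  code <- binary_codes(y)
  D2 <- unclass(euclidean_distances(Zp))^2
  obs_loc <- permanova_f_binary(D2, code)
  obs_disp <- .permdisp_f_cpp(Zp, code, 2L, 1e-8, 1000L)
  if (!obs_disp$converged) stop("Weiszfeld iteration failed to converge")
  null_loc <- .permanova_f_null_cpp(D2, P, 2L)
  null_disp <- .permdisp_f_null_cpp(Zp, P, 2L, 1e-8, 1000L)
  sd_loc <- sd(null_loc); sd_disp <- sd(null_disp)
  if (!is.finite(sd_loc) || !is.finite(sd_disp) || sd_loc == 0 || sd_disp == 0)
    stop("degenerate permutation null (zero or non-finite standard deviation)")
  f_hat_loc <- (obs_loc - mean(null_loc)) / sd_loc
  f_hat_disp <- (obs_disp$F - mean(null_disp)) / sd_disp
  new_association_stat(
    "cF_scaled", f_hat_loc + f_hat_disp,
    list(F_location = obs_loc, F_dispersion = obs_disp$F,
         F_hat_location = f_hat_loc, F_hat_dispersion = f_hat_disp,
         null_mean_location = mean(null_loc), null_sd_location = sd_loc,
         null_mean_dispersion = mean(null_disp), null_sd_dispersion = sd_disp),
    m = nrow(P))
}

# fast internal scaled combined-F used in the greedy loop: takes the squared
# Euclidean distance matrix directly (built incrementally from per-ratio
# squared differences) plus the subset coordinates for the dispersion term
scaled_cf_fast <- function(D2, X, code, P) {
  obs_loc <- permanova_f_binary(D2, code)
  obs_disp <- .permdisp_f_cpp(X, code, 2L, 1e-8, 1000L)
  if (!obs_disp$converged) stop("Weiszfeld iteration failed to converge")
  null_loc <- .permanova_f_null_cpp(D2, P, 2L)
  null_disp <- .permdisp_f_null_cpp(X, P, 2L, 1e-8, 1000L)
  sd_loc <- sd(null_loc); sd_disp <- sd(null_disp)
  if (!is.finite(sd_loc) || !is.finite(sd_disp) || sd_loc == 0 || sd_disp == 0)
    stop("degenerate permutation null (zero or non-finite standard deviation)")
  (obs_loc - mean(null_loc)) / sd_loc + (obs_disp$F - mean(null_disp)) / sd_disp
}

permanova_f_binary <- function(D2, code) {
  n <- nrow(D2)
  parts <- .permanova_parts_cpp(D2, code, 2L)
  den <- parts$SS_W / (n - 2)
  if (den <= 0) Inf else parts$SS_A / den
}

# coerce a list of label vectors (or a 0/1 matrix) to an integer matrix with
# one permutation per row, consistent with the level coding of y
as_perm_matrix <- function(perm_labels, y) {
  if (is.matrix(perm_labels)) return(matrix(as.integer(perm_labels), nrow(perm_labels)))
  lev <- levels(as_group_labels(y, min_per_class = 1L))
  P <- vapply(perm_labels, function(p) {
    p <- factor(as.character(p), levels = lev)
    if (anyNA(p)) stop("permuted labels contain classes absent from y")
    as.integer(p) - 1L
  }, integer(length(perm_labels[[1L]])))
  t(P)
}

#' Test for between-group dispersion effects
#'
#' Permutation test of the PERMDISP F statistic with `k` free permutations;
#' the p-value uses the add-one Monte-Carlo estimator (`p >= 1 / (k + 1)`).
#' Used by [selection_energy()] to decide between the plain energy-partition
#' F and the scaled combined-F statistic.
#'
#' @inheritParams permdisp_f
#' @param k number of permutations, at least 99.
#' @param alpha_level significance level for the detection call.
#' @param seed optional RNG seed for the permutations.
#' @return logical; the p-value and observed F are attached as attributes.
#' @export
dispersion_detected <- function(Zp, y, k = 99L, alpha_level = 0.05, seed = NULL) {
  if (k < 99L) stop("k must be at least 99")
  Zp <- as.matrix(Zp)
  code <- binary_codes(y)
  obs <- .permdisp_f_cpp(Zp, code, 2L, 1e-8, 1000L)
  if (!obs$converged) stop("Weiszfeld iteration failed to converge")
  # null arrangements are drawn from the sorted class-count template so that,
  # under a fixed seed, every labeling with the same class counts is tested
  # against one identical arrangement set; inside the selection-embedded
  # permutation test this keeps the label -> statistic map a single function
  # of the label/data pairing, which exactness requires
  P <- with_seed(seed, t(replicate(k, sample(sort(code)))))
  null <- .permdisp_f_null_cpp(Zp, P, 2L, 1e-8, 1000L)
  p <- (1 + sum(null > obs$F)) / (k + 1)
  structure(p <= alpha_level, p_value = p, F_obs = obs$F, k = k)
}

#' ANOSIM R statistic
#'
#' Rank-based separation measure: all `M = n(n-1)/2` inter-sample distances
#' are ranked (average ranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)`,
#' bounded in `[-1, 1]`.
#'
#' @inheritParams disco_f
#' @return an `association_stat`.
#' @export
anosim_r <- function(D, y) {
  D <- as_distance_matrix(D)
  y <- as_group_labels(y, min_per_class = 1L)
  n <- nrow(D)
  lower <- lower.tri(D)
  r <- rank(D[lower])
  between <- (as.integer(y)[row(D)[lower]] != as.integer(y)[col(D)[lower]])
  M <- n * (n - 1) / 2
  value <- (mean(r[between]) - mean(r[!between])) / (M / 2)
  new_association_stat("anosimR", value, list())
}
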