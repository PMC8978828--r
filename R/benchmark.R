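#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' summary of a reject/accept confusion matrix over true-case and null-case
#' datasets.  Defined as 0 when any marginal factor is 0 (the expression is
#' otherwise indeterminate).
#'
#' @param tp,tn,fp,fn confusion counts, or pass a single list/vector with
#'   named elements via `tp`.
#' @return a number in `[-1, 1]`.
#' @examples
#' mcc(100, 100, 0, 0)   # 1
#' mcc(90, 95, 5, 10)    # ~0.8511
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn)) {
    x <- as.list(tp)
    tp <- x$TP %||% x$tp; tn <- x$TN %||% x$tn
    fp <- x$FP %||% x$fp; fn <- x$FN %||% x$fn
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (anyNA(counts) || any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("at least one nonzero margin required")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature-selection quality metrics for a signature
#'
#' Signature size (model-complexity proxy), the global clustering coefficient
#' of its logratio network (redundancy proxy: any closed triangle means a
#' linearly dependent triple, and signatures built from a spanning tree score
#' exactly 0), and the scaled combined-F of the signature sub-frame (strength
#' of the captured association).
#'
#' @param result a [selection_energy()] result with a nonempty signature.
#' @param Zfull the full [pairwise_logratios()] frame the selection ran on.
#' @param y the group labels.
#' @param perm_labels permutation set for the combined-F scaling (list of
#'   label vectors or 0/1 matrix, >= 30 rows); reuse one set across methods
#'   for comparability.
#' @return list with `size`, `clustering_coefficient`, `cF`.
#' @export
feature_selection_metrics <- function(result, Zfull, y, perm_labels) {
  stopifnot(inherits(result, "selenergy_selection"), nrow(result$signature) > 0)
  Zp <- plr_subset(Zfull, result$signature)
  list(size = nrow(result$signature),
       clustering_coefficient = global_clustering_coefficient(result$signature),
       cF = scaled_combined_f(Zp, y, perm_labels)$value)
}

#' Detection benchmark: power, type I error, and MCC per method
#'
#' For each replicate dataset a true-case and a null-case variant are drawn
#' from a scenario generator, and every method tests the group association at
#' `alpha_level` using one shared set of `k_perms` permuted label vectors per
#' dataset (so significance is computed consistently across methods).  The
#' comparator tests (PERMANOVA, ANOSIM, energy, and PERMDISP as a
#' dispersion indicator) run on Euclidean distances over the full pairwise
#' logratio frame; `selenergyperm` reruns the full selection pipeline per
#' permutation.  Rejections are tallied into TP/FP/TN/FN and summarized as
#' power (true-case rejection rate), type I error (null-case rejection rate),
#' and [mcc()].
#'
#' @param scenario scenario id passed to [simulate_synthetic()] (`"syn1"` ...
#'   `"syn5"`), or a function `(case, seed)` returning a `simulated_dataset`.
#' @param d taxa count for the synthetic scenarios.
#' @param methods subset of `c("selenergyperm", "permanova", "anosim",
#'   "energy", "permdisp2")`.
#' @param n_datasets replicate datasets per case (desk-scale default 25; the
#'   full-scale design uses 100).
#' @param k_perms shared permutations per dataset (desk-scale default 99;
#'   full scale 150).
#' @param alpha_level rejection level.
#' @param design `"balanced"` (40/40) or `"unbalanced"` (20/60).
#' @param seed master seed; datasets and permutations derive from it, so
#'   results are reproducible bit-for-bit.
#' @param cfg [selection_config()] for the selection runs; its `scaling_m` is
#'   ignored in favour of the shared permutation set.
#' @param signature_metrics also record mean signature size, clustering
#'   coefficient, and scaled combined-F of the true-case selection runs.
#' @return data.frame with one row per method: confusion counts, power,
#'   type I error, MCC, and (for selenergyperm) signature metrics.
#' @export
run_detection_benchmark <- function(scenario, d = 50L,
                                    methods = c("selenergyperm", "permanova",
                                                "anosim", "energy", "permdisp2"),
                                    n_datasets = 25L, k_perms = 99L,
                                    alpha_level = 0.05,
                                    design = c("balanced", "unbalanced"),
                                    seed = 1L, cfg = NULL,
                                    signature_metrics = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  design <- match.arg(design)
  n1 <- if (design == "balanced") 40L else 20L
  n2 <- if (design == "balanced") 40L else 60L
  gen <- if (is.function(scenario)) scenario else {
    scen <- scenario
    function(case, s) simulate_synthetic(scen, d = d, n1 = n1, n2 = n2,
                                         case = case, seed = s)
  }
  scen_label <- if (is.function(scenario)) "custom" else scenario

  reject <- matrix(0L, length(methods), 2,
                   dimnames = list(methods, c("true", "null")))
  evaluated <- reject
  sig_size <- sig_cc <- sig_cf <- numeric(0)

  for (i in seq_len(n_datasets)) {
    for (case in c("true", "null")) {
      ds_seed <- child_seed(seed, 2L * i + (case == "null"))
      sim <- gen(case, ds_seed)
      y <- sim$labels
      R <- preprocess_to_composition(sim$data)
      Z <- pairwise_logratios(R)
      scheme <- permutation_scheme("free", k = k_perms,
                                   seed = child_seed(ds_seed, 999L))
      perms <- generate_permutations(y, scheme)
      P <- as_perm_matrix(perms, y)
      D <- euclidean_distances(Z)
      D2 <- unclass(D)^2
      code <- binary_codes(y)

      for (mth in methods) {
        res <- tryCatch({
          if (mth == "selenergyperm") {
            cfg_i <- cfg %||% selection_config()
            cfg_i$seed <- child_seed(ds_seed, 7L)
            forced <- switch(cfg_i$statistic_mode, auto = NULL,
                             force_discoF = "discoF", force_cF = "cF")
            obs <- selection_core(Z, y, cfg_i, forced_kind = forced,
                                  perm_matrix = P)
            nulls <- vapply(perms, function(pl)
              selection_core(Z, pl, cfg_i, forced_kind = forced,
                             perm_matrix = P)$statistic_value, numeric(1))
            p <- (1 + sum(nulls > obs$statistic_value)) / (length(nulls) + 1)
            if (signature_metrics && case == "true") {
              fm <- feature_selection_metrics(obs, Z, y, P)
              sig_size <- c(sig_size, fm$size)
              sig_cc <- c(sig_cc, fm$clustering_coefficient)
              sig_cf <- c(sig_cf, fm$cF)
            }
            p
          } else if (mth == "permanova") {
            obs <- permanova_f_binary(D2, code)
            nulls <- .permanova_f_null_cpp(D2, P, 2L)
            (1 + sum(nulls > obs)) / (nrow(P) + 1)
          } else if (mth == "anosim") {
            obs <- anosim_r(D, y)$value
            nulls <- vapply(perms, function(pl) anosim_r(D, pl)$value, numeric(1))
            (1 + sum(nulls > obs)) / (nrow(P) + 1)
          } else if (mth == "energy") {
            obs <- .energy_stat_cpp(unclass(D), code)
            nulls <- apply(P, 1L, function(g) .energy_stat_cpp(unclass(D), g))
            (1 + sum(nulls > obs)) / (nrow(P) + 1)
          } else {  # permdisp2 dispersion indicator
            Zm <- unclass(Z)
            obs <- .permdisp_f_cpp(Zm, code, 2L, 1e-8, 1000L)$F
            nulls <- .permdisp_f_null_cpp(Zm, P, 2L, 1e-8, 1000L)
            (1 + sum(nulls > obs)) / (nrow(P) + 1)
          }
        }, error = function(e) {
          warning("method ", mth, " failed on dataset ", i, " (", case,
                  " case): ", conditionMessage(e))
          NA_real_
        })
        if (!is.na(res)) {
          evaluated[mth, case] <- evaluated[mth, case] + 1L
          if (res <= alpha_level) reject[mth, case] <- reject[mth, case] + 1L
        }
      }
    }
  }

  out <- data.frame(
    scenario = scen_label, d = d, design = design, method = methods,
    n_datasets = n_datasets, k_perms = k_perms,
    TP = reject[, "true"], FN = evaluated[, "true"] - reject[, "true"],
    FP = reject[, "null"], TN = evaluated[, "null"] - reject[, "null"],
    stringsAsFactors = FALSE, row.names = NULL)
  out$power <- ifelse(evaluated[, "true"] > 0, out$TP / evaluated[, "true"], NA)
  out$type_I <- ifelse(evaluated[, "null"] > 0, out$FP / evaluated[, "null"], NA)
  out$MCC <- vapply(seq_len(nrow(out)), function(r)
    mcc(out$TP[r], out$TN[r], out$FP[r], out$FN[r]), numeric(1))
  if ("selenergyperm" %in% methods && length(sig_size)) {
    is_sep <- out$method == "selenergyperm"
    out$mean_signature_size <- ifelse(is_sep, mean(sig_size), NA)
    out$mean_clustering_coefficient <- ifelse(is_sep, mean(sig_cc), NA)
    out$mean_cF <- ifelse(is_sep, mean(sig_cf), NA)
  }
  out
}
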