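#' Permutation scheme for significance testing
#'
#' @param mode `"free"` (uniform relabelings preserving class counts),
#'   `"within_strata"` (labels shuffled independently inside each stratum), or
#'   `"block"` (whole blocks, e.g. hosts with repeated samples, exchange their
#'   block-level labels; every block must carry a single class).
#' @param k number of permutations (>= 1; >= 99 recommended for testing).
#' @param strata length-n stratum or block labels; required unless `mode` is
#'   `"free"`.
#' @param seed optional RNG seed making the permutation list reproducible.
#' @return a `permutation_scheme` list.
#' @export
permutation_scheme <- function(mode = c("free", "within_strata", "block"),
                               k = 999L, strata = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  if (mode != "free" && is.null(strata))
    stop("mode '", mode, "' requires strata/block labels")
  structure(list(mode = mode, k = as.integer(k), strata = strata, seed = seed),
            class = "permutation_scheme")
}

#' Generate permuted label vectors
#'
#' @param y group labels.
#' @param scheme a [permutation_scheme()].
#' @return list of `k` label vectors, each a permutation of `y` under the
#'   scheme's restrictions.
#' @export
generate_permutations <- function(y, scheme) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  y <- as.character(y)
  n <- length(y)
  if (!is.null(scheme$strata) && length(scheme$strata) != n)
    stop("strata must have one entry per sample")
  one <- switch(scheme$mode,
    free = function() sample(y),
    within_strata = {
      idx <- split(seq_len(n), scheme$strata)
      function() {
        out <- y
        for (ix in idx) out[ix] <- y[sample(ix)]
        out
      }
    },
    block = {
      blocks <- as.character(scheme$strata)
      ub <- unique(blocks)
      block_label <- vapply(ub, function(b) {
        lab <- unique(y[blocks == b])
        if (length(lab) != 1L)
          stop("block '", b, "' carries more than one class label")
        lab
      }, character(1))
      function() {
        newlab <- setNames(sample(block_label), ub)
        unname(newlab[blocks])
      }
    })
  with_seed(scheme$seed, replicate(scheme$k, one(), simplify = FALSE))
}

#' Selection-embedded permutation association test
#'
#' Runs the full selection pipeline ([selection_energy()]) on the observed
#' labels to obtain `F_obs`, then reruns the identical pipeline (DCV scoring,
#' spanning tree, dispersion detection, greedy search) on every permuted
#' label vector to sample the null distribution of the post-selection
#' statistic.  In `auto` mode each replicate re-decides its statistic kind
#' (energy-partition F or scaled combined-F) from its own labels with shared
#' detection/scaling permutation sets, so observed and null values are the
#' same deterministic function of the label vector — the property that makes
#' the permutation p-value exact under exchangeability.  The one-sided
#' Monte-Carlo p-value is `(1 + #\{F_null > F_obs\}) / (k + 1)`; ties count
#' as non-exceedances.
#'
#' @param M a [count_table()] (preprocessed with `prevalence` filtering,
#'   closure and multiplicative zero replacement internally) or an
#'   already-compositional matrix (rows summing to 1).
#' @param y two-class labels, one per sample.
#' @param scheme a [permutation_scheme()]; `k >= 99` recommended.
#' @param cfg a [selection_config()].
#' @param prevalence prevalence threshold applied when `M` is a count table.
#' @return an object of class `selenergy_test`: list with `F_obs`,
#'   `statistic_kind`, `null_values` (length `k`, minus any failed replicates,
#'   reported with a warning), `p_value`, `selection` (the observed
#'   [selection_energy()] result), `signature`, and a settings echo.
#' @examples
#' sim <- simulate_synthetic("syn2", d = 12, n1 = 10, n2 = 10, case = "true", seed = 2)
#' res <- sel_energy_perm_test(sim$data, sim$labels,
#'                             permutation_scheme("free", k = 99, seed = 3),
#'                             selection_config(seed = 3))
#' res$p_value
#' @export
sel_energy_perm_test <- function(M, y, scheme = permutation_scheme(),
                                 cfg = selection_config(), prevalence = 0.10) {
  R <- preprocess_to_composition(M, prevalence)
  y <- as_group_labels(y)
  if (length(y) != nrow(R)) stop("length(y) must equal the number of samples")
  Z <- pairwise_logratios(R)

  # One shared scaling permutation set keeps the combined-F scaling
  # comparable across the observed run and every replicate.
  code <- binary_codes(y)
  perm_matrix <- with_seed(child_seed(cfg$seed, 2L),
                           t(replicate(cfg$scaling_m, sample(sort(code)))))
  obs <- selection_core(Z, y, cfg, perm_matrix = perm_matrix)
  kind <- obs$statistic_kind

  # Every replicate applies the identical label -> statistic map as the
  # observed run: in auto mode that includes re-deciding the statistic kind
  # from the replicate's own labels (with the same detection-permutation
  # seed), which keeps the permutation test exact under exchangeability.
  # Forcing the observed kind onto the replicates would condition on a
  # label-dependent choice and inflate type I error.
  forced <- switch(cfg$statistic_mode, auto = NULL,
                   force_discoF = "discoF", force_cF = "cF")
  perms <- generate_permutations(y, scheme)
  null_runs <- lapply(seq_along(perms), function(i) {
    tryCatch({
      r <- selection_core(Z, perms[[i]], cfg, forced_kind = forced,
                          perm_matrix = perm_matrix)
      c(r$statistic_value, r$statistic_kind == "cF")
    },
    error = function(e) {
      warning("permutation replicate ", i, " failed and was excluded: ",
              conditionMessage(e))
      c(NA_real_, NA)
    })
  })
  null_values <- vapply(null_runs, `[`, numeric(1), 1L)
  null_cf <- vapply(null_runs, `[`, numeric(1), 2L)
  failed <- sum(is.na(null_values))
  null_cf <- null_cf[!is.na(null_values)]
  null_values <- null_values[!is.na(null_values)]
  k_eff <- length(null_values)
  if (k_eff == 0L) stop("all permutation replicates failed")
  p <- (1 + sum(null_values > obs$statistic_value)) / (k_eff + 1)

  structure(list(F_obs = obs$statistic_value,
                 statistic_kind = kind,
                 null_values = null_values,
                 null_cf_fraction = mean(null_cf),
                 p_value = p,
                 k = k_eff,
                 k_requested = scheme$k,
                 failed_replicates = failed,
                 selection = obs,
                 signature = obs$signature,
                 settings = list(scheme = scheme[c("mode", "k", "seed")],
                                 config = unclass(cfg),
                                 prevalence = prevalence)),
            class = "selenergy_test")
}

# counts -> filtered, closed, zero-imputed composition; compositional input
# passes through (with zero imputation if needed)
preprocess_to_composition <- function(M, prevalence = 0.10) {
  if (inherits(M, "composition")) return(multiplicative_replacement(M))
  m <- as.matrix(M)
  if (is_composition_like(m)) return(multiplicative_replacement(as_composition(m)))
  tab <- prevalence_filter(count_table(m), prevalence)
  multiplicative_replacement(closure(tab))
}

#' @export
print.selenergy_test <- function(x, ...) {
  cat("selenergy_test: ", x$statistic_kind, " = ", signif(x$F_obs, 6),
      ", p = ", signif(x$p_value, 4), " (k = ", x$k, ")\n",
      "signature: ", nrow(x$signature), " logratio(s)\n", sep = "")
  invisible(x)
}
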