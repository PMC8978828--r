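# shared fixture builders (everything generated in code, no files)

random_count_table <- function(n = 20, d = 30, seed = 1, lambda = 5,
                               zero_frac = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * d, lambda), n, d)
    m[matrix(runif(n * d) < zero_frac, n, d)] <- 0L
    m[rowSums(m) == 0, 1] <- 1L  # keep every sample nonempty
    count_table(m)
  })
}

random_composition <- function(n = 15, d = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * d, shape = 2), n, d)
    as_composition(m / rowSums(m))
  })
}

# a small two-class logratio-like frame built from raw gaussians
random_frame <- function(n = 20, p = 6, seed = 1) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    d <- ceiling((1 + sqrt(1 + 8 * p)) / 2)
    pairs <- t(combn(d, 2))[seq_len(p), , drop = FALSE]
    ratios <- data.frame(num = paste0("t", pairs[, 2]), den = paste0("t", pairs[, 1]))
    selenergy:::new_logratio_frame(Z, ratios, paste0("s", seq_len(n)))
  })
}

two_class_labels <- function(n1, n2) rep(c("c1", "c2"), c(n1, n2))

# dcv_scores object with prescribed per-ratio scores over all pairs of taxa
scores_fixture <- function(score_by_ratio) {
  ratios <- selenergy:::ratio_table_from_names(names(score_by_ratio))
  structure(list(scores = score_by_ratio,
                 standardized = NULL, components = NULL, ratios = ratios),
            class = "dcv_scores")
}

all_pairs_scores <- function(taxa, scores) {
  pairs <- t(combn(taxa, 2))
  nm <- paste0(pairs[, 2], "/", pairs[, 1])
  scores_fixture(setNames(scores, nm))
}
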