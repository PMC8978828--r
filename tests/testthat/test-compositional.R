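test_that("prevalence filter keeps exactly the taxa meeting the ceiling rule", {
  # boundary: present in 1 of 10 samples at threshold 0.10 -> retained
  m <- matrix(1L, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  m[, 2] <- 0L
  m[1, 2] <- 1L
  kept <- prevalence_filter(count_table(m), 0.10)
  expect_equal(colnames(kept), c("a", "b", "c"))

  # all-zero column always removed
  m[, 2] <- 0L
  kept <- prevalence_filter(count_table(m), 0.01)
  expect_equal(colnames(kept), c("a", "c"))

  # random table vs independent per-column scan oracle
  tab <- random_count_table(n = 20, d = 30, seed = 7)
  kept <- prevalence_filter(tab, 0.15)
  oracle <- colnames(tab)[vapply(seq_len(ncol(tab)),
                                 function(j) sum(tab[, j] > 0) >= ceiling(0.15 * 20),
                                 logical(1))]
  expect_identical(colnames(kept), oracle)
  expect_identical(rownames(kept), rownames(tab))

  # hard error naming the threshold when < 2 taxa survive
  sparse <- count_table(rbind(c(5L, 0L, 0L), c(4L, 1L, 1L), c(6L, 0L, 0L),
                              c(3L, 0L, 0L), c(2L, 0L, 0L)))
  expect_error(prevalence_filter(sparse, 0.9), "90")
})

test_that("closure normalizes rows and is idempotent", {
  expect_equal(unclass(closure(matrix(c(1, 1, 2), 1, 3)))[1, ],
               c(0.25, 0.25, 0.50), ignore_attr = TRUE)
  comp <- random_composition(10, 5, seed = 2)
  expect_equal(unclass(closure(comp)), unclass(comp), tolerance = 1e-12,
               ignore_attr = TRUE)

  tab <- random_count_table(12, 9, seed = 3)
  expect_true(all(abs(rowSums(closure(tab)) - 1) < 1e-12))

  m <- rbind(sA = c(1, 2), sB = c(0, 0))
  expect_error(closure(m), "sB")
})

test_that("multiplicative zero replacement follows the global-delta rule", {
  # delta = smallest nonzero value across the matrix = 0.1 here
  comp <- as_composition(rbind(c(0.5, 0.5, 0.0), c(0.4, 0.5, 0.1)))
  rep1 <- multiplicative_replacement(comp)
  expect_equal(unclass(rep1)[1, ], c(0.45, 0.45, 0.10), ignore_attr = TRUE)
  expect_equal(unclass(rep1)[2, ], c(0.4, 0.5, 0.1), ignore_attr = TRUE)

  # no zeros -> identity
  comp2 <- random_composition(6, 4, seed = 5)
  expect_identical(unclass(multiplicative_replacement(comp2)), unclass(comp2))

  # unit sums exact, strictly positive, within-row nonzero ratios preserved
  tab <- random_count_table(15, 12, seed = 8, zero_frac = 0.4)
  comp3 <- closure(tab)
  rep3 <- multiplicative_replacement(comp3)
  expect_true(all(rep3 > 0))
  expect_true(all(abs(rowSums(rep3) - 1) < 1e-12))
  i <- which(rowSums(comp3 == 0) > 0)[1]
  nz <- which(comp3[i, ] > 0)
  expect_equal(rep3[i, nz[1]] / rep3[i, nz[2]], comp3[i, nz[1]] / comp3[i, nz[2]],
               tolerance = 1e-12)
})

test_that("pairwise logratio frame has the right shape, order, and signs", {
  comp <- random_composition(4, 2, seed = 1)
  Z <- pairwise_logratios(comp)
  expect_equal(ncol(Z), 1L)
  expect_equal(Z[, 1], log(comp[, 2] / comp[, 1]), ignore_attr = TRUE)

  comp <- random_composition(5, 6, seed = 2)
  Z <- pairwise_logratios(comp)
  expect_equal(ncol(Z), choose(6, 2))
  # lower-off-diagonal enumeration: (2,1), (3,1), ..., then (3,2), ...
  expect_equal(colnames(Z)[1:5], paste0("taxon_", 2:6, "/taxon_1"))
  # every column is log(num) - log(den)
  rt <- attr(Z, "ratios")
  for (j in seq_len(ncol(Z))) {
    expect_equal(Z[, j], log(comp[, rt$num[j]]) - log(comp[, rt$den[j]]),
                 ignore_attr = TRUE)
  }
  # column counts match the closed form across d, including printed values
  for (d in c(2, 5, 50, 57)) {
    cc <- random_composition(2, d, seed = d)
    expect_equal(ncol(pairwise_logratios(cc)), d * (d - 1) / 2)
  }
  comp0 <- as_composition(rbind(c(0.5, 0.5, 0)))
  expect_error(pairwise_logratios(comp0), "positive")
})

test_that("plr_subset is order-stable, lossless, and handles reversed ratios", {
  comp <- random_composition(7, 5, seed = 3)
  Z <- pairwise_logratios(comp)
  pick <- c("taxon_4/taxon_2", "taxon_2/taxon_1", "taxon_5/taxon_3")
  sub <- plr_subset(Z, pick)
  expect_identical(colnames(sub), pick)
  expect_equal(unclass(sub), unclass(Z)[, pick], ignore_attr = TRUE)

  # antisymmetry: a reversed request returns the negated column
  rev <- plr_subset(Z, "taxon_1/taxon_2")
  expect_equal(rev[, 1], -Z[, "taxon_2/taxon_1"], ignore_attr = TRUE)

  expect_error(plr_subset(Z, "taxon_9/taxon_1"), "not present")
})

test_that("alr and inverse_alr round trip", {
  expect_equal(unclass(inverse_alr(matrix(0, 1, 2)))[1, ], rep(1 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(unclass(inverse_alr(matrix(log(2), 1, 1)))[1, ], c(2 / 3, 1 / 3),
               ignore_attr = TRUE)
  S <- matrix(rnorm(12), 3, 4)
  expect_equal(unclass(alr(inverse_alr(S))), S, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("count table validation catches malformed input", {
  expect_error(count_table(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
  expect_error(count_table(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
  expect_error(count_table(matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE)), "all-zero")
  expect_error(count_table(matrix(1:2, 2, 1)), "2 taxa")
})
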