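# independent R oracles for the five DCV components
oracle_components <- function(x, y) {
  g1 <- x[y == "c1"]; g2 <- x[y == "c2"]
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  guard <- function(num, den) if (num == 0) 0 else num / max(den, 1e-12)
  m1 <- mean(g1); m2 <- mean(g2); m <- mean(x)
  v1 <- var(g1); v2 <- var(g2)
  welch <- guard(abs(m1 - m2), sqrt(v1 / n1 + v2 / n2))
  meanf <- guard(n1 * (m1 - m)^2 + n2 * (m2 - m)^2, v1 + v2)
  b1 <- abs(g1 - median(g1)); b2 <- abs(g2 - median(g2))
  bb <- mean(c(b1, b2))
  bf <- guard(n1 * (mean(b1) - bb)^2 + n2 * (mean(b2) - bb)^2,
              (sum((b1 - mean(b1))^2) + sum((b2 - mean(b2))^2)) / (n - 2))
  # brute-force ECDF sup over all observed thresholds
  ks <- max(vapply(c(g1, g2), function(t) abs(mean(g1 <= t) - mean(g2 <= t)),
                   numeric(1)))
  c(welch = welch, meanf = meanf, bf = bf, ks = ks)
}

test_that("DCV components match hand values and brute-force oracles", {
  Z <- selenergy:::new_logratio_frame(
    cbind(c(0, 2, 3, 5)), data.frame(num = "b", den = "a"), paste0("s", 1:4))
  y <- two_class_labels(2, 2)
  V <- dcv_components(Z, y)
  expect_equal(unname(V[1, "welch_t"]), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(V[1, "ks_d"]), 1)

  Z2 <- selenergy:::new_logratio_frame(
    cbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
    data.frame(num = c("b", "c"), den = c("a", "a")), paste0("s", 1:4))
  V2 <- dcv_components(Z2, y)
  expect_equal(unname(V2[, "ks_d"]), c(1, 0.5))

  # random frames vs the independent oracle, all four closed-form components
  for (seed in 1:3) {
    Zr <- random_frame(n = 24, p = 10, seed = seed)
    yr <- two_class_labels(10, 14)
    Vr <- dcv_components(Zr, yr)
    for (j in seq_len(ncol(Zr))) {
      o <- oracle_components(Zr[, j], yr)
      expect_equal(unname(Vr[j, 1:4]), unname(o), tolerance = 1e-10)
    }
  }
})

test_that("a constant logratio scores zero on every component", {
  Z <- selenergy:::new_logratio_frame(
    cbind(rep(1.7, 10), rnorm(10)),
    data.frame(num = c("b", "c"), den = c("a", "a")), paste0("s", 1:10))
  V <- dcv_components(Z, two_class_labels(5, 5))
  expect_equal(unname(V[1, ]), rep(0, 5))
})

test_that("information gain is sane on separable and null data", {
  # perfectly separated classes: IG equals the full class entropy (in nats)
  x <- c(1:10, 101:110)
  y <- two_class_labels(10, 10)
  Z <- selenergy:::new_logratio_frame(cbind(x), data.frame(num = "b", den = "a"))
  V <- dcv_components(Z, y)
  expect_equal(unname(V[1, "info_gain"]), log(2), tolerance = 1e-10)

  # label-independent feature: IG stays small (median-split fallback bound)
  withr::with_seed(4, {
    xr <- rnorm(60)
    Zr <- selenergy:::new_logratio_frame(cbind(xr), data.frame(num = "b", den = "a"))
    Vr <- dcv_components(Zr, two_class_labels(30, 30))
    expect_gte(unname(Vr[1, "info_gain"]), 0)
    expect_lt(unname(Vr[1, "info_gain"]), 0.15)
  })
})

test_that("dcv_scores standardizes columns and aggregates row sums", {
  withr::with_seed(11, V <- matrix(rexp(500), 100, 5))
  rownames(V) <- paste0("t", rep(2:101), "/t", 1)
  colnames(V) <- c("welch_t", "mean_f", "bf_f", "ks_d", "info_gain")
  sc <- dcv_scores(V)
  oracle <- rowSums(apply(V, 2, function(col) (col - mean(col)) / sd(col)))
  expect_lt(max(abs(sc$scores - oracle)), 1e-10)
  expect_equal(unname(colMeans(sc$standardized)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sc$standardized, 2, sd)), rep(1, 5), tolerance = 1e-12)

  # constant component column contributes 0 to every score
  V2 <- V; V2[, 3] <- 4.2
  sc2 <- dcv_scores(V2)
  expect_true(all(sc2$standardized[, 3] == 0))

  # identical component rows give equal scores
  V3 <- V; V3[2, ] <- V3[1, ]
  sc3 <- dcv_scores(V3)
  expect_equal(sc3$scores[[1]], sc3$scores[[2]])

  # p = 1 degenerates with a warning
  expect_warning(sc1 <- dcv_scores(V[1, , drop = FALSE]), "one logratio")
  expect_equal(unname(sc1$scores), 0)
})

test_that("DCV scores are orientation- and label-swap invariant", {
  Z <- pairwise_logratios(random_composition(30, 6, seed = 9))
  y <- two_class_labels(14, 16)
  base <- dcv_scores(Z, y)

  flipped <- unclass(Z)
  flipped[, 3] <- -flipped[, 3]
  Zf <- selenergy:::new_logratio_frame(flipped, attr(Z, "ratios"), rownames(Z))
  expect_equal(dcv_scores(Zf, y)$scores, base$scores, tolerance = 1e-10)

  yswap <- ifelse(y == "c1", "c2", "c1")
  expect_equal(dcv_components(Z, yswap), dcv_components(Z, y), tolerance = 1e-12)

  # component range invariants
  V <- base$components
  expect_true(all(V[, c("mean_f", "bf_f", "info_gain")] >= 0))
  expect_true(all(V[, "ks_d"] >= 0 & V[, "ks_d"] <= 1))
})
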