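test_that("euclidean distances match a double-loop oracle", {
  Z <- matrix(c(0, 3), 2, 1)
  D <- euclidean_distances(Z)
  expect_equal(D[1, 2], 3)
  Z2 <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(0, 0, 0, 0))
  D2 <- euclidean_distances(Z2)
  expect_equal(D2[1, 2], 0)
  withr::with_seed(2, Zr <- matrix(rnorm(40), 10, 4))
  Dr <- euclidean_distances(Zr)
  for (i in 1:10) for (j in 1:10)
    expect_equal(Dr[i, j], sqrt(sum((Zr[i, ] - Zr[j, ])^2)), tolerance = 1e-12)
})

test_that("discoF matches explicit double-sum oracle and conserves dispersion", {
  # 4 points in 1-D, groups {0,1} vs {10,11}, alpha = 1
  x <- c(0, 1, 10, 11)
  y <- two_class_labels(2, 2)
  D <- euclidean_distances(cbind(x))
  st <- disco_f(D, y, alpha = 1)
  mB <- mean(abs(outer(x[1:2], x[3:4], "-")))
  mW1 <- mean(abs(outer(x[1:2], x[1:2], "-")))
  mW2 <- mean(abs(outer(x[3:4], x[3:4], "-")))
  S <- (2 * 2 / (2 * 4)) * (2 * mB - mW1 - mW2)
  W <- (2 / 2) * mW1 + (2 / 2) * mW2  # sum over groups of (n_g / 2) * mean within
  expect_equal(st$parts$S, S, tolerance = 1e-12)
  expect_equal(st$parts$W, W, tolerance = 1e-12)
  expect_equal(st$value, S / (W / 2), tolerance = 1e-12)

  # conservation S + W = total over random instances and alphas
  withr::with_seed(8, {
    for (r in 1:100) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      Dr <- euclidean_distances(matrix(rnorm((n1 + n2) * 3), n1 + n2, 3))
      al <- runif(1, 0.2, 2)
      p <- disco_f(Dr, two_class_labels(n1, n2), al)$parts
      expect_equal(p$S + p$W, p$total, tolerance = 1e-10)
    }
  })

  # invariance to which class is called which
  y2 <- ifelse(y == "c1", "g2", "g1")
  expect_equal(disco_f(D, y2, 1)$value, st$value, tolerance = 1e-12)
})

test_that("energy statistic matches hand computation and is nonnegative", {
  D <- euclidean_distances(cbind(c(0, 1)))
  expect_equal(energy_statistic(D, c("a", "b"))$value, 1)
  D2 <- euclidean_distances(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1)))
  expect_equal(energy_statistic(D2, two_class_labels(2, 2))$value, 0)
  withr::with_seed(4, {
    for (r in 1:20) {
      Dr <- euclidean_distances(matrix(rnorm(24), 8, 3))
      expect_gte(energy_statistic(Dr, two_class_labels(4, 4))$value, -1e-12)
    }
  })
})

test_that("PERMANOVA F matches the hand-computed toy and vegan", {
  x <- c(0, 1, 10, 11)
  y <- two_class_labels(2, 2)
  st <- permanova_f(euclidean_distances(cbind(x)), y)
  expect_equal(st$parts$SS_T, 101)
  expect_equal(st$parts$SS_W, 1)
  expect_equal(st$parts$SS_A, 100)
  expect_equal(st$value, 200)

  withr::with_seed(6, {
    Zr <- matrix(rnorm(60), 15, 4)
    yr <- two_class_labels(7, 8)
    Dr <- euclidean_distances(Zr)
    st <- permanova_f(Dr, yr)
    expect_equal(st$parts$SS_A + st$parts$SS_W, st$parts$SS_T, tolerance = 1e-10)
    # vegan oracle
    df <- data.frame(y = yr)
    ad <- vegan::adonis2(dist(Zr) ~ y, data = df, permutations = 0)
    expect_equal(st$value, ad$F[1], tolerance = 1e-8)

    # permutation distribution of F has mean ~ 1 on exchangeable data
    code <- selenergy:::binary_codes(yr)
    P <- t(replicate(3000, sample(code)))
    nulls <- selenergy:::.permanova_f_null_cpp(unclass(Dr)^2, P, 2L)
    expect_equal(mean(nulls), 1, tolerance = 0.05)
  })
})

test_that("PERMDISP F agrees with vegan::betadisper and detects spread", {
  withr::with_seed(9, {
    Zr <- matrix(rnorm(80), 20, 4)
    yr <- two_class_labels(10, 10)
    mine <- permdisp_f(Zr, yr)
    bd <- vegan::betadisper(dist(Zr), yr, type = "median")
    van <- anova(bd)$`F value`[1]
    expect_equal(mine$value, van, tolerance = 1e-4)

    # spatial median of a symmetric point set is the center of symmetry
    pts <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
    expect_equal(unname(spatial_median(pts)), c(0, 0), tolerance = 1e-6)

    # 10x spread difference -> strongly significant dispersion
    Zs <- rbind(matrix(rnorm(40 * 3, sd = 1), 40, 3),
                matrix(rnorm(40 * 3, sd = 10), 40, 3))
    det <- dispersion_detected(Zs, two_class_labels(40, 40), k = 99, seed = 1)
    expect_true(det)
    expect_lte(attr(det, "p_value"), 0.05)
    # permutation p floor at k = 99
    expect_gte(attr(det, "p_value"), 1 / 100)
  })
})

test_that("combined-F parts recombine and respond to the right effects", {
  withr::with_seed(10, {
    # pure location shift: cF dominated by F_location
    Zloc <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, mean = 3), 20, 3))
    y <- two_class_labels(20, 20)
    st <- combined_f(Zloc, y)
    expect_equal(st$value, st$parts$F_location + st$parts$F_dispersion)
    expect_gt(st$parts$F_location, 10 * st$parts$F_dispersion)

    # pure dispersion difference: dominated by F_dispersion
    Zdisp <- rbind(matrix(rnorm(60, sd = 1), 20, 3),
                   matrix(rnorm(60, sd = 6), 20, 3))
    st2 <- combined_f(Zdisp, y)
    expect_gt(st2$parts$F_dispersion, 10 * st2$parts$F_location)
    expect_gte(st2$value, 0)
  })
})

test_that("scaled combined-F z-scores against the permutation null", {
  withr::with_seed(12, {
    Z <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, mean = 2, sd = 3), 20, 3))
    y <- two_class_labels(20, 20)
    code <- selenergy:::binary_codes(y)
    P <- t(replicate(80, sample(code)))
    st <- scaled_combined_f(Z, y, P)
    expect_equal(st$value, st$parts$F_hat_location + st$parts$F_hat_dispersion)
    # strong two-sided signal clears the entire null
    nulls_loc <- selenergy:::.permanova_f_null_cpp(unclass(euclidean_distances(Z))^2, P, 2L)
    expect_gt(st$parts$F_location, max(nulls_loc))
    expect_gt(st$value, 5)
    # identical permutation set -> identical value (determinism contract)
    expect_identical(scaled_combined_f(Z, y, P)$value, st$value)
    # fast greedy-path evaluator agrees with the reference
    fast <- selenergy:::scaled_cf_fast(unclass(euclidean_distances(Z))^2, Z, code, P)
    expect_equal(fast, st$value, tolerance = 1e-8)
    expect_error(scaled_combined_f(Z, y, P[1:10, ]), "at least 30")
    # degenerate null: constant coordinates
    Zc <- matrix(1, 40, 2)
    expect_error(scaled_combined_f(Zc, y, P), "degenerate|converge")
  })
})

test_that("ANOSIM R matches vegan and hits its bounds", {
  # complete separation
  Zs <- rbind(matrix(0, 4, 2), matrix(10, 4, 2) + diag(4)[, 1:2])
  D <- euclidean_distances(Zs)
  y <- two_class_labels(4, 4)
  expect_equal(anosim_r(D, y)$value, 1, tolerance = 1e-12)

  withr::with_seed(14, {
    Zr <- matrix(rnorm(48), 12, 4)
    yr <- two_class_labels(6, 6)
    mine <- anosim_r(euclidean_distances(Zr), yr)$value
    van <- vegan::anosim(dist(Zr), yr, permutations = 0)$statistic
    expect_equal(mine, unname(van), tolerance = 1e-10)
    expect_true(mine >= -1 && mine <= 1)
    # expectation ~ 0 under label permutation
    r0 <- replicate(400, anosim_r(euclidean_distances(Zr), sample(yr))$value)
    expect_lt(abs(mean(r0)), 0.05)
  })
})

test_that("statistics are invariant to consistent sample reordering", {
  withr::with_seed(15, {
    Z <- matrix(rnorm(60), 15, 4)
    y <- two_class_labels(7, 8)
    perm <- sample(15)
    D <- euclidean_distances(Z)
    Dp <- euclidean_distances(Z[perm, ])
    expect_equal(disco_f(Dp, y[perm])$value, disco_f(D, y)$value, tolerance = 1e-10)
    expect_equal(permanova_f(Dp, y[perm])$value, permanova_f(D, y)$value, tolerance = 1e-10)
    expect_equal(anosim_r(Dp, y[perm])$value, anosim_r(D, y)$value, tolerance = 1e-10)
    expect_equal(permdisp_f(Z[perm, ], y[perm])$value, permdisp_f(Z, y)$value,
                 tolerance = 1e-6)
  })
})
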