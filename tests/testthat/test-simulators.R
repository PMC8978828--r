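test_that("inverse ALR behaves on hand cases and round-trips", {
  expect_equal(unclass(inverse_alr(matrix(0, 1, 2)))[1, ], rep(1/3, 3),
               ignore_attr = TRUE)
  expect_equal(unclass(inverse_alr(matrix(log(2), 1, 1)))[1, ], c(2/3, 1/3),
               ignore_attr = TRUE)
  withr::with_seed(1, S <- matrix(rnorm(30, sd = 2), 5, 6))
  expect_equal(unclass(alr(inverse_alr(S))), S, tolerance = 1e-10, ignore_attr = TRUE)
  # overflow guard: huge coordinates survive the exponentiation
  big <- inverse_alr(matrix(c(800, -800), 1, 2))
  expect_true(all(is.finite(big)) && abs(sum(big) - 1) < 1e-12)
})

test_that("NB library sizes match their moments and the Poisson limit", {
  x <- nb_library_sizes(s = 1, mu = 1e7, n = 10000, seed = 3)
  expect_equal(mean(x), 1e7, tolerance = 0.05)
  # s -> infinity behaves like Poisson: variance/mean -> 1
  xp <- nb_library_sizes(s = 1e6, mu = 1000, n = 20000, seed = 4)
  expect_equal(var(xp) / mean(xp), 1, tolerance = 0.1)
  expect_identical(nb_library_sizes(1, 1e7, 50, seed = 9),
                   nb_library_sizes(1, 1e7, 50, seed = 9))
})

test_that("synthetic scenarios honor their stated distributions", {
  # syn1 null: symmetric Dirichlet, per-taxon mean ~ 1/d
  sim <- simulate_synthetic("syn1", d = 50, n1 = 40, n2 = 40, case = "null", seed = 2)
  expect_s3_class(sim$data, "composition")
  expect_false(sim$truth)
  expect_equal(unname(colMeans(sim$data)), rep(0.02, 50), tolerance = 0.25)
  expect_true(all(abs(rowSums(sim$data) - 1) < 1e-9))

  # syn2 true: class-2 first-component abundance stochastically larger
  sim2 <- simulate_synthetic("syn2", d = 20, n1 = 25, n2 = 25, case = "true", seed = 5)
  expect_s3_class(sim2$data, "count_table")
  rel <- sim2$data[, 1] / rowSums(sim2$data)
  w <- wilcox.test(rel[sim2$labels == "c2"], rel[sim2$labels == "c1"],
                   alternative = "greater")
  expect_lt(w$p.value, 1e-6)

  # syn3 covariance template: tridiagonal 1 / 0.2 before shifts
  S <- selenergy:::banded_sigma(5)
  expect_equal(diag(S), rep(1, 5))
  expect_equal(S[cbind(1:4, 2:5)], rep(0.2, 4))
  expect_equal(S[1, 3], 0)

  # syn3/4/5: d taxa out, positive-definite class covariances, reproducible
  for (scen in c("syn3", "syn4", "syn5")) {
    s <- simulate_synthetic(scen, d = 12, n1 = 10, n2 = 10, case = "true", seed = 7)
    expect_equal(ncol(s$data), 12L)
    expect_true(all(s$data > 0))
    s2 <- simulate_synthetic(scen, d = 12, n1 = 10, n2 = 10, case = "true", seed = 7)
    expect_identical(unclass(s$data), unclass(s2$data))
  }

  # syn4 shifts exactly the first ALR coordinate by log(d)/3
  s4 <- simulate_synthetic("syn4", d = 12, n1 = 10, n2 = 10, case = "true", seed = 7)
  expect_equal(s4$provenance$mu2[1], log(12) / 3)
  expect_equal(s4$provenance$mu2[-1], rep(0, 10))
})

test_that("location-shift scenario recovers the planted mean shift", {
  ref <- zinb_reference_table(n = 120, d = 20, seed = 11)
  sim <- sim_location_shift(ref, P_frac = 0.25, factor = 1.25,
                            n1 = 2500, n2 = 2500, case = "true", seed = 12)
  prov <- sim$provenance
  nsh <- prov$n_shifted
  expect_equal(nsh, ceiling(0.25 * (prov$d - 1)))
  # Gaussian moment recovery: class-2 minus class-1 ALR means should match
  # (factor - 1) * mu on the shifted (ranked) coordinates; the norm of the
  # difference is invariant to the coordinate reordering applied on output
  A <- alr(sim$data)
  m1 <- colMeans(A[sim$labels == "c1", ])
  m2 <- colMeans(A[sim$labels == "c2", ])
  shift_expected <- prov$mu2 - prov$mu  # ranked space
  expect_gte(sum(abs(shift_expected) > 0), 1)
  expect_equal(sqrt(sum((m2 - m1)^2)), sqrt(sum(shift_expected^2)),
               tolerance = 0.15)

  # factor = 1 -> true case distributionally identical to null
  simf <- sim_location_shift(ref, P_frac = 0.5, factor = 1, n1 = 10, n2 = 10,
                             case = "true", seed = 13)
  expect_equal(simf$provenance$mu2, simf$provenance$mu)
})

test_that("covariance-shift scenario inflates class-2 dispersion with beta", {
  ref <- zinb_reference_table(n = 100, d = 15, seed = 21)
  # the eigenvalue shift delta = |min eig| + 0.05 enters both class
  # covariances, so the clean beta-monotone quantity is the delta-free
  # dispersion gap trace(Sigma_s2) - trace(Sigma_s1) = beta * trace(T0)
  gap <- vapply(c(0.1, 1.4, 2.7, 4.0), function(b) {
    sim <- sim_covariance_shift(ref, beta = b, n1 = 5, n2 = 5, case = "true",
                                seed = 22)
    p <- sim$provenance
    expect_gt(min(eigen(p$Sigma_s1, only.values = TRUE)$values), 0)
    expect_gt(min(eigen(p$Sigma_s2, only.values = TRUE)$values), 0)
    sum(diag(p$Sigma_s2)) - sum(diag(p$Sigma_s1))
  }, numeric(1))
  expect_true(all(gap > 0))
  expect_true(all(diff(gap) > 0))

  # beta = 0 -> pure location scenario (equal covariances)
  sim0 <- sim_covariance_shift(ref, beta = 0, n1 = 5, n2 = 5, case = "true",
                               seed = 23)
  expect_equal(sim0$provenance$Sigma_s1, sim0$provenance$Sigma_s2, tolerance = 1e-12)
})

test_that("zinb_sample reduces to NB and respects zero inflation", {
  tab <- zinb_sample(rep(50, 4), rep(2, 4), rep(0, 4), n = 4000, seed = 31)
  expect_equal(unname(colMeans(tab)), rep(50, 4), tolerance = 0.1)
  # NB variance mu + mu^2/size
  expect_equal(unname(apply(tab, 2, var)), rep(50 + 2500 / 2, 4), tolerance = 0.2)
  # d large enough that the all-zero-row guard (which plants a single count)
  # cannot dilute the structural-zero fraction noticeably
  tab2 <- zinb_sample(rep(100, 10), rep(5, 10), rep(0.5, 10), n = 4000, seed = 32)
  expect_gte(mean(tab2 == 0), 0.5 - 0.02)
  expect_identical(unclass(zinb_sample(1:3 * 10, rep(1, 3), rep(0.2, 3), 50, seed = 7)),
                   unclass(zinb_sample(1:3 * 10, rep(1, 3), rep(0.2, 3), 50, seed = 7)))
})
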