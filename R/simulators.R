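# Benchmark data generators: Dirichlet, logistic-normal with structured
# covariance, negative-binomial library sizes, and ZINB-style count tables.

rdirichlet_mat <- function(n, alpha) {
  d <- length(alpha)
  g <- matrix(rgamma(n * d, shape = rep(alpha, each = n)), n, d)
  g / rowSums(g)
}

# multivariate normal via Cholesky; Sigma must be positive definite
rmvnorm_chol <- function(n, mu, Sigma) {
  ch <- chol(Sigma)
  matrix(rnorm(n * length(mu)), n) %*% ch + rep(mu, each = n)
}

# tridiagonal template: 1 on the diagonal, 0.2 on the two off-diagonals
banded_sigma <- function(m, off = 0.2) {
  S <- diag(m)
  if (m > 1) {
    idx <- cbind(seq_len(m - 1), seq_len(m - 1) + 1)
    S[idx] <- off
    S[idx[, 2:1, drop = FALSE]] <- off
  }
  S
}

# eigenvalue shift making Sigma and Sigma + U positive definite
pd_shift <- function(Sigma, U) {
  delta <- abs(min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values,
                   eigen(Sigma + U, symmetric = TRUE, only.values = TRUE)$values)) + 0.05
  S1 <- Sigma + delta * diag(nrow(Sigma))
  S2 <- Sigma + U + delta * diag(nrow(Sigma))
  stopifnot(min(eigen(S1, symmetric = TRUE, only.values = TRUE)$values) > 0,
            min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values) > 0)
  list(S1 = S1, S2 = S2, delta = delta)
}

half_up <- function(x) floor(x + 0.5)

new_simulated_dataset <- function(data, labels, case, provenance) {
  structure(list(data = data,
                 labels = as_group_labels(labels),
                 truth = identical(case, "true"),
                 provenance = provenance),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset [", x$provenance$scenario, "]: ",
      nrow(x$data), " samples x ", ncol(x$data), " taxa; ",
      if (x$truth) "true case\n" else "null case\n", sep = "")
  invisible(x)
}

#' Negative-binomial library sizes
#'
#' Draws sequencing depths `C_i ~ NB(s, s / (s + mu))` so the mean is `mu` and
#' the variance `mu + mu^2 / s`; with `s = 1`, depths are geometric-like and
#' heavily right-skewed, mimicking real per-sample total counts.
#'
#' @param s dispersion (size) parameter, > 0.
#' @param mu mean library size, > 0.
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @return integer vector of length `n`.
#' @export
nb_library_sizes <- function(s = 1, mu = 1e7, n, seed = NULL) {
  check_scalar_number(s, "s", lower = 1e-12)
  check_scalar_number(mu, "mu", lower = 1e-12)
  with_seed(seed, rnbinom(n, size = s, prob = s / (s + mu)))
}

#' Synthetic benchmark scenarios
#'
#' Five two-class generators spanning sparse and dense association signals:
#' \describe{
#'   \item{syn1}{symmetric Dirichlet; class 1 concentration 3, class 2
#'     concentration `3 * log(d) / 5`, so location and dispersion differences
#'     grow with dimension.}
#'   \item{syn2}{sparse count data: Dirichlet compositions scaled by
#'     NB(1, mean 1e7) library sizes and rounded (half-up) to counts.  The
#'     class-2 concentration of the first taxon is drawn from U[12500, 17500]
#'     versus U[3000, 5000] for class 1; taxa 2-10 use U[500, 1500] and the
#'     remaining taxa U[1, 5] (random sparsity) in both classes.  Requires
#'     `d >= 11`.}
#'   \item{syn3}{logistic-normal, dense location shift: class-2 ALR mean
#'     `1 / sqrt(d)` in the first 25% of the `d - 1` ALR coordinates;
#'     covariance = tridiagonal(1, 0.2) plus a symmetrized U[0, 9 / d^2]
#'     perturbation for class 2, both made positive definite by an eigenvalue
#'     shift.}
#'   \item{syn4}{as syn3 but a sparse shift: class-2 ALR mean `log(d) / 3` in
#'     the first `shift_dims` coordinates (default 1).}
#'   \item{syn5}{as syn3 but a small dense shift `1 / sqrt(n1 + n2)` in all
#'     coordinates and a large U[0, 9] covariance perturbation (dispersion
#'     dominated).}
#' }
#' Null cases draw both classes from the class-1 distribution.  Gaussian ALR
#' draws are mapped to the simplex with [inverse_alr()], so compositions have
#' exactly `d` taxa.
#'
#' @param scenario one of `"syn1"` ... `"syn5"`.
#' @param d number of taxa (>= 2; syn2 needs >= 11).
#' @param n1,n2 class sample sizes (40/40 balanced and 20/60 unbalanced are
#'   the benchmark designs).
#' @param case `"true"` (classes differ) or `"null"` (both from class 1).
#' @param seed optional RNG seed; fixed seed gives a bit-identical dataset.
#' @param shift_dims number of shifted leading coordinates for syn4.
#' @return a `simulated_dataset`: list with `data` (a `composition` for
#'   syn1/3/4/5, a `count_table` for syn2), `labels` (`c1`/`c2`), `truth`,
#'   and a `provenance` echo of all parameters.
#' @export
simulate_synthetic <- function(scenario = c("syn1", "syn2", "syn3", "syn4", "syn5"),
                               d = 50L, n1 = 40L, n2 = 40L,
                               case = c("true", "null"), seed = NULL,
                               shift_dims = 1L) {
  scenario <- match.arg(scenario)
  case <- match.arg(case)
  if (d < 2) stop("d must be >= 2")
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2")
  labels <- rep(c("c1", "c2"), c(n1, n2))
  taxa <- paste0("taxon_", seq_len(d))
  prov <- list(scenario = scenario, d = d, n1 = n1, n2 = n2, case = case,
               seed = seed)

  with_seed(seed, {
    if (scenario == "syn1") {
      a1 <- rep(3, d)
      a2 <- if (case == "true") rep(3 * log(d) / 5, d) else a1
      X <- rbind(rdirichlet_mat(n1, a1), rdirichlet_mat(n2, a2))
      colnames(X) <- taxa
      data <- as_composition(X, check = FALSE)
      prov$alpha <- c(a1 = 3, a2 = a2[1])
    } else if (scenario == "syn2") {
      if (d < 11) stop("scenario syn2 requires d >= 11")
      draw_alpha <- function(first_lo, first_hi)
        c(runif(1, first_lo, first_hi), runif(9, 500, 1500), runif(d - 10, 1, 5))
      a1 <- draw_alpha(3000, 5000)
      a2 <- if (case == "true") draw_alpha(12500, 17500) else a1
      C <- rnbinom(n1 + n2, size = 1, prob = 1 / (1 + 1e7))
      X <- rbind(rdirichlet_mat(n1, a1), rdirichlet_mat(n2, a2))
      counts <- half_up(X * C)
      colnames(counts) <- taxa
      data <- count_table(counts)
      prov$alpha1 <- a1; prov$alpha2 <- a2
    } else {
      m <- d - 1L
      Sigma <- banded_sigma(m)
      U <- switch(scenario,
        syn3 = matrix(runif(m * m, 0, 9 / d^2), m, m),
        syn4 = matrix(runif(m * m, 0, 9 / d^2), m, m),
        syn5 = matrix(runif(m * m, 0, 9), m, m))
      U <- (U + t(U)) / 2
      cov <- pd_shift(Sigma, U)
      mu1 <- rep(0, m)
      mu2 <- mu1
      if (scenario == "syn3") {
        mu2[seq_len(ceiling(0.25 * m))] <- 1 / sqrt(d)
      } else if (scenario == "syn4") {
        mu2[seq_len(min(shift_dims, m))] <- log(d) / 3
      } else {
        mu2[] <- 1 / sqrt(n1 + n2)
      }
      S1 <- rmvnorm_chol(n1, mu1, cov$S1)
      S2 <- if (case == "true") rmvnorm_chol(n2, mu2, cov$S2)
            else rmvnorm_chol(n2, mu1, cov$S1)
      data <- inverse_alr(rbind(S1, S2), taxon_names = taxa)
      prov$delta <- cov$delta
      prov$mu2 <- mu2
    }
    rownames(data) <- paste0("sample_", seq_len(n1 + n2))
    new_simulated_dataset(data, labels, case, prov)
  })
}

#' Location-shift scenario calibrated on a reference count table
#'
#' Fits an additive-logistic-normal model to a reference table (closure, zero
#' imputation, ALR with the last taxon as reference, empirical mean and
#' covariance), reorders ALR coordinates by ascending variance so the shift
#' lands in minimal-variance features, multiplies the first
#' `ceiling(P_frac * (d - 1))` coordinates of the class-2 mean by `factor`,
#' and maps Gaussian draws back to the simplex.
#'
#' @param reference a [count_table()] (>= 3 taxa), e.g. from [zinb_sample()].
#' @param P_frac fraction of ALR coordinates shifted, in `(0, 1]`.
#' @param factor multiplicative mean shift (1.25 in the benchmark settings;
#'   1 reproduces the null distribution exactly).
#' @param n1,n2 class sample sizes.
#' @param case `"true"` or `"null"` (both classes from the reference model).
#' @param seed optional RNG seed.
#' @param prevalence prevalence filter applied to the reference (0.15 for
#'   these scenarios).
#' @return a `simulated_dataset` whose `data` is a `composition`.
#' @export
sim_location_shift <- function(reference, P_frac, factor = 1.25,
                               n1 = 40L, n2 = 40L, case = c("true", "null"),
                               seed = NULL, prevalence = 0.15) {
  case <- match.arg(case)
  check_scalar_number(P_frac, "P_frac", lower = 1e-12, upper = 1)
  fit <- alr_reference_fit(reference, prevalence, rank_variance = TRUE)
  m <- length(fit$mu)
  nshift <- ceiling(P_frac * m)
  mu2 <- fit$mu
  mu2[seq_len(nshift)] <- mu2[seq_len(nshift)] * factor
  with_seed(seed, {
    S1 <- rmvnorm_chol(n1, fit$mu, fit$Sigma)
    S2 <- if (case == "true") rmvnorm_chol(n2, mu2, fit$Sigma)
          else rmvnorm_chol(n2, fit$mu, fit$Sigma)
    data <- alr_draws_to_composition(rbind(S1, S2), fit)
    new_simulated_dataset(data, rep(c("c1", "c2"), c(n1, n2)), case,
                          list(scenario = "exp_location", d = m + 1L,
                               n1 = n1, n2 = n2, case = case, seed = seed,
                               P_frac = P_frac, factor = factor,
                               n_shifted = nshift, mu = fit$mu, mu2 = mu2,
                               Sigma = fit$Sigma))
  })
}

#' Covariance-shift scenario calibrated on a reference count table
#'
#' As [sim_location_shift()] but the class-2 covariance is inflated:
#' `Sigma_s2 = Sigma + T + delta * I` with `T` a symmetrized U[0, beta] matrix
#' and `delta` the eigenvalue shift guaranteeing positive definiteness of
#' both `Sigma_s1 = Sigma + delta * I` and `Sigma_s2`; the class-2 mean is
#' additionally shifted by `shift_factor` on the first
#' `ceiling(P_frac * (d - 1))` coordinates.
#'
#' @inheritParams sim_location_shift
#' @param beta upper bound of the uniform covariance perturbation (>= 0;
#'   0 reduces to a pure location scenario).
#' @param shift_factor multiplicative mean shift on the leading coordinates.
#' @return a `simulated_dataset` whose `data` is a `composition`.
#' @export
sim_covariance_shift <- function(reference, beta, shift_factor = 1.25,
                                 P_frac = 0.10, n1 = 40L, n2 = 40L,
                                 case = c("true", "null"), seed = NULL,
                                 prevalence = 0.15) {
  case <- match.arg(case)
  if (beta < 0) stop("beta must be >= 0")
  fit <- alr_reference_fit(reference, prevalence, rank_variance = TRUE)
  m <- length(fit$mu)
  with_seed(seed, {
    Tm <- matrix(runif(m * m, 0, beta), m, m)
    Tm <- (Tm + t(Tm)) / 2
    cov <- pd_shift(fit$Sigma, Tm)
    nshift <- ceiling(P_frac * m)
    mu2 <- fit$mu
    mu2[seq_len(nshift)] <- mu2[seq_len(nshift)] * shift_factor
    S1 <- rmvnorm_chol(n1, fit$mu, cov$S1)
    S2 <- if (case == "true") rmvnorm_chol(n2, mu2, cov$S2)
          else rmvnorm_chol(n2, fit$mu, cov$S1)
    data <- alr_draws_to_composition(rbind(S1, S2), fit)
    new_simulated_dataset(data, rep(c("c1", "c2"), c(n1, n2)), case,
                          list(scenario = "exp_covariance", d = m + 1L,
                               n1 = n1, n2 = n2, case = case, seed = seed,
                               beta = beta, shift_factor = shift_factor,
                               P_frac = P_frac, delta = cov$delta,
                               Sigma_s1 = cov$S1, Sigma_s2 = cov$S2))
  })
}

# closure + zero imputation + ALR + empirical moments of a reference table;
# optionally reorders coordinates by ascending variance
alr_reference_fit <- function(reference, prevalence, rank_variance = TRUE) {
  if (!inherits(reference, "count_table")) reference <- count_table(reference)
  if (ncol(reference) < 3L) stop("reference needs at least 3 taxa")
  tab <- prevalence_filter(reference, prevalence)
  R <- multiplicative_replacement(closure(tab))
  A <- alr(R)
  mu <- colMeans(A)
  Sigma <- cov(A)
  if (inherits(try(chol(Sigma), silent = TRUE), "try-error")) {
    warning("singular reference covariance; adding ridge 1e-8")
    Sigma <- Sigma + 1e-8 * diag(ncol(Sigma))
  }
  ord <- if (rank_variance) order(diag(Sigma)) else seq_along(mu)
  list(mu = mu[ord], Sigma = Sigma[ord, ord, drop = FALSE],
       order = ord, taxa = colnames(R))
}

# undo the variance ranking, then project ALR draws back onto the simplex
alr_draws_to_composition <- function(S, fit) {
  inv <- order(fit$order)
  comp <- inverse_alr(S[, inv, drop = FALSE], taxon_names = fit$taxa)
  rownames(comp) <- paste0("sample_", seq_len(nrow(comp)))
  comp
}

#' Zero-inflated negative binomial count table
#'
#' Independent per-taxon ZINB draws: with probability `zero_inflation[j]` a
#' count is a structural zero, otherwise `NB(dispersion[j], mean[j])`.  Used
#' as the default reference generator for the experimental-style scenarios
#' when no real count table is supplied.
#'
#' @param mean_vector per-taxon NB means (> 0).
#' @param dispersion_vector per-taxon NB size parameters (> 0).
#' @param zero_inflation_vector per-taxon structural-zero probabilities in
#'   `[0, 1)`.
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @param taxon_names optional taxon names.
#' @return a [count_table()].
#' @export
zinb_sample <- function(mean_vector, dispersion_vector, zero_inflation_vector,
                        n, seed = NULL, taxon_names = NULL) {
  d <- length(mean_vector)
  stopifnot(length(dispersion_vector) == d, length(zero_inflation_vector) == d,
            all(mean_vector > 0), all(dispersion_vector > 0),
            all(zero_inflation_vector >= 0), all(zero_inflation_vector < 1))
  with_seed(seed, {
    counts <- vapply(seq_len(d), function(j) {
      x <- as.numeric(rnbinom(n, size = dispersion_vector[j], mu = mean_vector[j]))
      x[rbinom(n, 1L, zero_inflation_vector[j]) == 1L] <- 0
      x
    }, numeric(n))
    # guard against all-zero samples (vanishingly rare for realistic means)
    zero_rows <- rowSums(counts) == 0
    if (any(zero_rows)) counts[zero_rows, which.max(mean_vector)] <- 1L
    count_table(counts, taxon_names = taxon_names)
  })
}

#' Synthetic 16S-like ZINB reference table
#'
#' Convenience generator of a sparse, over-dispersed count table used as the
#' reference for [sim_location_shift()] / [sim_covariance_shift()] when no
#' real dataset is available: log-normal taxon means (meanlog 4, sdlog 1.5),
#' dispersions U[0.1, 2], and structural-zero probabilities U[0, 0.6].
#'
#' @param n number of samples.
#' @param d number of taxa.
#' @param seed optional RNG seed.
#' @return a [count_table()].
#' @export
zinb_reference_table <- function(n = 100L, d = 50L, seed = NULL) {
  with_seed(seed, {
    mu <- exp(rnorm(d, 4, 1.5))
    size <- runif(d, 0.1, 2)
    pi0 <- runif(d, 0, 0.6)
    zinb_sample(mu, size, pi0, n)
  })
}
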