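#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ===========================================================================
// DISCO energy partition (two groups)
// ===========================================================================

// D must already be |d|^alpha.  Returns between (S), within (W) and total (T)
// dispersion; the identity S + W = T holds algebraically.
static void disco_sw(const NumericMatrix& D, const IntegerVector& y,
                     double* S, double* W, double* T) {
  const int n = D.nrow();
  int n0 = 0, n1 = 0;
  for (int i = 0; i < n; ++i) (y[i] == 0 ? n0 : n1)++;
  double cross = 0.0, w0 = 0.0, w1 = 0.0;  // ordered-pair sums
  for (int i = 0; i < n; ++i) {
    const int yi = y[i];
    for (int k = 0; k < n; ++k) {
      const double d = D(i, k);
      if (yi != y[k]) cross += d;
      else if (yi == 0) w0 += d;
      else w1 += d;
    }
  }
  const double mB = 0.5 * cross / ((double)n0 * n1);
  const double mW0 = w0 / ((double)n0 * n0);
  const double mW1 = w1 / ((double)n1 * n1);
  *S = ((double)n0 * n1 / (2.0 * n)) * (2.0 * mB - mW0 - mW1);
  *W = w0 / (2.0 * n0) + w1 / (2.0 * n1);
  *T = (cross + w0 + w1) / (2.0 * n);
}

//' @noRd
// [[Rcpp::export(name = ".disco_parts_cpp")]]
List disco_parts_cpp(NumericMatrix D, IntegerVector y) {
  double S, W, T;
  disco_sw(D, y, &S, &W, &T);
  return List::create(_["S"] = S, _["W"] = W, _["total"] = T);
}

// Two-sample energy statistic on raw distances; singleton groups allowed
// (within-group mean is 0 for a singleton).
//' @noRd
// [[Rcpp::export(name = ".energy_stat_cpp")]]
double energy_stat_cpp(NumericMatrix D, IntegerVector y) {
  const int n = D.nrow();
  int n0 = 0, n1 = 0;
  for (int i = 0; i < n; ++i) (y[i] == 0 ? n0 : n1)++;
  double cross = 0.0, w0 = 0.0, w1 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k) {
      const double d = D(i, k);
      if (y[i] != y[k]) cross += d;
      else if (y[i] == 0) w0 += d;
      else w1 += d;
    }
  const double mB = 0.5 * cross / ((double)n0 * n1);
  const double mW0 = w0 / ((double)n0 * n0);
  const double mW1 = w1 / ((double)n1 * n1);
  return ((double)n0 * n1 / (double)n) * (2.0 * mB - mW0 - mW1);
}

// discoF across greedy candidates: squared-distance matrix of the current
// subset plus, per candidate, one ratio's pairwise squared differences.
// `cand` holds one flattened n*n matrix per column.
//' @noRd
// [[Rcpp::export(name = ".disco_f_candidates_cpp")]]
NumericVector disco_f_candidates_cpp(NumericMatrix base, NumericMatrix cand,
                                     IntegerVector y, double alpha) {
  const int n = base.nrow(), K = cand.ncol();
  NumericVector out(K);
  NumericMatrix D(n, n);
  const double half_alpha = alpha / 2.0;
  for (int c = 0; c < K; ++c) {
    const double* cd = &cand(0, c);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < n; ++k) {
        const double ss = base(i, k) + cd[i + n * k];
        D(i, k) = (alpha == 1.0) ? std::sqrt(ss) : std::pow(ss, half_alpha);
      }
    double S, W, T;
    disco_sw(D, y, &S, &W, &T);
    out[c] = (W <= 0.0) ? R_PosInf : S / (W / (n - 2.0));
  }
  return out;
}

// ===========================================================================
// PERMANOVA partition from squared distances
// ===========================================================================

static void permanova_ss(const double* D2, int n, const int* g, int a,
                         double* SST, double* SSW) {
  std::vector<double> within(a, 0.0);
  std::vector<int> cnt(a, 0);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  const double* col = D2;
  for (int k = 0; k < n; ++k, col += n) {  // column-contiguous sweep
    const int gk = g[k];
    for (int i = 0; i < k; ++i) {
      const double d2 = col[i];
      tot += d2;
      if (g[i] == gk) within[gk] += d2;
    }
  }
  *SST = tot / n;
  double ssw = 0.0;
  for (int c = 0; c < a; ++c) ssw += within[c] / cnt[c];
  *SSW = ssw;
}

//' @noRd
// [[Rcpp::export(name = ".permanova_parts_cpp")]]
List permanova_parts_cpp(NumericMatrix D2, IntegerVector g, int a) {
  std::vector<int> gv(g.begin(), g.end());
  double SST, SSW;
  permanova_ss(D2.begin(), D2.nrow(), gv.data(), a, &SST, &SSW);
  return List::create(_["SS_T"] = SST, _["SS_W"] = SSW, _["SS_A"] = SST - SSW);
}

//' @noRd
// [[Rcpp::export(name = ".permanova_f_null_cpp")]]
NumericVector permanova_f_null_cpp(NumericMatrix D2, IntegerMatrix perms, int a) {
  const int m = perms.nrow(), n = D2.nrow();
  NumericVector out(m);
  std::vector<int> g(n);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) g[i] = perms(r, i);
    double SST, SSW;
    permanova_ss(D2.begin(), n, g.data(), a, &SST, &SSW);
    const double num = (SST - SSW) / (a - 1.0);
    const double den = SSW / (n - a);
    out[r] = (den <= 0.0) ? R_PosInf : num / den;
  }
  return out;
}

// ===========================================================================
// geometric (spatial) median machinery
//
// X is column-major (n rows, p cols); `rows` indexes the point subset.
// Primary iteration is Weiszfeld with the Vardi-Zhang correction; a damped
// Newton step takes over when the linear rate stalls (common on elongated
// heavy-tailed logratio clouds, where plain Weiszfeld can need >> 10^3
// iterations for 1e-8 accuracy).
// ===========================================================================

static double gm_objective(const double* X, int n, int p,
                           const std::vector<int>& rows,
                           const std::vector<double>& m) {
  double f = 0.0;
  for (int i : rows) {
    double d2 = 0.0;
    for (int j = 0; j < p; ++j) {
      const double diff = X[i + (size_t)j * n] - m[j];
      d2 += diff * diff;
    }
    f += std::sqrt(d2);
  }
  return f;
}

// in-place lower Cholesky factorization; returns false if not SPD
static bool chol_factor(std::vector<double>& H, int p) {
  for (int j = 0; j < p; ++j) {
    double d = H[(size_t)j * p + j];
    for (int k = 0; k < j; ++k) d -= H[(size_t)j * p + k] * H[(size_t)j * p + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    H[(size_t)j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = H[(size_t)i * p + j];
      for (int k = 0; k < j; ++k) s -= H[(size_t)i * p + k] * H[(size_t)j * p + k];
      H[(size_t)i * p + j] = s / d;
    }
  }
  return true;
}

static void chol_apply(const std::vector<double>& L, int p, double* b) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[(size_t)i * p + k] * b[k];
    b[i] = s / L[(size_t)i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= L[(size_t)k * p + i] * b[k];
    b[i] = s / L[(size_t)i * p + i];
  }
}

// gradient of sum ||med - x_i|| over rows; returns weight sum (sum 1/d_i)
static double gm_gradient(const double* X, int n, int p,
                          const std::vector<int>& rows,
                          const std::vector<double>& med, double* g) {
  for (int j = 0; j < p; ++j) g[j] = 0.0;
  double wsum = 0.0;
  for (int i : rows) {
    double d2 = 0.0;
    for (int j = 0; j < p; ++j) {
      const double diff = X[i + (size_t)j * n] - med[j];
      d2 += diff * diff;
    }
    const double d = std::sqrt(d2);
    if (d < 1e-12) continue;
    const double w = 1.0 / d;
    wsum += w;
    for (int j = 0; j < p; ++j) g[j] -= (X[i + (size_t)j * n] - med[j]) * w;
  }
  return wsum;
}

// build H = sum w_i (I - u_i u_i^T) at med (plus a tiny ridge)
static double gm_hessian(const double* X, int n, int p,
                         const std::vector<int>& rows,
                         const std::vector<double>& med, std::vector<double>& H) {
  std::fill(H.begin(), H.end(), 0.0);
  double wsum = 0.0;
  std::vector<double> u(p);
  for (int i : rows) {
    double d2 = 0.0;
    for (int j = 0; j < p; ++j) {
      u[j] = X[i + (size_t)j * n] - med[j];
      d2 += u[j] * u[j];
    }
    const double d = std::sqrt(d2);
    if (d < 1e-12) continue;
    const double w = 1.0 / d;
    wsum += w;
    for (int j = 0; j < p; ++j) u[j] *= w;
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k <= j; ++k) H[(size_t)j * p + k] -= w * u[j] * u[k];
      H[(size_t)j * p + j] += w;
    }
  }
  for (int j = 0; j < p; ++j) {
    for (int k = j + 1; k < p; ++k) H[(size_t)j * p + k] = H[(size_t)k * p + j];
    H[(size_t)j * p + j] += 1e-10 * (wsum > 0 ? wsum : 1.0);
  }
  return wsum;
}

// damped Newton minimization of the sum-of-distances objective
static bool newton_gm(const double* X, int n, int p, const std::vector<int>& rows,
                      double tol, int maxit, std::vector<double>& med) {
  std::vector<double> g(p), H((size_t)p * p), delta(p), trial(p);
  double f = gm_objective(X, n, p, rows, med);
  for (int it = 0; it < maxit; ++it) {
    const double wsum = gm_hessian(X, n, p, rows, med, H);
    if (wsum <= 0.0) return true;
    gm_gradient(X, n, p, rows, med, g.data());
    for (int j = 0; j < p; ++j) delta[j] = -g[j];
    if (!chol_factor(H, p)) return false;
    chol_apply(H, p, delta.data());

    double step = 1.0, ft = f;
    bool improved = false;
    for (int t = 0; t < 40; ++t) {
      for (int j = 0; j < p; ++j) trial[j] = med[j] + step * delta[j];
      ft = gm_objective(X, n, p, rows, trial);
      if (ft <= f) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) {
      double gn = 0.0;
      for (int j = 0; j < p; ++j) gn += g[j] * g[j];
      return std::sqrt(gn) <= 1e-6 * wsum;  // stationary enough
    }
    double shift = 0.0, scale = 1.0;
    for (int j = 0; j < p; ++j) {
      shift += std::fabs(trial[j] - med[j]);
      med[j] = trial[j];
      scale += std::fabs(med[j]);
    }
    f = ft;
    if (shift < tol * scale) return true;
  }
  return false;
}

// Weiszfeld iteration (Vardi-Zhang corrected) with Newton hand-over
static int weiszfeld(const double* X, int n, int p, const std::vector<int>& rows,
                     double tol, int maxit, std::vector<double>& med,
                     const std::vector<double>* init = NULL) {
  const int ng = (int)rows.size();
  if (ng == 1) {
    med.assign(p, 0.0);
    for (int j = 0; j < p; ++j) med[j] = X[rows[0] + (size_t)j * n];
    return 0;
  }
  if (init != NULL && (int)init->size() == p) {
    med = *init;
  } else {
    med.assign(p, 0.0);
    for (int i : rows)
      for (int j = 0; j < p; ++j) med[j] += X[i + (size_t)j * n];
    for (int j = 0; j < p; ++j) med[j] /= ng;
  }

  std::vector<double> Tnum(p), Rvec(p), next(p);
  const double eps_coincide = 1e-10;
  const int warmup = (p <= 200) ? 10 : maxit;  // Newton takes over after warm-up
  for (int it = 1; it <= maxit; ++it) {
    double wsum = 0.0;
    int eta = 0;
    std::fill(Tnum.begin(), Tnum.end(), 0.0);
    std::fill(Rvec.begin(), Rvec.end(), 0.0);
    for (int i : rows) {
      double d2 = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = X[i + (size_t)j * n] - med[j];
        d2 += diff * diff;
      }
      const double d = std::sqrt(d2);
      if (d < eps_coincide) { ++eta; continue; }
      const double w = 1.0 / d;
      wsum += w;
      for (int j = 0; j < p; ++j) {
        Tnum[j] += w * X[i + (size_t)j * n];
        Rvec[j] += (X[i + (size_t)j * n] - med[j]) * w;
      }
    }
    if (wsum <= 0.0) return it;  // all points coincide with the iterate
    double gamma = 0.0;
    if (eta > 0) {
      double r2 = 0.0;
      for (int j = 0; j < p; ++j) r2 += Rvec[j] * Rvec[j];
      const double r = std::sqrt(r2);
      if (r <= (double)eta) return it;  // current iterate is the optimum
      gamma = (double)eta / r;
    }
    double shift = 0.0, scale = 1.0;
    for (int j = 0; j < p; ++j) {
      next[j] = (1.0 - gamma) * (Tnum[j] / wsum) + gamma * med[j];
      shift += std::fabs(next[j] - med[j]);
      med[j] = next[j];
      scale += std::fabs(med[j]);
    }
    if (shift < tol * scale) return it;
    if (it >= warmup && it % warmup == 0) {
      if (newton_gm(X, n, p, rows, tol, 100, med)) return it;
    }
  }
  if (p <= 200 && newton_gm(X, n, p, rows, tol, 100, med)) return maxit;
  return -1;
}

// exact univariate median (midpoint-of-two for even counts)
static double median1d(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  const size_t m = v.size();
  return (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
}

// one-way ANOVA F on distances of each sample to its group spatial median
static double permdisp_F(const double* X, int n, int p, const int* g, int a,
                         double tol, int maxit, bool* converged,
                         const std::vector<double>* init = NULL) {
  *converged = true;
  std::vector<std::vector<int> > rows(a);
  for (int i = 0; i < n; ++i) rows[g[i]].push_back(i);

  std::vector<double> resid(n), gm(a, 0.0), med, vals;
  for (int c = 0; c < a; ++c) {
    if (p == 1) {
      vals.clear();
      for (int i : rows[c]) vals.push_back(X[i]);
      med.assign(1, median1d(vals));
    } else if (weiszfeld(X, n, p, rows[c], tol, maxit, med, init) < 0) {
      *converged = false;
      return NA_REAL;
    }
    for (int i : rows[c]) {
      double d2 = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = X[i + (size_t)j * n] - med[j];
        d2 += diff * diff;
      }
      resid[i] = std::sqrt(d2);
      gm[c] += resid[i];
    }
  }
  double m = 0.0;
  for (int c = 0; c < a; ++c) gm[c] /= rows[c].size();
  for (int i = 0; i < n; ++i) m += resid[i];
  m /= n;

  double ssb = 0.0, ssw = 0.0;
  for (int c = 0; c < a; ++c) {
    ssb += rows[c].size() * (gm[c] - m) * (gm[c] - m);
    for (int i : rows[c]) ssw += (resid[i] - gm[c]) * (resid[i] - gm[c]);
  }
  const double num = ssb / (a - 1.0), den = ssw / (n - a);
  if (den <= 0.0) return (num > 0.0) ? R_PosInf : 0.0;
  return num / den;
}

//' @noRd
// [[Rcpp::export(name = ".permdisp_f_cpp")]]
List permdisp_f_cpp(NumericMatrix X, IntegerVector g, int a,
                    double tol = 1e-8, int maxit = 1000) {
  std::vector<int> gv(g.begin(), g.end());
  bool conv;
  const double f = permdisp_F(X.begin(), X.nrow(), X.ncol(), gv.data(), a,
                              tol, maxit, &conv);
  return List::create(_["F"] = f, _["converged"] = conv, _["maxit"] = maxit);
}

//' @noRd
// [[Rcpp::export(name = ".permdisp_f_null_cpp")]]
NumericVector permdisp_f_null_cpp(NumericMatrix X, IntegerMatrix perms, int a,
                                  double tol = 1e-8, int maxit = 1000) {
  const int m = perms.nrow(), n = X.nrow();
  NumericVector out(m);
  std::vector<int> g(n);
  // permuted groups are blends of the original ones, so the pooled spatial
  // median is an excellent warm start for every replicate
  std::vector<double> pooled;
  const std::vector<double>* init = NULL;
  if (X.ncol() > 1) {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    if (weiszfeld(X.begin(), n, X.ncol(), all, tol, maxit, pooled) >= 0)
      init = &pooled;
  }
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) g[i] = perms(r, i);
    bool conv;
    const double f = permdisp_F(X.begin(), n, X.ncol(), g.data(), a, tol, maxit,
                                &conv, init);
    if (!conv) stop("Weiszfeld iteration failed to converge within %d iterations", maxit);
    out[r] = f;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".spatial_median_cpp")]]
List spatial_median_cpp(NumericMatrix X, double tol = 1e-8, int maxit = 1000) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<double> med;
  const int it = weiszfeld(X.begin(), X.nrow(), X.ncol(), rows, tol, maxit, med);
  return List::create(_["median"] = NumericVector(med.begin(), med.end()),
                      _["iterations"] = it, _["converged"] = it >= 0);
}


// ===========================================================================
// fused greedy forward selection
//
// Runs the entire greedy loop of selectionEnergy in C++.  Zsub holds the
// spanning-tree logratios in descending DCV order; the search starts from
// column 0, at each step evaluates the statistic for the current subset plus
// each remaining column, appends the best candidate, and stops after
// `patience` consecutive non-improving steps (the R caller trims to the
// best-so-far prefix).  kind 0 = discoF (energy partition F with exponent
// alpha), kind 1 = scaled combined-F (PERMANOVA + PERMDISP F, each z-scored
// against the supplied permutation set).
//
// Hot-path economics: squared distances of the current subset are maintained
// incrementally (adding one ratio adds its pairwise squared differences);
// the PERMANOVA permutation null per candidate reduces to O(m n) via the
// per-group decomposition sum_{i<j in g} (v_i - v_j)^2 =
// n_g sum v^2 - (sum v)^2; PERMDISP group medians are solved by chord
// iterations sharing one Hessian factorization per candidate and warm
// starts carried over from the previously accepted subset, with full
// Newton / Weiszfeld fallbacks.  Identical results to the reference
// per-candidate path up to solver tolerance.
// ===========================================================================

//' @noRd
// [[Rcpp::export(name = ".greedy_select_cpp")]]
List greedy_select_cpp(NumericMatrix Zsub, IntegerVector y, int kind,
                       Nullable<IntegerMatrix> permsN, double alpha,
                       int patience, double max_features,
                       IntegerVector name_rank, double tol = 1e-8,
                       int maxit = 1000) {
  const int n = Zsub.nrow(), ptree = Zsub.ncol();
  const double* Z = Zsub.begin();
  int n0 = 0;
  for (int i = 0; i < n; ++i) if (y[i] == 0) ++n0;
  const int n1 = n - n0;
  std::vector<int> yv(y.begin(), y.end());

  // permutations, transposed into contiguous per-replicate rows; grouping
  // index 0 is the observed labeling, 1..m the permutations
  int m = 0;
  std::vector<int> Pt, cnt0;
  if (kind == 1) {
    if (permsN.isNull()) stop("scaled combined-F requires a permutation set");
    IntegerMatrix P(permsN);
    m = P.nrow();
    if (P.ncol() != n) stop("permutation matrix has wrong width");
    Pt.resize((size_t)(m + 1) * n);
    cnt0.assign(m + 1, n0);
    for (int i = 0; i < n; ++i) Pt[i] = yv[i];
    for (int r = 0; r < m; ++r) {
      int c0 = 0;
      for (int i = 0; i < n; ++i) {
        Pt[(size_t)(r + 1) * n + i] = P(r, i);
        if (P(r, i) == 0) ++c0;
      }
      cnt0[r + 1] = c0;
    }
  }
  const int ngrp = m + 1;

  std::vector<double> baseD2((size_t)n * n, 0.0);  // upper triangle [i + n*j], i<j
  double Tbase = 0.0;
  std::vector<double> Xbuf((size_t)n * ptree);     // selected columns + cand slot
  std::vector<char> inpool(ptree, 1);
  std::vector<int> selected;
  std::vector<double> stepvals;
  std::vector<double> Bg(2 * (size_t)std::max(ngrp, 1));  // base within-pair sums
  // carried-over group medians (dim k) per grouping, and the pooled median
  std::vector<double> gmed0((size_t)ngrp * ptree), gmed1((size_t)ngrp * ptree);
  std::vector<double> pooled_full;
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  const double half_alpha = alpha / 2.0;

  // ---- discoF for current-subset + candidate column v ----
  auto eval_disco = [&](const double* v) -> double {
    double s0 = 0.0, s1 = 0.0, sc = 0.0;
    for (int j = 1; j < n; ++j) {
      const double vj = v[j];
      const int yj = yv[j];
      const double* col = &baseD2[(size_t)n * j];
      for (int i = 0; i < j; ++i) {
        const double diff = v[i] - vj;
        const double d2 = col[i] + diff * diff;
        const double d = (alpha == 1.0) ? std::sqrt(d2) : std::pow(d2, half_alpha);
        if (yv[i] != yj) sc += d;
        else if (yj == 0) s0 += d;
        else s1 += d;
      }
    }
    const double mB = sc / ((double)n0 * n1);
    const double mW0 = 2.0 * s0 / ((double)n0 * n0);
    const double mW1 = 2.0 * s1 / ((double)n1 * n1);
    const double S = ((double)n0 * n1 / (2.0 * n)) * (2.0 * mB - mW0 - mW1);
    const double W = s0 / n0 + s1 / n1;
    return (W <= 0.0) ? R_PosInf : S / (W / (n - 2.0));
  };

  // ---- PERMANOVA F from incremental sums for one grouping ----
  auto permanova_cf = [&](const double* v, const int* g, double B0, double B1,
                          int ng0, double sall, double qall,
                          double Tpair) -> double {
    double s0 = 0.0, q0 = 0.0;
    for (int i = 0; i < n; ++i)
      if (g[i] == 0) { s0 += v[i]; q0 += v[i] * v[i]; }
    const double s1 = sall - s0, q1 = qall - q0;
    const int ng1 = n - ng0;
    const double SSW = (B0 + (ng0 * q0 - s0 * s0)) / ng0 +
                       (B1 + (ng1 * q1 - s1 * s1)) / ng1;
    const double SST = Tpair / n;
    const double den = SSW / (n - 2.0);
    return (den <= 0.0) ? R_PosInf : (SST - SSW) / den;
  };

  // 1-D PERMDISP F with exact medians, for single-ratio subsets
  std::vector<double> b0v, b1v;
  auto disp1d = [&](const double* v, const int* g) -> double {
    b0v.clear(); b1v.clear();
    for (int i = 0; i < n; ++i) (g[i] == 0 ? b0v : b1v).push_back(v[i]);
    const double md0 = median1d(b0v), md1 = median1d(b1v);
    const int c0 = (int)b0v.size(), c1 = (int)b1v.size();
    double m0 = 0.0, m1 = 0.0, ss = 0.0;
    for (double x : b0v) m0 += std::fabs(x - md0);
    for (double x : b1v) m1 += std::fabs(x - md1);
    m0 /= c0; m1 /= c1;
    for (double x : b0v) { const double r_ = std::fabs(x - md0) - m0; ss += r_ * r_; }
    for (double x : b1v) { const double r_ = std::fabs(x - md1) - m1; ss += r_ * r_; }
    const double mm = (m0 * c0 + m1 * c1) / n;
    const double ssb = c0 * (m0 - mm) * (m0 - mm) + c1 * (m1 - mm) * (m1 - mm);
    const double den = ss / (n - 2.0);
    if (den <= 0.0) return (ssb > 0.0) ? R_PosInf : 0.0;
    return ssb / den;
  };

  // shared buffers for the multivariate dispersion path
  std::vector<double> H, med, grad, med0buf, med1buf, rowsmean;
  std::vector<int> rowsbuf;

  // solve one group's spatial median (dim pcur) by chord iterations with the
  // shared factorization; falls back to damped Newton then Weiszfeld
  auto solve_group = [&](const double* X, int pcur, const int* grp, int cls,
                         const double* init_base, double v_init,
                         double wsum_pool, bool have_factor,
                         std::vector<double>& out) {
    rowsbuf.clear();
    for (int i = 0; i < n; ++i) if (grp[i] == cls) rowsbuf.push_back(i);
    out.assign(pcur, 0.0);
    for (int j = 0; j < pcur - 1; ++j) out[j] = init_base[j];
    out[pcur - 1] = v_init;
    if (rowsbuf.size() <= 1) {
      if (rowsbuf.size() == 1)
        for (int j = 0; j < pcur; ++j) out[j] = X[rowsbuf[0] + (size_t)j * n];
      return;
    }
    bool done = false;
    if (have_factor) {
      double prev_shift = R_PosInf;
      for (int it = 0; it < 60; ++it) {
        const double wsum_g = gm_gradient(X, n, pcur, rowsbuf, out, grad.data());
        if (wsum_g <= 0.0) { done = true; break; }
        for (int j = 0; j < pcur; ++j) grad[j] = -grad[j];
        chol_apply(H, pcur, grad.data());
        const double sc_ = wsum_pool / wsum_g;
        double shift = 0.0, scale = 1.0;
        for (int j = 0; j < pcur; ++j) {
          const double step_ = sc_ * grad[j];
          out[j] += step_;
          shift += std::fabs(step_);
          scale += std::fabs(out[j]);
        }
        if (shift < tol * scale) { done = true; break; }
        if (shift > 4.0 * prev_shift) break;  // diverging: fall back
        prev_shift = shift;
      }
    }
    if (!done && !newton_gm(X, n, pcur, rowsbuf, tol, 100, out)) {
      if (weiszfeld(X, n, pcur, rowsbuf, tol, maxit, out, &out) < 0)
        stop("Weiszfeld iteration failed to converge within %d iterations", maxit);
    }
  };

  // residual ANOVA F given the two group medians
  auto resid_F = [&](const double* X, int pcur, const int* grp,
                     const std::vector<double>& md0,
                     const std::vector<double>& md1) -> double {
    double s0_ = 0.0, s1_ = 0.0, ss0 = 0.0, ss1 = 0.0;
    int c0 = 0, c1 = 0;
    for (int i = 0; i < n; ++i) {
      const std::vector<double>& mu = (grp[i] == 0) ? md0 : md1;
      double d2 = 0.0;
      for (int j = 0; j < pcur; ++j) {
        const double diff = X[i + (size_t)j * n] - mu[j];
        d2 += diff * diff;
      }
      const double r_ = std::sqrt(d2);
      if (grp[i] == 0) { s0_ += r_; ss0 += r_ * r_; ++c0; }
      else { s1_ += r_; ss1 += r_ * r_; ++c1; }
    }
    const double m0 = s0_ / c0, m1 = s1_ / c1, mm = (s0_ + s1_) / n;
    const double ssb = c0 * (m0 - mm) * (m0 - mm) + c1 * (m1 - mm) * (m1 - mm);
    const double ssw = (ss0 - c0 * m0 * m0) + (ss1 - c1 * m1 * m1);
    const double den = ssw / (n - 2.0);
    if (den <= 0.0) return (ssb > 0.0) ? R_PosInf : 0.0;
    return ssb / den;
  };

  // ---- scaled combined-F for current subset (k cols of Xbuf) + column v ----
  // (v already written into Xbuf slot k); when `stash` the solved medians are
  // saved as warm starts for the next step
  auto eval_cf = [&](int k, bool stash) -> double {
    const int pcur = k + 1;
    const double* X = Xbuf.data();
    const double* v = X + (size_t)k * n;
    double sall = 0.0, qall = 0.0;
    for (int i = 0; i < n; ++i) { sall += v[i]; qall += v[i] * v[i]; }
    const double Tpair = Tbase + (n * qall - sall * sall);

    // location component: observed + permutation null
    double Floc = 0.0, sl = 0.0, sl2 = 0.0;
    for (int r = 0; r < ngrp; ++r) {
      const double f = permanova_cf(v, &Pt[(size_t)r * n], Bg[2 * (size_t)r],
                                    Bg[2 * (size_t)r + 1], cnt0[r], sall, qall,
                                    Tpair);
      if (r == 0) Floc = f;
      else { sl += f; sl2 += f * f; }
    }
    const double ml = sl / m;
    const double sdl = std::sqrt(std::max((sl2 - m * ml * ml) / (m - 1.0), 0.0));

    // dispersion component
    double Fdisp = 0.0, sD = 0.0, sD2 = 0.0;
    if (pcur == 1) {
      for (int r = 0; r < ngrp; ++r) {
        const double f = disp1d(v, &Pt[(size_t)r * n]);
        if (r == 0) Fdisp = f;
        else { sD += f; sD2 += f * f; }
      }
      if (stash) {
        std::vector<double> vv;
        for (int r = 0; r < ngrp; ++r) {
          const int* pr = &Pt[(size_t)r * n];
          for (int cls = 0; cls < 2; ++cls) {
            vv.clear();
            for (int i = 0; i < n; ++i) if (pr[i] == cls) vv.push_back(v[i]);
            (cls == 0 ? gmed0 : gmed1)[(size_t)r * ptree] = median1d(vv);
          }
        }
        vv.assign(v, v + n);
        pooled_full.assign(1, median1d(vv));
      }
    } else {
      // local Hessian at [pooled median of the base subset, mean of v],
      // factored once and reused by every group's chord iteration
      H.assign((size_t)pcur * pcur, 0.0);
      med.assign(pcur, 0.0);
      grad.assign(pcur, 0.0);
      for (int j = 0; j < k; ++j) med[j] = pooled_full[j];
      med[k] = sall / n;
      const double wsum_pool = gm_hessian(X, n, pcur, all_rows, med, H);
      const bool have_factor = chol_factor(H, pcur);

      for (int r = 0; r < ngrp; ++r) {
        const int* pr = &Pt[(size_t)r * n];
        // group means of v as the new-coordinate warm start
        double sv0 = 0.0;
        int c0 = 0;
        for (int i = 0; i < n; ++i) if (pr[i] == 0) { sv0 += v[i]; ++c0; }
        const double mv0 = sv0 / std::max(c0, 1);
        const double mv1 = (sall - sv0) / std::max(n - c0, 1);
        solve_group(X, pcur, pr, 0, &gmed0[(size_t)r * ptree], mv0,
                    wsum_pool, have_factor, med0buf);
        solve_group(X, pcur, pr, 1, &gmed1[(size_t)r * ptree], mv1,
                    wsum_pool, have_factor, med1buf);
        const double f = resid_F(X, pcur, pr, med0buf, med1buf);
        if (r == 0) Fdisp = f;
        else { sD += f; sD2 += f * f; }
        if (stash) {
          std::copy(med0buf.begin(), med0buf.end(), gmed0.begin() + (size_t)r * ptree);
          std::copy(med1buf.begin(), med1buf.end(), gmed1.begin() + (size_t)r * ptree);
        }
      }
      if (stash) {
        pooled_full.assign(pcur, 0.0);
        for (int j = 0; j < k; ++j) pooled_full[j] = med[j];
        pooled_full[k] = sall / n;
        if (!newton_gm(X, n, pcur, all_rows, tol, 100, pooled_full))
          weiszfeld(X, n, pcur, all_rows, tol, maxit, pooled_full, &pooled_full);
      }
    }
    const double md_ = sD / m;
    const double sdd = std::sqrt(std::max((sD2 - m * md_ * md_) / (m - 1.0), 0.0));

    if (!std::isfinite(ml) || !std::isfinite(sdl) || sdl == 0.0 ||
        !std::isfinite(md_) || !std::isfinite(sdd) || sdd == 0.0)
      stop("degenerate permutation null (zero or non-finite standard deviation)");
    return (Floc - ml) / sdl + (Fdisp - md_) / sdd;
  };

  // ---- main loop ----
  int nonimp = 0;
  double bestval = R_NegInf;
  while ((double)selected.size() < max_features) {
    const int k = (int)selected.size();
    // base within-pair sums per grouping for the location component
    if (kind == 1) {
      std::fill(Bg.begin(), Bg.end(), 0.0);
      if (k > 0) {
        for (int r = 0; r < ngrp; ++r) {
          const int* pr = &Pt[(size_t)r * n];
          double b0 = 0.0, b1 = 0.0;
          for (int j = 1; j < n; ++j) {
            const double* col = &baseD2[(size_t)n * j];
            const int gj = pr[j];
            for (int i = 0; i < j; ++i)
              if (pr[i] == gj) { if (gj == 0) b0 += col[i]; else b1 += col[i]; }
          }
          Bg[2 * (size_t)r] = b0;
          Bg[2 * (size_t)r + 1] = b1;
        }
      }
    }

    int chosen = -1;
    double chosenval = R_NegInf;
    bool any = false;
    for (int c = 0; c < ptree; ++c) {
      if (!inpool[c]) continue;
      const double* v = Z + (size_t)c * n;
      double val;
      if (kind == 1) {
        std::copy(v, v + n, Xbuf.begin() + (size_t)k * n);
        val = eval_cf(k, false);
      } else {
        val = eval_disco(v);
      }
      if (!any || val > chosenval ||
          (val == chosenval && name_rank[c] < name_rank[chosen])) {
        chosen = c;
        chosenval = val;
        any = true;
      }
      if (k == 0) break;  // initialization: take the highest-DCV tree ratio
    }
    if (!any) break;

    // accept the chosen candidate
    inpool[chosen] = 0;
    const double* v = Z + (size_t)chosen * n;
    std::copy(v, v + n, Xbuf.begin() + (size_t)k * n);
    if (kind == 1) eval_cf(k, true);  // stash warm starts for the next step
    for (int j = 1; j < n; ++j) {
      double* col = &baseD2[(size_t)n * j];
      const double vj = v[j];
      for (int i = 0; i < j; ++i) {
        const double diff = v[i] - vj;
        col[i] += diff * diff;
        Tbase += diff * diff;
      }
    }
    selected.push_back(chosen + 1);  // 1-based for R
    stepvals.push_back(chosenval);
    if (chosenval > bestval) {
      bestval = chosenval;
      nonimp = 0;
    } else {
      if (++nonimp >= patience) break;
    }
  }

  return List::create(_["selected"] = IntegerVector(selected.begin(), selected.end()),
                      _["values"] = NumericVector(stepvals.begin(), stepvals.end()));
}
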