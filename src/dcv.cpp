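#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Degenerate-denominator guard shared by all ratio-form components:
// denominators are floored at 1e-12; an exactly-zero numerator defines the
// component as 0 so constant logratios score 0 on every component.
static const double DEN_FLOOR = 1e-12;

static double guarded_ratio(double num, double den) {
  if (num == 0.0) return 0.0;
  return num / std::max(den, DEN_FLOOR);
}

// midpoint-of-two median for even n; sorts its argument in place
static double median_inplace(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  const size_t n = v.size();
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// two-sample Kolmogorov-Smirnov sup distance, inputs sorted ascending
static double ks_sorted(const std::vector<double>& a, const std::vector<double>& b) {
  const double na = (double)a.size(), nb = (double)b.size();
  size_t i = 0, j = 0;
  double d = 0.0;
  while (i < a.size() && j < b.size()) {
    const double x = std::min(a[i], b[j]);
    while (i < a.size() && a[i] <= x) ++i;
    while (j < b.size() && b[j] <= x) ++j;
    const double diff = std::fabs((double)i / na - (double)j / nb);
    if (diff > d) d = diff;
  }
  return d;
}

// natural-log entropy of a binary split with class counts c0, c1
static double ent2(double c0, double c1) {
  const double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  if (c0 > 0) h -= (c0 / n) * std::log(c0 / n);
  if (c1 > 0) h -= (c1 / n) * std::log(c1 / n);
  return h;
}

// Fayyad-Irani MDL recursive binary discretization on [lo, hi) of the sorted
// (x, y) arrays; accepted cut indices (split between i-1 and i) appended to
// `cuts`.  All entropies in nats; the MDL acceptance threshold is the
// classical one with every log rebased from bits to nats (rebasing multiplies
// both sides of the inequality by ln 2, so the decision is unchanged).
static void mdl_recurse(const std::vector<double>& x, const std::vector<int>& y,
                        int lo, int hi, std::vector<int>& cuts) {
  const int n = hi - lo;
  if (n < 4) return;
  int c1tot = 0;
  for (int i = lo; i < hi; ++i) c1tot += y[i];
  const int c0tot = n - c1tot;
  const double entS = ent2(c0tot, c1tot);
  if (entS == 0.0) return;

  int bestIdx = -1, bestC0l = 0, bestC1l = 0;
  double bestE = R_PosInf, bestEl = 0.0, bestEr = 0.0;
  int c1left = 0;
  for (int i = lo + 1; i < hi; ++i) {
    c1left += y[i - 1];
    if (!(x[i] > x[i - 1])) continue;  // no cut between tied values
    const int nl = i - lo, nr = hi - i;
    const int c1l = c1left, c0l = nl - c1l;
    const int c1r = c1tot - c1l, c0r = nr - c1r;
    const double el = ent2(c0l, c1l), er = ent2(c0r, c1r);
    const double e = ((double)nl / n) * el + ((double)nr / n) * er;
    if (e < bestE) {
      bestE = e; bestIdx = i;
      bestEl = el; bestEr = er; bestC0l = c0l; bestC1l = c1l;
    }
  }
  if (bestIdx < 0) return;

  const double gain = entS - bestE;
  const int k  = (c0tot > 0) + (c1tot > 0);
  const int kl = (bestC0l > 0) + (bestC1l > 0);
  const int kr = ((c0tot - bestC0l) > 0) + ((c1tot - bestC1l) > 0);
  const double delta = std::log(std::pow(3.0, k) - 2.0) -
                       (k * entS - kl * bestEl - kr * bestEr);
  if (gain <= (std::log((double)n - 1.0) + delta) / n) return;

  cuts.push_back(bestIdx);
  mdl_recurse(x, y, lo, bestIdx, cuts);
  mdl_recurse(x, y, bestIdx, hi, cuts);
}

// information gain of the class labels given the MDL-discretized attribute,
// falling back to a median split when MDL accepts no cut
static double info_gain_mdl(const std::vector<double>& x, const std::vector<int>& y) {
  const int n = (int)x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n);
  std::vector<int> ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = x[idx[i]]; ys[i] = y[idx[i]]; }

  int c1 = 0;
  for (int i = 0; i < n; ++i) c1 += ys[i];
  const double H = ent2(n - c1, c1);
  if (H == 0.0) return 0.0;

  std::vector<int> cuts;
  mdl_recurse(xs, ys, 0, n, cuts);

  double cond = 0.0;
  if (cuts.empty()) {
    const double med = (n % 2 == 1) ? xs[n / 2] : 0.5 * (xs[n / 2 - 1] + xs[n / 2]);
    int nl = 0, c1l = 0;
    for (int i = 0; i < n; ++i)
      if (xs[i] <= med) { ++nl; c1l += ys[i]; }
    if (nl == 0 || nl == n) return 0.0;  // constant attribute
    const int nr = n - nl, c1r = c1 - c1l;
    cond = ((double)nl / n) * ent2(nl - c1l, c1l) +
           ((double)nr / n) * ent2(nr - c1r, c1r);
  } else {
    std::sort(cuts.begin(), cuts.end());
    cuts.push_back(n);
    int lo = 0;
    for (int ci : cuts) {
      const int nb = ci - lo;
      int c1b = 0;
      for (int i = lo; i < ci; ++i) c1b += ys[i];
      cond += ((double)nb / n) * ent2(nb - c1b, c1b);
      lo = ci;
    }
  }
  const double ig = H - cond;
  return ig > 0.0 ? ig : 0.0;
}

//' @noRd
// [[Rcpp::export(name = ".dcv_components_cpp")]]
NumericMatrix dcv_components_cpp(NumericMatrix Z, IntegerVector y) {
  const int n = Z.nrow(), p = Z.ncol();
  std::vector<int> i0, i1;
  for (int i = 0; i < n; ++i) {
    if (y[i] == 0) i0.push_back(i); else i1.push_back(i);
  }
  const int n0 = (int)i0.size(), n1 = (int)i1.size();
  if (n0 < 2 || n1 < 2) stop("each class must contain at least 2 samples");

  NumericMatrix out(p, 5);
  std::vector<double> a0(n0), a1(n1);

  for (int j = 0; j < p; ++j) {
    double s0 = 0.0, s1 = 0.0;
    for (int i = 0; i < n0; ++i) { a0[i] = Z(i0[i], j); s0 += a0[i]; }
    for (int i = 0; i < n1; ++i) { a1[i] = Z(i1[i], j); s1 += a1[i]; }
    if (!std::isfinite(s0) || !std::isfinite(s1))
      stop("non-finite logratio values in column %d", j + 1);
    const double m0 = s0 / n0, m1 = s1 / n1, m = (s0 + s1) / n;

    double v0 = 0.0, v1 = 0.0;
    for (int i = 0; i < n0; ++i) v0 += (a0[i] - m0) * (a0[i] - m0);
    for (int i = 0; i < n1; ++i) v1 += (a1[i] - m1) * (a1[i] - m1);
    v0 /= (n0 - 1);
    v1 /= (n1 - 1);

    // component 1: |Welch t|
    out(j, 0) = guarded_ratio(std::fabs(m0 - m1), std::sqrt(v0 / n0 + v1 / n1));

    // component 2: mean-difference F with tau_c1 + tau_c2 denominator
    out(j, 1) = guarded_ratio(
        n0 * (m0 - m) * (m0 - m) + n1 * (m1 - m) * (m1 - m), v0 + v1);

    // component 3: Brown-Forsythe F (absolute deviations from class medians)
    {
      std::vector<double> t0(a0), t1(a1);
      const double med0 = median_inplace(t0), med1 = median_inplace(t1);
      std::vector<double> b0(n0), b1(n1);
      double bs0 = 0.0, bs1 = 0.0;
      for (int i = 0; i < n0; ++i) { b0[i] = std::fabs(a0[i] - med0); bs0 += b0[i]; }
      for (int i = 0; i < n1; ++i) { b1[i] = std::fabs(a1[i] - med1); bs1 += b1[i]; }
      const double bm0 = bs0 / n0, bm1 = bs1 / n1, bm = (bs0 + bs1) / n;
      const double num =
          n0 * (bm0 - bm) * (bm0 - bm) + n1 * (bm1 - bm) * (bm1 - bm);
      double den = 0.0;
      for (int i = 0; i < n0; ++i) den += (b0[i] - bm0) * (b0[i] - bm0);
      for (int i = 0; i < n1; ++i) den += (b1[i] - bm1) * (b1[i] - bm1);
      den /= (n0 + n1 - 2);
      out(j, 2) = guarded_ratio(num, den);
    }

    // component 4: two-sample KS sup distance between class ECDFs
    {
      std::vector<double> t0(a0), t1(a1);
      std::sort(t0.begin(), t0.end());
      std::sort(t1.begin(), t1.end());
      out(j, 3) = ks_sorted(t0, t1);
    }

    // component 5: information gain under MDL discretization
    {
      std::vector<double> xall(n);
      std::vector<int> yall(n);
      for (int i = 0; i < n0; ++i) { xall[i] = a0[i]; yall[i] = 0; }
      for (int i = 0; i < n1; ++i) { xall[n0 + i] = a1[i]; yall[n0 + i] = 1; }
      out(j, 4) = info_gain_mdl(xall, yall);
    }
  }
  return out;
}
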