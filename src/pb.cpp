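#include <Rcpp.h>
using namespace Rcpp;

// Poisson-binomial count distribution by sequential convolution.
// p: success probabilities; returns P(count = 0..n).
static std::vector<double> pbDist(const std::vector<double>& p) {
  std::vector<double> f(p.size() + 1, 0.0);
  f[0] = 1.0;
  for (size_t i = 0; i < p.size(); ++i) {
    for (size_t k = i + 1; k >= 1; --k) {
      f[k] = f[k] * (1.0 - p[i]) + f[k - 1] * p[i];
    }
    f[0] *= (1.0 - p[i]);
  }
  return f;
}

static double windowMass(const std::vector<double>& f, int lo, int hi) {
  double s = 0.0;
  int n = (int)f.size() - 1;
  if (lo < 0) lo = 0;
  if (hi > n) hi = n;
  for (int k = lo; k <= hi; ++k) s += f[k];
  return s;
}

// [[Rcpp::export(name = ".pbCountDistribution")]]
NumericVector pbCountDistribution(NumericVector p) {
  std::vector<double> pv(p.begin(), p.end());
  std::vector<double> f = pbDist(pv);
  return NumericVector(f.begin(), f.end());
}

// Conditional-expectation label update: for each i,
//   y_i = p_i * P(SL-1 <= X_{-i} <= SU-1) / P(SL <= X <= SU)
// with X the Poisson-binomial count over the batch and X_{-i} the
// leave-one-out count (recomputed without item i; exact, O(n^2) per batch).
// [[Rcpp::export(name = ".pbExpectationUpdate")]]
NumericVector pbExpectationUpdate(NumericVector p, int sl, int su) {
  int n = p.size();
  if (n == 0) stop("empty batch");
  if (sl < 0 || su < sl || su > n) stop("invalid count bounds");
  std::vector<double> pv(p.begin(), p.end());
  std::vector<double> full = pbDist(pv);
  double denom = windowMass(full, sl, su);
  if (denom <= 0.0)
    stop("infeasible constraint: the count window has zero probability");
  NumericVector y(n);
  std::vector<double> loo;
  loo.reserve(n);
  for (int i = 0; i < n; ++i) {
    loo.clear();
    for (int j = 0; j < n; ++j) if (j != i) loo.push_back(pv[j]);
    std::vector<double> fi = pbDist(loo);
    double num = windowMass(fi, sl - 1, su - 1);
    y[i] = pv[i] * num / denom;
    if (y[i] < 0.0) y[i] = 0.0;
    if (y[i] > 1.0) y[i] = 1.0;
  }
  return y;
}
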