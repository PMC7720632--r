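#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularised L1-loss (hinge) linear SVM,
// following the standard liblinear-style dual update.  The bias is absorbed
// as an augmented constant feature (and hence regularised).  Updates are
// cyclic with a projected-gradient stopping rule, so the solver is fully
// deterministic for a given input.
static void solve_dual(const std::vector<double>& X, // n x p, column-major
                       const std::vector<int>& y,    // +1 / -1
                       int n, int p, double C, double tol, int max_epochs,
                       std::vector<double>& alpha, std::vector<double>& w) {
  std::vector<double> Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) {
      double v = X[(size_t)j * n + i];
      s += v * v;
    }
    Qii[i] = s;
  }
  for (int ep = 0; ep < max_epochs; ++ep) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += w[j] * X[(size_t)j * n + i];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-14) {
        double a_old = alpha[i];
        double a_new = a_old - g / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        if (a_new != a_old) {
          double d = (a_new - a_old) * y[i];
          for (int j = 0; j < p; ++j) w[j] += d * X[(size_t)j * n + i];
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
}

// Leave-one-out cross-validated decision values for the linear SVM.
// Features are standardised inside each training fold (mean/SD of the
// n-1 retained samples); the held-out sample is scored on the trained
// hyperplane.  Folds are warm-started from the full-data dual solution.
// A degenerate fold (single-class training set) scores the held-out
// sample by the training class sign (the prior decision value).
// [[Rcpp::export]]
NumericVector svm_loocv_decision(NumericMatrix X, IntegerVector y,
                                 double C = 1.0, double tol = 0.05,
                                 int max_epochs = 150, int warm_epochs = 40) {
  const int n = X.nrow(), p = X.ncol(), pa = p + 1; // + bias column
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) {
    if (y[i] != 1 && y[i] != -1) stop("y must be coded +1/-1");
    yy[i] = y[i];
  }

  // column sums for O(p) fold-wise mean/SD updates
  std::vector<double> csum(p, 0.0), csum2(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      csum[j] += v;
      csum2[j] += v * v;
    }

  // full-data solve (for warm starts)
  std::vector<double> Xs((size_t)pa * n), alpha_full(n, 0.0), w(pa, 0.0);
  std::vector<double> mu(p), sd(p);
  for (int j = 0; j < p; ++j) {
    mu[j] = csum[j] / n;
    double v = (csum2[j] - n * mu[j] * mu[j]) / std::max(1, n - 1);
    sd[j] = v > 0 ? std::sqrt(v) : 1.0;
  }
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      Xs[(size_t)j * n + i] = (X(i, j) - mu[j]) / sd[j];
  for (int i = 0; i < n; ++i) Xs[(size_t)p * n + i] = 1.0; // bias
  solve_dual(Xs, yy, n, pa, C, tol, max_epochs, alpha_full, w);

  NumericVector dec(n);
  std::vector<double> Xf((size_t)pa * (n - 1)), af(n - 1), wf(pa);
  std::vector<int> yf(n - 1);
  for (int hold = 0; hold < n; ++hold) {
    const int m = n - 1;
    int npos = 0;
    for (int i = 0; i < n; ++i)
      if (i != hold && yy[i] > 0) ++npos;
    if (npos == 0 || npos == m) { // degenerate fold
      dec[hold] = (npos == m) ? 1.0 : -1.0;
      continue;
    }
    // fold-wise standardisation parameters (training samples only)
    std::vector<double> fmu(p), fsd(p);
    for (int j = 0; j < p; ++j) {
      double s = csum[j] - X(hold, j);
      double s2 = csum2[j] - X(hold, j) * X(hold, j);
      fmu[j] = s / m;
      double v = (s2 - m * fmu[j] * fmu[j]) / std::max(1, m - 1);
      fsd[j] = v > 1e-24 ? std::sqrt(v) : 1.0;
    }
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      yf[r] = yy[i];
      af[r] = alpha_full[i]; // warm start
      for (int j = 0; j < p; ++j)
        Xf[(size_t)j * m + r] = (X(i, j) - fmu[j]) / fsd[j];
      Xf[(size_t)p * m + r] = 1.0;
      ++r;
    }
    std::fill(wf.begin(), wf.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      if (af[i] == 0.0) continue;
      double d = af[i] * yf[i];
      for (int j = 0; j < pa; ++j) wf[j] += d * Xf[(size_t)j * m + i];
    }
    solve_dual(Xf, yf, m, pa, C, tol, warm_epochs, af, wf);
    // score without the intercept: the intercept tracks the training class
    // balance, which differs across folds by exactly the held-out label and
    // would leak it (biasing the null AUC below 0.5)
    double sc = 0.0;
    for (int j = 0; j < p; ++j) sc += wf[j] * (X(hold, j) - fmu[j]) / fsd[j];
    dec[hold] = sc;
  }
  return dec;
}

// Single linear-SVM fit on pre-scaled data; returns decision values for
// `Xnew`.  Exposed mainly for cross-checking against reference SVM
// implementations in the test-suite.
// [[Rcpp::export]]
NumericVector svm_fit_decision(NumericMatrix X, IntegerVector y,
                               NumericMatrix Xnew, double C = 1.0,
                               double tol = 1e-5, int max_epochs = 2000) {
  const int n = X.nrow(), p = X.ncol(), pa = p + 1;
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[i];
  std::vector<double> Xs((size_t)pa * n), alpha(n, 0.0), w(pa, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xs[(size_t)j * n + i] = X(i, j);
  for (int i = 0; i < n; ++i) Xs[(size_t)p * n + i] = 1.0;
  solve_dual(Xs, yy, n, pa, C, tol, max_epochs, alpha, w);
  NumericVector out(Xnew.nrow());
  for (int i = 0; i < Xnew.nrow(); ++i) {
    double s = w[p];
    for (int j = 0; j < p; ++j) s += w[j] * Xnew(i, j);
    out[i] = s;
  }
  return out;
}
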