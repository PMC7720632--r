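#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// k-sample log-rank machinery: observed minus expected event counts with
// the hypergeometric variance, accumulated over distinct event times.
// The chi-squared form drops groups with zero expected count, then removes
// one group and solves the reduced linear system (the same reduction the
// classical test uses, so values agree with standard implementations).

struct LogrankAccum {
  std::vector<double> obs, expd, var; // var is k x k, row-major
  int k;
};

// idx: indices sorted by ascending time
static void accumulate(const NumericVector& time, const IntegerVector& event,
                       const std::vector<int>& grp, int k,
                       const std::vector<int>& idx, LogrankAccum& acc) {
  const int n = time.size();
  acc.k = k;
  acc.obs.assign(k, 0.0);
  acc.expd.assign(k, 0.0);
  acc.var.assign((size_t)k * k, 0.0);
  std::vector<double> nrisk(k, 0.0);
  for (int i = 0; i < n; ++i) nrisk[grp[i]] += 1.0;
  double ntot = n;
  int i = 0;
  while (i < n) {
    double t = time[idx[i]];
    int j = i;
    std::vector<double> d(k, 0.0);
    double dtot = 0.0;
    while (j < n && time[idx[j]] == t) {
      if (event[idx[j]] == 1) {
        d[grp[idx[j]]] += 1.0;
        dtot += 1.0;
      }
      ++j;
    }
    if (dtot > 0.0 && ntot > 0.0) {
      for (int g = 0; g < k; ++g) {
        acc.obs[g] += d[g];
        acc.expd[g] += dtot * nrisk[g] / ntot;
      }
      if (ntot > 1.0) {
        double mult = dtot * (ntot - dtot) / (ntot - 1.0);
        for (int a = 0; a < k; ++a)
          for (int b = 0; b < k; ++b) {
            double del = (a == b) ? 1.0 : 0.0;
            acc.var[(size_t)a * k + b] +=
              mult * (nrisk[a] / ntot) * (del - nrisk[b] / ntot);
          }
      }
    }
    for (int m = i; m < j; ++m) {
      nrisk[grp[idx[m]]] -= 1.0;
      ntot -= 1.0;
    }
    i = j;
  }
}

// solve A x = b in place (small dense system, partial pivoting);
// returns false if singular
static bool solve_small(std::vector<double>& A, std::vector<double>& b, int m) {
  for (int c = 0; c < m; ++c) {
    int piv = c;
    for (int r = c + 1; r < m; ++r)
      if (std::fabs(A[(size_t)r * m + c]) > std::fabs(A[(size_t)piv * m + c]))
        piv = r;
    if (std::fabs(A[(size_t)piv * m + c]) < 1e-300) return false;
    if (piv != c) {
      for (int cc = 0; cc < m; ++cc)
        std::swap(A[(size_t)c * m + cc], A[(size_t)piv * m + cc]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < m; ++r) {
      double f = A[(size_t)r * m + c] / A[(size_t)c * m + c];
      if (f == 0.0) continue;
      for (int cc = c; cc < m; ++cc)
        A[(size_t)r * m + cc] -= f * A[(size_t)c * m + cc];
      b[r] -= f * b[c];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    double s = b[r];
    for (int cc = r + 1; cc < m; ++cc) s -= A[(size_t)r * m + cc] * b[cc];
    b[r] = s / A[(size_t)r * m + r];
  }
  return true;
}

static double chi2_from_accum(const LogrankAccum& acc) {
  int k = acc.k;
  std::vector<int> keep;
  for (int g = 0; g < k; ++g)
    if (acc.expd[g] > 0.0) keep.push_back(g);
  int m = (int)keep.size() - 1;
  if (m < 1) return 0.0;
  std::vector<double> A((size_t)m * m), b(m), x(m);
  for (int a = 0; a < m; ++a) {
    b[a] = acc.obs[keep[a + 1]] - acc.expd[keep[a + 1]];
    x[a] = b[a];
    for (int c = 0; c < m; ++c)
      A[(size_t)a * m + c] = acc.var[(size_t)keep[a + 1] * k + keep[c + 1]];
  }
  if (!solve_small(A, b, m)) return 0.0;
  double chi = 0.0;
  for (int a = 0; a < m; ++a) chi += b[a] * x[a];
  return chi;
}

static std::vector<int> order_by_time(const NumericVector& time) {
  std::vector<int> idx(time.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  return idx;
}

// [[Rcpp::export]]
List logrank_chi2_cpp(NumericVector time, IntegerVector event,
                      IntegerVector group, int k) {
  const int n = time.size();
  std::vector<int> grp(n);
  for (int i = 0; i < n; ++i) {
    if (group[i] < 1 || group[i] > k) stop("group codes must lie in 1..k");
    grp[i] = group[i] - 1;
  }
  std::vector<int> idx = order_by_time(time);
  LogrankAccum acc;
  accumulate(time, event, grp, k, idx, acc);
  double chi = chi2_from_accum(acc);
  return List::create(_["chi2"] = chi,
                      _["observed"] = NumericVector(acc.obs.begin(), acc.obs.end()),
                      _["expected"] = NumericVector(acc.expd.begin(), acc.expd.end()));
}

// Exhaustive search over ordered pairs of score cutpoints (c1 < c2 from a
// candidate grid) maximising the 3-group log-rank chi-squared, subject to a
// minimum per-group size.  Candidates are scanned in ascending (c1, c2)
// order and only strictly larger chi2 replaces the incumbent, so ties
// resolve to the smallest c1, then smallest c2.
// [[Rcpp::export]]
List cutpoint_grid_search(NumericVector time, IntegerVector event,
                          NumericVector score, NumericVector cuts,
                          int min_n) {
  const int n = time.size(), nc = cuts.size();
  std::vector<int> idx = order_by_time(time);
  std::vector<int> grp(n);
  double best_chi = -1.0, best_c1 = NA_REAL, best_c2 = NA_REAL;
  int best_n1 = 0, best_n2 = 0, best_n3 = 0;
  long n_eval = 0;
  LogrankAccum acc;
  for (int a = 0; a < nc - 1; ++a) {
    // group sizes below/above c1 never change with c2; precompute lower size
    int nlow = 0;
    for (int i = 0; i < n; ++i)
      if (score[i] <= cuts[a]) ++nlow;
    if (nlow < min_n) continue;
    if (n - nlow < 2 * min_n) break; // cuts ascending: only shrinks further
    for (int b = a + 1; b < nc; ++b) {
      int n1 = 0, n2 = 0, n3 = 0;
      for (int i = 0; i < n; ++i) {
        if (score[i] <= cuts[a]) { grp[i] = 0; ++n1; }
        else if (score[i] <= cuts[b]) { grp[i] = 1; ++n2; }
        else { grp[i] = 2; ++n3; }
      }
      if (n2 < min_n) continue;
      if (n3 < min_n) break; // larger b only shrinks the top group
      ++n_eval;
      accumulate(time, event, grp, 3, idx, acc);
      double chi = chi2_from_accum(acc);
      if (chi > best_chi) {
        best_chi = chi;
        best_c1 = cuts[a];
        best_c2 = cuts[b];
        best_n1 = n1; best_n2 = n2; best_n3 = n3;
      }
    }
  }
  return List::create(_["chi2"] = best_chi, _["c1"] = best_c1, _["c2"] = best_c2,
                      _["n1"] = best_n1, _["n2"] = best_n2, _["n3"] = best_n3,
                      _["n_evaluated"] = (double)n_eval);
}
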