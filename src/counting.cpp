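#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Joint coincidence count of two spike-count series at a single lag.
// Equals the sum over matched binary layers, which collapses to
// sum_t min(a_t, b_{t+l}); lag may be negative (b leading a).
static double joint_count_one(const int* a, const int* b, int T, int lag) {
  double s = 0.0;
  if (lag >= 0) {
    for (int t = 0; t < T - lag; ++t) s += std::min(a[t], b[t + lag]);
  } else {
    for (int t = 0; t < T + lag; ++t) s += std::min(a[t - lag], b[t]);
  }
  return s;
}

// [[Rcpp::export(name = ".cpp_joint_count")]]
double cpp_joint_count(IntegerVector a, IntegerVector b, int lag) {
  int T = a.size();
  return joint_count_one(INTEGER(a), INTEGER(b), T, lag);
}

// Joint counts for every lag in -lmax..lmax (the cross-correlogram of the
// layer-matched counts). Hot path of pair screening.
// [[Rcpp::export(name = ".cpp_lag_profile")]]
NumericVector cpp_lag_profile(IntegerVector a, IntegerVector b, int lmax) {
  int T = a.size();
  NumericVector out(2 * lmax + 1);
  for (int l = -lmax; l <= lmax; ++l)
    out[l + lmax] = joint_count_one(INTEGER(a), INTEGER(b), T, l);
  return out;
}

// Layer totals (#X^alpha, alpha = 1..M) of a count series on bins
// [from, to] (1-based, inclusive): number of bins with count >= alpha.
static std::vector<double> layer_totals_range(const int* x, int from, int to,
                                              int& maxc) {
  maxc = 0;
  for (int t = from; t <= to; ++t) maxc = std::max(maxc, x[t]);
  std::vector<double> tot(maxc, 0.0);
  for (int t = from; t <= to; ++t)
    for (int al = 0; al < x[t]; ++al) tot[al] += 1.0;
  return tot;
}

// Multivariate-hypergeometric variance of the joint count given layer
// totals on a window of length n:
//   sum_a  A_a B_a (n-A_a)(n-B_a) / (n^2 (n-1))
// + 2 sum_{a<g} A_g B_g (n-A_a)(n-B_a) / (n^2 (n-1))
static double hyper_var(const std::vector<double>& A,
                        const std::vector<double>& B, double n) {
  int M = std::min(A.size(), B.size());
  if (M == 0 || n < 2.0) return 0.0;
  double acc = 0.0, cumF = 0.0;
  for (int g = 0; g < M; ++g) {
    double Fg = (n - A[g]) * (n - B[g]);
    double Wg = A[g] * B[g];
    acc += Wg * (Fg + 2.0 * cumF);
    cumF += Fg;
  }
  return acc / (n * n * (n - 1.0));
}

// Segmented variance of the corrected difference count
// #ABBA = #AB,sel - #AB,ref:
//   sigma^2 = 2 sum_c var_c - 2 sum_c cov_c,
// with var_c the within-segment hypergeometric variance (window length ->
// segment length) and cov_c = -var_c / (k_c - 1), the exact within-segment
// forward/reverse covariance under the permutation null.
// seg_start/seg_end are 1-based inclusive bin indices.
// [[Rcpp::export(name = ".cpp_segmented_variance")]]
double cpp_segmented_variance(IntegerVector a, IntegerVector b,
                              IntegerVector seg_start, IntegerVector seg_end) {
  int C = seg_start.size();
  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  double tot = 0.0;
  for (int c = 0; c < C; ++c) {
    int from = seg_start[c] - 1, to = seg_end[c] - 1;
    double k = to - from + 1;
    if (k < 2) continue;
    int ma, mb;
    std::vector<double> A = layer_totals_range(pa, from, to, ma);
    std::vector<double> B = layer_totals_range(pb, from, to, mb);
    if (ma == 0 || mb == 0) continue;  // silent unit in segment
    double v = hyper_var(A, B, k);
    double cv = -v / (k - 1.0);
    tot += 2.0 * v - 2.0 * cv;
  }
  return tot;
}

// Per-bin assembly activation series under the matched-layer rule:
// act[t] = min_j counts[t + lag_j, unit_j], zero where the constellation
// runs past the end of the recording. counts is the T x N bin matrix.
// [[Rcpp::export(name = ".cpp_assembly_series")]]
IntegerVector cpp_assembly_series(IntegerMatrix counts, IntegerVector units,
                                  IntegerVector lags) {
  int T = counts.nrow(), n = units.size();
  int maxlag = 0;
  for (int j = 0; j < n; ++j) maxlag = std::max(maxlag, lags[j]);
  IntegerVector out(T);
  for (int t = 0; t < T - maxlag; ++t) {
    int m = counts(t + lags[0], units[0] - 1);
    for (int j = 1; j < n && m > 0; ++j)
      m = std::min(m, counts(t + lags[j], units[j] - 1));
    out[t] = m;
  }
  return out;
}

// Greedy refractory dead-time filter: keep a spike only if it is at least
// tau after the previously kept spike.
// [[Rcpp::export(name = ".cpp_dead_time_filter")]]
NumericVector cpp_dead_time_filter(NumericVector times, double tau) {
  int n = times.size();
  std::vector<double> keep;
  keep.reserve(n);
  double last = -1e300;
  for (int i = 0; i < n; ++i) {
    if (times[i] - last >= tau) {
      keep.push_back(times[i]);
      last = times[i];
    }
  }
  return wrap(keep);
}
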