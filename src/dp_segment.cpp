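#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized least-squares change-point segmentation of a bivariate
// track (LogR everywhere, mirrored BAF on informative probes only).
//
// Minimizes, over all segmentations with segments of at least min_len probes,
//   sum_k [ wl * SSE_logr(seg_k) + wb * SSE_mbaf(seg_k) ] + penalty * (K - 1)
// where SSE is the within-segment sum of squared deviations from the segment
// mean and K the number of segments.  Solved by O(n^2) dynamic programming;
// mbaf entries that are NA contribute nothing.
//
// [[Rcpp::export]]
IntegerVector dp_segment_core(NumericVector y, NumericVector b,
                              double wl, double wb,
                              double penalty, int min_len) {
  const int n = y.size();
  if (n < min_len) stop("fewer probes than min_len");

  // prefix sums (index 0 = empty)
  std::vector<double> sy(n + 1, 0.0), sy2(n + 1, 0.0);
  std::vector<double> sb(n + 1, 0.0), sb2(n + 1, 0.0);
  std::vector<int> cb(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    sy[i + 1] = sy[i] + y[i];
    sy2[i + 1] = sy2[i] + y[i] * y[i];
    bool obs = !NumericVector::is_na(b[i]);
    sb[i + 1] = sb[i] + (obs ? b[i] : 0.0);
    sb2[i + 1] = sb2[i] + (obs ? b[i] * b[i] : 0.0);
    cb[i + 1] = cb[i] + (obs ? 1 : 0);
  }

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> F(n + 1, INF);
  std::vector<int> arg(n + 1, 0);
  F[0] = 0.0;

  // cost of probes (i, j] in prefix terms, i < j
  auto seg_cost = [&](int i, int j) -> double {
    int m = j - i;
    double s = sy[j] - sy[i];
    double c = wl * ((sy2[j] - sy2[i]) - s * s / m);
    int mb = cb[j] - cb[i];
    if (mb > 0) {
      double t = sb[j] - sb[i];
      c += wb * ((sb2[j] - sb2[i]) - t * t / mb);
    }
    return c;
  };

  for (int j = min_len; j <= n; ++j) {
    double best = F[0] + seg_cost(0, j);  // single-segment option, no penalty
    int besti = 0;
    for (int i = min_len; i <= j - min_len; ++i) {
      if (F[i] == INF) continue;
      double c = F[i] + seg_cost(i, j) + penalty;
      if (c < best - 1e-12) { best = c; besti = i; }
    }
    F[j] = best;
    arg[j] = besti;
  }

  // backtrack to segment end indices (1-based, increasing)
  std::vector<int> ends;
  int j = n;
  while (j > 0) {
    ends.push_back(j);
    j = arg[j];
  }
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
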