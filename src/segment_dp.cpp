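#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized least-squares segmentation of an ordered signal.
//
// Minimizes  sum_k SSE(segment_k) + penalty * K  over all partitions of
// x[0..n-1] into K contiguous segments, by O(n^2) dynamic programming on
// prefix sums. SSE of x[i..j] is computed as S2 - S^2/len, which is exact
// up to floating rounding and never negative beyond that rounding.
//
// Returns the 1-based end index of every segment (last element is n).
// [[Rcpp::export]]
IntegerVector dp_segment_ends(NumericVector x, double penalty) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i])) stop("non-finite value in segmentation input");
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  // F[j] = minimal cost of segmenting x[0..j-1]; F[0] = 0
  std::vector<double> F(n + 1, 0.0);
  std::vector<int> back(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    double best = R_PosInf;
    int arg = 0;
    for (int i = 0; i < j; ++i) {
      // segment x[i..j-1]
      double s = cs[j] - cs[i];
      double s2 = cs2[j] - cs2[i];
      double len = j - i;
      double sse = s2 - s * s / len;
      if (sse < 0) sse = 0; // guard rounding
      double cost = F[i] + sse + penalty;
      if (cost < best) { // strict: earliest change-point wins ties
        best = cost;
        arg = i;
      }
    }
    F[j] = best;
    back[j] = arg;
  }
  std::vector<int> ends;
  for (int j = n; j > 0; j = back[j]) ends.push_back(j);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
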