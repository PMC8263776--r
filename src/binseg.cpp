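#include <Rcpp.h>
using namespace Rcpp;

// Recursive binary segmentation of a 1-D signal into piecewise-constant
// plateaus. A split is kept only when it lowers the residual sum of squares
// by more than `threshold` (a BIC-type penalty computed by the caller from
// the noise variance and trace length). Cumulative sums make each split
// search O(segment length).
static void segment_rec(const std::vector<double>& cs,
                        const std::vector<double>& cs2,
                        int lo, int hi, double threshold, int min_seg,
                        std::vector<int>& out) {
  int n = hi - lo;
  if (n < 2 * min_seg) return;
  double sum_all = cs[hi] - cs[lo];
  double rss_all = (cs2[hi] - cs2[lo]) - sum_all * sum_all / n;
  double best = R_PosInf;
  int best_split = -1;
  for (int s = lo + min_seg; s <= hi - min_seg; ++s) {
    int nl = s - lo, nr = hi - s;
    double sl = cs[s] - cs[lo], sr = cs[hi] - cs[s];
    double rss = (cs2[s] - cs2[lo] - sl * sl / nl) +
                 (cs2[hi] - cs2[s] - sr * sr / nr);
    if (rss < best) { best = rss; best_split = s; }
  }
  if (best_split < 0 || !(rss_all - best > threshold)) return;
  segment_rec(cs, cs2, lo, best_split, threshold, min_seg, out);
  out.push_back(best_split);
  segment_rec(cs, cs2, best_split, hi, threshold, min_seg, out);
}

// [[Rcpp::export]]
IntegerVector binseg_changepoints(NumericVector y, double threshold,
                                  int min_seg) {
  int n = y.size();
  // centre on the mean: makes the fit exactly invariant to constant offsets
  // and keeps the cumulative squares well conditioned
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += y[i];
  m /= n;
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double v = y[i] - m;
    cs[i + 1] = cs[i] + v;
    cs2[i + 1] = cs2[i] + v * v;
  }
  std::vector<int> out;
  segment_rec(cs, cs2, 0, n, threshold, min_seg, out);
  // convert to 1-based index of the first frame of the new plateau
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}
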