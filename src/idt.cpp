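#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Greedy dispersion-threshold (I-DT) scan over one recording segment.
//
// Dispersion of a window is the maximum pairwise Euclidean distance of its
// samples (the "diameter" of the fixation area).  Starting at sample s, the
// window grows rightwards while its dispersion stays within `diameter`
// (the dispersion is monotone under growth, so the incremental update
// against the newly added point is exact).  A maximal window of duration at
// least `min_duration` becomes a fixation and the scan resumes after it;
// otherwise the start advances by one sample (classic I-DT tie-break), and
// the too-short window is counted as a false fixation when it has at least
// two samples, duration at most `false_fixation_max_duration`, and extends
// past the previously counted one (so overlapping rescans are not
// double-counted).
//
// [[Rcpp::export]]
List idt_scan(NumericVector t, NumericVector x, NumericVector y,
              double diameter, double min_duration,
              double false_fixation_max_duration) {
  const int n = t.size();
  std::vector<int> fs, fe;
  std::vector<double> fdisp;
  int false_count = 0;
  int last_false_end = -1;
  int s = 0;
  while (s < n) {
    int e = s;
    double disp = 0.0;
    while (e + 1 < n) {
      double m = 0.0;
      const double xn = x[e + 1], yn = y[e + 1];
      for (int i = s; i <= e; ++i) {
        const double dx = xn - x[i], dy = yn - y[i];
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d > m) m = d;
      }
      if ((m > disp ? m : disp) <= diameter) {
        if (m > disp) disp = m;
        ++e;
      } else {
        break;
      }
    }
    const double dur = t[e] - t[s];
    if (dur >= min_duration) {
      fs.push_back(s + 1);   // 1-based for R
      fe.push_back(e + 1);
      fdisp.push_back(disp);
      s = e + 1;
    } else {
      if (e > s && dur <= false_fixation_max_duration && e > last_false_end) {
        ++false_count;
        last_false_end = e;
      }
      ++s;
    }
  }
  return List::create(_["start"] = wrap(fs), _["end"] = wrap(fe),
                      _["dispersion"] = wrap(fdisp),
                      _["false_fixations"] = false_count);
}
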