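#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of each contiguous block of x. starts are 0-based block offsets,
// sizes the block lengths; x must already be ordered so that the sgRNAs of
// each gene form one block. Called once per permutation, so it is the hot
// loop of the null construction.
// [[Rcpp::export]]
NumericVector group_medians_cpp(NumericVector x, IntegerVector starts,
                                IntegerVector sizes) {
  const int g_total = starts.size();
  NumericVector out(g_total);
  std::vector<double> buf;
  for (int g = 0; g < g_total; ++g) {
    const int n = sizes[g];
    const int s = starts[g];
    buf.assign(x.begin() + s, x.begin() + s + n);
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      // even cardinality: midpoint of the two central order statistics
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[g] = m;
  }
  return out;
}
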