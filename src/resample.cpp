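#include <Rcpp.h>
using namespace Rcpp;

// Row-wise linear resampling: out[y, x] = frame[y, x + shift[y, x]] with
// linear interpolation between neighbouring columns; samples outside the
// frame take `fill`. Positions are 1-based pixel centers on the R side.
// [[Rcpp::export(name = ".resample_rows_cpp")]]
NumericMatrix resample_rows_cpp(const NumericMatrix& frame,
                                const NumericMatrix& shift,
                                double fill) {
  const int n = frame.nrow(), m = frame.ncol();
  NumericMatrix out(n, m);
  for (int x = 0; x < m; ++x) {
    for (int y = 0; y < n; ++y) {
      // 0-based sample position along the row
      double q = x + shift(y, x);
      if (q < 0.0 || q > m - 1.0) {
        out(y, x) = fill;
        continue;
      }
      int i0 = static_cast<int>(std::floor(q));
      if (i0 >= m - 1) i0 = m - 2; // exact right edge
      double frac = q - i0;
      out(y, x) = frame(y, i0) * (1.0 - frac) + frame(y, i0 + 1) * frac;
    }
  }
  return out;
}
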