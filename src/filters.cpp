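#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rectangular median filter with edge replication. kh, kw must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_rect(NumericMatrix img, int kh, int kw) {
  if (kh < 1 || kw < 1 || kh % 2 == 0 || kw % 2 == 0)
    stop("window sizes must be odd and >= 1");
  const int nr = img.nrow(), nc = img.ncol();
  const int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(kh * kw);
  const int m = kh * kw;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -rw; dj <= rw; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        const double* col = &img(0, jj);
        for (int di = -rh; di <= rh; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf[k++] = col[ii];
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                         buf.begin() + m / 2);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
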