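#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mirror-with-edge-duplication boundary: (d c b a | a b c d | d c b a).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable correlation with centered odd-length kernels and reflective
// boundaries. kRow runs down image rows, kCol across columns.
// [[Rcpp::export]]
arma::mat cpp_sepfilter(const arma::mat& x,
                        const arma::vec& kRow,
                        const arma::vec& kCol) {
  const int h = x.n_rows, w = x.n_cols;
  const int rr = ((int)kRow.n_elem - 1) / 2;
  const int rc = ((int)kCol.n_elem - 1) / 2;
  mat tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int u = -rr; u <= rr; ++u)
        s += kRow[u + rr] * x(reflect_idx(i + u, h), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int v = -rc; v <= rc; ++v)
        s += kCol[v + rc] * tmp(i, reflect_idx(j + v, w));
      out(i, j) = s;
    }
  return out;
}

// Dense 2D correlation with a centered odd-sized kernel, reflective boundary.
// [[Rcpp::export]]
arma::mat cpp_filter2(const arma::mat& x, const arma::mat& k) {
  const int h = x.n_rows, w = x.n_cols;
  const int rr = ((int)k.n_rows - 1) / 2;
  const int rc = ((int)k.n_cols - 1) / 2;
  mat out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int u = -rr; u <= rr; ++u) {
        const int ii = reflect_idx(i + u, h);
        for (int v = -rc; v <= rc; ++v)
          s += k(u + rr, v + rc) * x(ii, reflect_idx(j + v, w));
      }
      out(i, j) = s;
    }
  return out;
}

// Square median filter, window odd, reflective boundary.
// [[Rcpp::export]]
arma::mat cpp_median_filter(const arma::mat& x, int window) {
  const int h = x.n_rows, w = x.n_cols;
  const int r = (window - 1) / 2;
  const int m = window * window;
  mat out(h, w);
  std::vector<double> buf(m);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int t = 0;
      for (int u = -r; u <= r; ++u) {
        const int ii = reflect_idx(i + u, h);
        for (int v = -r; v <= r; ++v)
          buf[t++] = x(ii, reflect_idx(j + v, w));
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double hi = buf[m / 2];
      out(i, j) = hi;  // m is odd (window odd), exact median
    }
  return out;
}
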