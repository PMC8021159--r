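#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

// im2col for a HxWxC cube with zero padding. Row r = spatial position
// (i + j*H, column-major), column index = ((c * kh + u) * kw + v).
static mat im2col(const cube& x, int kh, int kw, int pt, int pl) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  mat M(h * w, kh * kw * c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const mat& sl = x.slice(ch);
    for (int u = 0; u < kh; ++u) {
      for (int v = 0; v < kw; ++v) {
        const int col = (ch * kh + u) * kw + v;
        for (int j = 0; j < w; ++j) {
          const int sj = j + v - pl;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            const int si = i + u - pt;
            if (si < 0 || si >= h) continue;
            M(i + j * h, col) = sl(si, sj);
          }
        }
      }
    }
  }
  return M;
}

static cube col2im(const mat& D, int h, int w, int c,
                   int kh, int kw, int pt, int pl) {
  cube out(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    mat& sl = out.slice(ch);
    for (int u = 0; u < kh; ++u) {
      for (int v = 0; v < kw; ++v) {
        const int col = (ch * kh + u) * kw + v;
        for (int j = 0; j < w; ++j) {
          const int sj = j + v - pl;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            const int si = i + u - pt;
            if (si < 0 || si >= h) continue;
            sl(si, sj) += D(i + j * h, col);
          }
        }
      }
    }
  }
  return out;
}

// Same-padded biased convolution (correlation), optional fused ReLU.
// W is (kh*kw*Cin) x Cout, rows ordered as in im2col above.
// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int kh, int kw,
                        int pt, int pl, bool relu) {
  const int h = x.n_rows, w = x.n_cols;
  const int f = W.n_cols;
  mat O = im2col(x, kh, kw, pt, pl) * W;
  O.each_row() += b.t();
  if (relu) O.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube out(h, w, f);
  std::memcpy(out.memptr(), O.memptr(), sizeof(double) * O.n_elem);
  return out;
}

// Backward pass; `out` is the forward activation (used for the ReLU mask).
// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& W,
                        const arma::cube& out, const arma::cube& gout,
                        int kh, int kw, int pt, int pl, bool relu) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int f = W.n_cols;
  mat G(h * w, f);
  std::memcpy(G.memptr(), gout.memptr(), sizeof(double) * G.n_elem);
  if (relu) {
    mat O(h * w, f);
    std::memcpy(O.memptr(), out.memptr(), sizeof(double) * O.n_elem);
    G %= conv_to<mat>::from(O > 0.0);
  }
  mat M = im2col(x, kh, kw, pt, pl);
  mat dW = M.t() * G;
  vec db = sum(G, 0).t();
  cube dx = col2im(G * W.t(), h, w, cin, kh, kw, pt, pl);
  return List::create(Rcpp::Named("dW") = dW,
                      Rcpp::Named("db") = db,
                      Rcpp::Named("dx") = dx);
}

// 2x2 max pooling (stride 2); records flat argmax indices for backward.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = h / 2, ow = w / 2;
  cube out(oh, ow, c);
  cube amax(oh, ow, c);  // flat input indices stored as doubles (exact)
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -datum::inf; double bi = 0;
        for (int v = 0; v < 2; ++v)
          for (int u = 0; u < 2; ++u) {
            const int si = 2 * i + u, sj = 2 * j + v;
            const double val = x(si, sj, ch);
            if (val > best) { best = val; bi = si + sj * h + ch * h * w; }
          }
        out(i, j, ch) = best;
        amax(i, j, ch) = bi;
      }
  return List::create(Rcpp::Named("out") = out,
                      Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& g, const arma::cube& amax,
                           int h, int w) {
  const int c = g.n_slices;
  cube out(h, w, c, fill::zeros);
  double* p = out.memptr();
  for (uword t = 0; t < g.n_elem; ++t)
    p[(uword)amax(t)] += g(t);
  return out;
}

// 2x2 nearest-neighbour upsampling.
// [[Rcpp::export]]
arma::cube cpp_upsample_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube out(2 * h, 2 * w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double v = x(i, j, ch);
        out(2 * i, 2 * j, ch) = v;
        out(2 * i + 1, 2 * j, ch) = v;
        out(2 * i, 2 * j + 1, ch) = v;
        out(2 * i + 1, 2 * j + 1, ch) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bwd(const arma::cube& g) {
  const int oh = g.n_rows / 2, ow = g.n_cols / 2, c = g.n_slices;
  cube out(oh, ow, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i)
        out(i, j, ch) = g(2 * i, 2 * j, ch) + g(2 * i + 1, 2 * j, ch) +
                        g(2 * i, 2 * j + 1, ch) + g(2 * i + 1, 2 * j + 1, ch);
  return out;
}
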