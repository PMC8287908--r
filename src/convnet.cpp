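#include <Rcpp.h>
using namespace Rcpp;

// Pooling and upsampling primitives on (H*W) x C activation matrices with
// column-major pixel order: pixel (r, c) (0-based) lives at row c*H + r.

// 2x2 max pooling (stride 2). Returns pooled activations and the flat index of
// each argmax for the backward pass. H and W must be even.
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& x, int H, int W) {
  int C = x.ncol(), H2 = H / 2, W2 = W / 2;
  NumericMatrix out(H2 * W2, C);
  IntegerMatrix idx(H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* px = &x(0, ch);
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        int best = -1;
        double bv = -std::numeric_limits<double>::infinity();
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            int i = (2 * c + dc) * H + 2 * r + dr;
            if (px[i] > bv) { bv = px[i]; best = i; }
          }
        }
        out(c * H2 + r, ch) = bv;
        idx(c * H2 + r, ch) = best;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bwd(const NumericMatrix& g, const IntegerMatrix& idx,
                           int H, int W) {
  int C = g.ncol(), n = g.nrow();
  NumericMatrix out(H * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int i = 0; i < n; ++i)
      out(idx(i, ch), ch) += g(i, ch);
  return out;
}

// Nearest-neighbour 2x upsampling: (H x W) -> (2H x 2W).
// [[Rcpp::export]]
NumericMatrix upsample2(const NumericMatrix& x, int H, int W) {
  int C = x.ncol(), H2 = 2 * H;
  NumericMatrix out(4 * H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* px = &x(0, ch);
    double* po = &out(0, ch);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double v = px[c * H + r];
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr)
            po[(2 * c + dc) * H2 + 2 * r + dr] = v;
      }
    }
  }
  return out;
}

// Adjoint of upsample2: sum each 2x2 group of the (2H x 2W) gradient.
// [[Rcpp::export]]
NumericMatrix upsample2_bwd(const NumericMatrix& g, int H, int W) {
  int C = g.ncol(), H2 = 2 * H;
  NumericMatrix out(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* pg = &g(0, ch);
    double* po = &out(0, ch);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double s = 0.0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr)
            s += pg[(2 * c + dc) * H2 + 2 * r + dr];
        po[c * H + r] = s;
      }
    }
  }
  return out;
}
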