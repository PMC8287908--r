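// Fused single-precision convolution kernels. Activations cross the R/C++
// boundary as double matrices ((H*W) x C, column-major pixel order) but all
// heavy lifting — im2col unrolling and the GEMMs — runs in float32, the
// customary precision for convolutional network training. The backward pass
// recomputes the im2col matrix from the cached layer input instead of
// holding it in memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat to_f(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* p = x.begin();
  float* q = out.memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericMatrix to_d(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  double* p = out.begin();
  const float* q = x.memptr();
  const size_t n = (size_t)x.n_rows * x.n_cols;
  for (size_t i = 0; i < n; ++i) p[i] = (double)q[i];
  return out;
}

// 3x3 zero-padded neighbourhood unrolling; tap order k = ch*9+(dc+1)*3+(dr+1).
static void im2col_f(const arma::fmat& x, int H, int W, arma::fmat& cols) {
  const int C = x.n_cols;
  cols.zeros((size_t)H * W, 9 * C);
  for (int ch = 0; ch < C; ++ch) {
    const float* px = x.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        float* po = cols.colptr(ch * 9 + (dc + 1) * 3 + (dr + 1));
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
          for (int r = rlo; r < rhi; ++r)
            po[c * H + r] = px[cs * H + r + dr];
        }
      }
    }
  }
}

static void col2im_f(const arma::fmat& g, int H, int W, arma::fmat& out) {
  const int C = g.n_cols / 9;
  out.zeros((size_t)H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    float* po = out.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const float* pg = g.colptr(ch * 9 + (dc + 1) * 3 + (dr + 1));
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
          for (int r = rlo; r < rhi; ++r)
            po[cs * H + r + dr] += pg[c * H + r];
        }
      }
    }
  }
}

// Forward "same" 3x3 convolution with bias and optional ReLU.
// [[Rcpp::export]]
NumericMatrix conv3_fwd(const NumericMatrix& x, const NumericMatrix& Wm,
                        const NumericVector& b, int H, int W, bool relu) {
  arma::fmat xf = to_f(x), wf = to_f(Wm);
  arma::fmat cols;
  im2col_f(xf, H, W, cols);
  arma::fmat pre = cols * wf;
  arma::frowvec bf(pre.n_cols);
  for (arma::uword j = 0; j < pre.n_cols; ++j) bf(j) = (float)b[j];
  pre.each_row() += bf;
  if (relu) pre.for_each([](float& v) { if (v < 0) v = 0; });
  return to_d(pre);
}

// Backward pass; `out` is the forward output (its zeros encode the ReLU
// mask). Returns weight/bias gradients and the input gradient.
// [[Rcpp::export]]
List conv3_bwd(const NumericMatrix& x, const NumericMatrix& Wm,
               const NumericMatrix& out, const NumericMatrix& dout,
               int H, int W, bool relu) {
  arma::fmat xf = to_f(x), wf = to_f(Wm), df = to_f(dout);
  if (relu) {
    const arma::fmat of = to_f(out);
    df.elem(arma::find(of <= 0)).zeros();
  }
  arma::fmat cols;
  im2col_f(xf, H, W, cols);
  arma::fmat gW = cols.t() * df;
  arma::frowvec gb = arma::sum(df, 0);
  arma::fmat dcols = df * wf.t();
  arma::fmat dx;
  col2im_f(dcols, H, W, dx);
  return List::create(_["gW"] = to_d(gW),
                      _["gb"] = NumericVector(gb.begin(), gb.end()),
                      _["dx"] = to_d(dx));
}

// y[, j] = x[, j] * g[j] — channel scaling used by squeeze-excitation gates
// and spatial dropout masks.
// [[Rcpp::export]]
NumericMatrix colscale(const NumericMatrix& x, const NumericVector& g) {
  NumericMatrix out(x.nrow(), x.ncol());
  const int n = x.nrow();
  for (int j = 0; j < x.ncol(); ++j) {
    const double gj = g[j];
    const double* p = &x(0, j);
    double* q = &out(0, j);
    for (int i = 0; i < n; ++i) q[i] = p[i] * gj;
  }
  return out;
}
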