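// Low-level numerical kernels for the CNN engine and classical filters.
//
// Feature maps are stored as R numeric matrices with C rows (channels) and
// N = D*H*W columns (spatial positions, index n = d*H*W + h*W + w). This
// makes a channel vector at one spatial position contiguous in memory, so
// im2col reduces to block copies and convolution to one GEMM per layer.
// Computation runs in single precision internally; interfaces are double.
//
// Convolutions are stride-1, zero-padded "same"; kernel sides are odd.
// Pooling/upsampling act in-plane (H, W) only: stacks keep their depth.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::fmat as_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static inline NumericMatrix as_rmat(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  double* dst = out.begin();
  const R_xlen_t n = (R_xlen_t)x.n_rows * x.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// Gather the im2col matrix: K x N with K = C*kd*kh*kw, rows grouped as
// [kernel-offset][channel] so that weight rows match layout
// w[cout, o*C + cin].
static arma::fmat im2col(const arma::fmat& x, int C, int D, int H, int W,
                         int kd, int kh, int kw) {
  const int N = D * H * W;
  const int kk = kd * kh * kw;
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  arma::fmat cols(C * kk, N, arma::fill::zeros);
  for (int od = 0; od < kd; ++od) {
    for (int oh = 0; oh < kh; ++oh) {
      for (int ow = 0; ow < kw; ++ow) {
        const int o = (od * kh + oh) * kw + ow;
        for (int d = 0; d < D; ++d) {
          const int sd = d + od - pd;
          if (sd < 0 || sd >= D) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + oh - ph;
            if (sh < 0 || sh >= H) continue;
            const int sw0 = ow - pw;
            int w0 = std::max(0, -sw0);
            int w1 = std::min(W, W - sw0);
            if (w0 >= w1) continue;
            // contiguous run over w
            const float* src = x.colptr((sd * H + sh) * W + (w0 + sw0));
            float* dst = cols.colptr((d * H + h) * W + w0) + o * C;
            for (int w = w0; w < w1; ++w) {
              std::memcpy(dst, src, sizeof(float) * C);
              src += C;
              dst += (R_xlen_t)C * kk;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add transpose of im2col.
static arma::fmat col2im(const arma::fmat& cols, int C, int D, int H, int W,
                         int kd, int kh, int kw) {
  const int kk = kd * kh * kw;
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  arma::fmat x(C, D * H * W, arma::fill::zeros);
  for (int od = 0; od < kd; ++od) {
    for (int oh = 0; oh < kh; ++oh) {
      for (int ow = 0; ow < kw; ++ow) {
        const int o = (od * kh + oh) * kw + ow;
        for (int d = 0; d < D; ++d) {
          const int sd = d + od - pd;
          if (sd < 0 || sd >= D) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + oh - ph;
            if (sh < 0 || sh >= H) continue;
            const int sw0 = ow - pw;
            int w0 = std::max(0, -sw0);
            int w1 = std::min(W, W - sw0);
            if (w0 >= w1) continue;
            float* dst = x.colptr((sd * H + sh) * W + (w0 + sw0));
            const float* src = cols.colptr((d * H + h) * W + w0) + o * C;
            for (int w = w0; w < w1; ++w) {
              for (int c = 0; c < C; ++c) dst[c] += src[c];
              dst += C;
              src += (R_xlen_t)C * kk;
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
NumericMatrix nn_conv_fwd(NumericMatrix x, NumericMatrix w, NumericVector b,
                          IntegerVector dims, IntegerVector kdim) {
  const int C = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  arma::fmat xf = as_fmat(x);
  arma::fmat wf = as_fmat(w);
  arma::fmat y;
  if (kd == 1 && kh == 1 && kw == 1) {
    y = wf * xf;
  } else {
    arma::fmat cols = im2col(xf, C, D, H, W, kd, kh, kw);
    y = wf * cols;
  }
  arma::fvec bf(b.size());
  for (int i = 0; i < b.size(); ++i) bf[i] = (float)b[i];
  y.each_col() += bf;
  return as_rmat(y);
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericMatrix x, NumericMatrix w, NumericMatrix dy,
                 IntegerVector dims, IntegerVector kdim) {
  const int C = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  arma::fmat xf = as_fmat(x);
  arma::fmat wf = as_fmat(w);
  arma::fmat dyf = as_fmat(dy);
  arma::fmat dw, dx;
  if (kd == 1 && kh == 1 && kw == 1) {
    dw = dyf * xf.t();
    dx = wf.t() * dyf;
  } else {
    arma::fmat cols = im2col(xf, C, D, H, W, kd, kh, kw);
    dw = dyf * cols.t();
    arma::fmat dcols = wf.t() * dyf;
    dx = col2im(dcols, C, D, H, W, kd, kh, kw);
  }
  arma::fvec db = arma::sum(dyf, 1);
  return List::create(_["dx"] = as_rmat(dx), _["dw"] = as_rmat(dw),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 stride-2 max pooling in (H, W); H and W must be even.
// [[Rcpp::export]]
List nn_maxpool2_fwd(NumericMatrix x, IntegerVector dims) {
  const int C = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix y(C, D * Ho * Wo);
  IntegerMatrix idx(C, D * Ho * Wo);  // winning input spatial column
  for (int d = 0; d < D; ++d) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int no = (d * Ho + ho) * Wo + wo;
        const int n00 = (d * H + 2 * ho) * W + 2 * wo;
        const int cand[4] = {n00, n00 + 1, n00 + W, n00 + W + 1};
        for (int c = 0; c < C; ++c) {
          double best = x(c, cand[0]);
          int bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            const double v = x(c, cand[k]);
            if (v > best) { best = v; bi = cand[k]; }
          }
          y(c, no) = best;
          idx(c, no) = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix nn_maxpool2_bwd(NumericMatrix dy, IntegerMatrix idx,
                              IntegerVector dims) {
  const int C = dy.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];  // input dims
  NumericMatrix dx(C, D * H * W);
  const int No = dy.ncol();
  for (int no = 0; no < No; ++no)
    for (int c = 0; c < C; ++c)
      dx(c, idx(c, no)) += dy(c, no);
  return dx;
}

// Nearest-neighbour 2x upsampling in (H, W).
// [[Rcpp::export]]
NumericMatrix nn_up2_fwd(NumericMatrix x, IntegerVector dims) {
  const int C = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix y(C, D * Ho * Wo);
  for (int d = 0; d < D; ++d)
    for (int ho = 0; ho < Ho; ++ho)
      for (int wo = 0; wo < Wo; ++wo) {
        const int ni = (d * H + ho / 2) * W + wo / 2;
        const int no = (d * Ho + ho) * Wo + wo;
        for (int c = 0; c < C; ++c) y(c, no) = x(c, ni);
      }
  return y;
}

// [[Rcpp::export]]
NumericMatrix nn_up2_bwd(NumericMatrix dy, IntegerVector dims) {
  const int C = dy.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];  // input (small) dims
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix dx(C, D * H * W);
  for (int d = 0; d < D; ++d)
    for (int ho = 0; ho < Ho; ++ho)
      for (int wo = 0; wo < Wo; ++wo) {
        const int ni = (d * H + ho / 2) * W + wo / 2;
        const int no = (d * Ho + ho) * Wo + wo;
        for (int c = 0; c < C; ++c) dx(c, ni) += dy(c, no);
      }
  return dx;
}

// 2x2 stride-2 transposed convolution in (H, W): output is (2H, 2W).
// Weight layout: w[cout, o*Cin + cin], o = oh*2 + ow.
// [[Rcpp::export]]
NumericMatrix nn_convT2_fwd(NumericMatrix x, NumericMatrix w, NumericVector b,
                            IntegerVector dims) {
  const int Cin = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Cout = w.nrow();
  const int Ho = 2 * H, Wo = 2 * W;
  arma::fmat xf = as_fmat(x);
  arma::fmat wf = as_fmat(w);
  arma::fmat y(Cout, (R_xlen_t)D * Ho * Wo, arma::fill::zeros);
  for (int o = 0; o < 4; ++o) {
    const int oh = o / 2, ow = o % 2;
    arma::fmat yo = wf.cols(o * Cin, (o + 1) * Cin - 1) * xf;  // Cout x N
    for (int d = 0; d < D; ++d)
      for (int h = 0; h < H; ++h)
        for (int wcol = 0; wcol < W; ++wcol) {
          const int ni = (d * H + h) * W + wcol;
          const int no = (d * Ho + 2 * h + oh) * Wo + 2 * wcol + ow;
          float* dst = y.colptr(no);
          const float* src = yo.colptr(ni);
          for (int c = 0; c < Cout; ++c) dst[c] += src[c];
        }
  }
  arma::fvec bf(b.size());
  for (int i = 0; i < b.size(); ++i) bf[i] = (float)b[i];
  y.each_col() += bf;
  return as_rmat(y);
}

// [[Rcpp::export]]
List nn_convT2_bwd(NumericMatrix x, NumericMatrix w, NumericMatrix dy,
                   IntegerVector dims) {
  const int Cin = x.nrow();
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Cout = w.nrow();
  const int Ho = 2 * H, Wo = 2 * W;
  arma::fmat xf = as_fmat(x);
  arma::fmat wf = as_fmat(w);
  arma::fmat dyf = as_fmat(dy);
  arma::fmat dx(Cin, (R_xlen_t)D * H * W, arma::fill::zeros);
  arma::fmat dw(Cout, 4 * Cin, arma::fill::zeros);
  arma::fmat dyo(Cout, (R_xlen_t)D * H * W);
  for (int o = 0; o < 4; ++o) {
    const int oh = o / 2, ow = o % 2;
    for (int d = 0; d < D; ++d)
      for (int h = 0; h < H; ++h)
        for (int wcol = 0; wcol < W; ++wcol) {
          const int ni = (d * H + h) * W + wcol;
          const int no = (d * Ho + 2 * h + oh) * Wo + 2 * wcol + ow;
          std::memcpy(dyo.colptr(ni), dyf.colptr(no), sizeof(float) * Cout);
        }
    dw.cols(o * Cin, (o + 1) * Cin - 1) = dyo * xf.t();
    dx += wf.cols(o * Cin, (o + 1) * Cin - 1).t() * dyo;
  }
  arma::fvec db = arma::sum(dyf, 1);
  return List::create(_["dx"] = as_rmat(dx), _["dw"] = as_rmat(dw),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---------------------------------------------------------------------------
// Classical 2D filters on plain H x W matrices (reflective boundaries).

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric reflection, period 2n
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix img_median2d(NumericMatrix x, int window) {
  const int H = x.nrow(), W = x.ncol();
  const int r = window / 2;
  NumericMatrix y(H, W);
  std::vector<double> buf(window * window);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect_idx(j + dj, W);
        for (int di = -r; di <= r; ++di)
          buf[k++] = x(reflect_idx(i + di, H), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      y(i, j) = buf[k / 2];
    }
  return y;
}

// Separable convolution with a 1D kernel along rows then columns.
// [[Rcpp::export]]
NumericMatrix img_sepconv2d(NumericMatrix x, NumericVector kern) {
  const int H = x.nrow(), W = x.ncol();
  const int r = (kern.size() - 1) / 2;
  NumericMatrix tmp(H, W), y(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d)
        s += kern[d + r] * x(reflect_idx(i + d, H), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d)
        s += kern[d + r] * tmp(i, reflect_idx(j + d, W));
      y(i, j) = s;
    }
  return y;
}

// ---------------------------------------------------------------------------
// Whole-graph executor. Runs forward (and optionally backward) passes for a
// batch of samples entirely in single precision, avoiding per-layer R
// round-trips. Node table columns (1-based indices, 0 = none):
//   op, in1, in2, wi, bi, kd, kh, kw
// with op: 1 input, 2 conv, 3 convT2, 4 relu, 5 pool, 6 up2, 7 concat,
// 8 add.

enum { OP_INPUT = 1, OP_CONV, OP_CONVT2, OP_RELU, OP_POOL, OP_UP2,
       OP_CONCAT, OP_ADD };

static void pool2_fwd_f(const arma::fmat& x, int D, int H, int W,
                        arma::fmat& y, arma::Mat<arma::uword>& idx) {
  const int C = x.n_rows, Ho = H / 2, Wo = W / 2;
  y.set_size(C, (R_xlen_t)D * Ho * Wo);
  idx.set_size(C, (R_xlen_t)D * Ho * Wo);
  for (int d = 0; d < D; ++d)
    for (int ho = 0; ho < Ho; ++ho)
      for (int wo = 0; wo < Wo; ++wo) {
        const int no = (d * Ho + ho) * Wo + wo;
        const int n00 = (d * H + 2 * ho) * W + 2 * wo;
        const int cand[4] = {n00, n00 + 1, n00 + W, n00 + W + 1};
        for (int c = 0; c < C; ++c) {
          float best = x(c, cand[0]); int bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            const float v = x(c, cand[k]);
            if (v > best) { best = v; bi = cand[k]; }
          }
          y(c, no) = best;
          idx(c, no) = bi;
        }
      }
}

static arma::fmat up2_fwd_f(const arma::fmat& x, int D, int H, int W) {
  const int C = x.n_rows, Ho = 2 * H, Wo = 2 * W;
  arma::fmat y(C, (R_xlen_t)D * Ho * Wo);
  for (int d = 0; d < D; ++d)
    for (int ho = 0; ho < Ho; ++ho) {
      const int base_i = (d * H + ho / 2) * W;
      const int base_o = (d * Ho + ho) * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        y.col(base_o + wo) = x.col(base_i + wo / 2);
    }
  return y;
}

static arma::fmat up2_bwd_f(const arma::fmat& dy, int D, int H, int W) {
  const int C = dy.n_rows, Ho = 2 * H, Wo = 2 * W;
  arma::fmat dx(C, (R_xlen_t)D * H * W, arma::fill::zeros);
  for (int d = 0; d < D; ++d)
    for (int ho = 0; ho < Ho; ++ho) {
      const int base_i = (d * H + ho / 2) * W;
      const int base_o = (d * Ho + ho) * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        dx.col(base_i + wo / 2) += dy.col(base_o + wo);
    }
  return dx;
}

static arma::fmat convT2_fwd_f(const arma::fmat& x, const arma::fmat& w,
                               const arma::fvec& b, int D, int H, int W) {
  const int Cin = x.n_rows, Cout = w.n_rows, Ho = 2 * H, Wo = 2 * W;
  arma::fmat y(Cout, (R_xlen_t)D * Ho * Wo, arma::fill::zeros);
  for (int o = 0; o < 4; ++o) {
    const int oh = o / 2, ow = o % 2;
    arma::fmat yo = w.cols(o * Cin, (o + 1) * Cin - 1) * x;
    for (int d = 0; d < D; ++d)
      for (int h = 0; h < H; ++h) {
        const int base_i = (d * H + h) * W;
        const int base_o = (d * Ho + 2 * h + oh) * Wo + ow;
        for (int wc = 0; wc < W; ++wc)
          y.col(base_o + 2 * wc) += yo.col(base_i + wc);
      }
  }
  y.each_col() += b;
  return y;
}

static void convT2_bwd_f(const arma::fmat& x, const arma::fmat& w,
                         const arma::fmat& dy, int D, int H, int W,
                         arma::fmat& dx, arma::fmat& dw, arma::fvec& db) {
  const int Cin = x.n_rows, Cout = w.n_rows, Ho = 2 * H, Wo = 2 * W;
  dx.zeros(Cin, (R_xlen_t)D * H * W);
  arma::fmat dyo(Cout, (R_xlen_t)D * H * W);
  for (int o = 0; o < 4; ++o) {
    const int oh = o / 2, ow = o % 2;
    for (int d = 0; d < D; ++d)
      for (int h = 0; h < H; ++h) {
        const int base_i = (d * H + h) * W;
        const int base_o = (d * Ho + 2 * h + oh) * Wo + ow;
        for (int wc = 0; wc < W; ++wc)
          dyo.col(base_i + wc) = dy.col(base_o + 2 * wc);
      }
    dw.cols(o * Cin, (o + 1) * Cin - 1) += dyo * x.t();
    dx += w.cols(o * Cin, (o + 1) * Cin - 1).t() * dyo;
  }
  db += arma::sum(dy, 1);
}

// [[Rcpp::export]]
List nn_exec_batch(IntegerMatrix nodes, List params, List X, SEXP Y,
                   IntegerVector dims0, int loss_type, bool want_grads,
                   bool want_pred) {
  const int n_nodes = nodes.nrow();
  const int n_par = params.size();
  // convert parameters once
  std::vector<arma::fmat> W(n_par);
  std::vector<arma::fvec> B(n_par);     // biases stored in same slot list
  std::vector<bool> is_vec(n_par, false);
  for (int i = 0; i < n_par; ++i) {
    SEXP p = params[i];
    if (Rf_isMatrix(p)) {
      W[i] = as_fmat(NumericMatrix(p));
    } else {
      NumericVector v(p);
      B[i] = arma::fvec(v.size());
      for (int j = 0; j < v.size(); ++j) B[i][j] = (float)v[j];
      is_vec[i] = true;
    }
  }
  std::vector<arma::fmat> GW(n_par);
  std::vector<arma::fvec> GB(n_par);
  if (want_grads)
    for (int i = 0; i < n_par; ++i) {
      if (is_vec[i]) GB[i].zeros(B[i].n_elem);
      else GW[i].zeros(W[i].n_rows, W[i].n_cols);
    }

  const bool has_y = !Rf_isNull(Y);
  List Yl = has_y ? List(Y) : List();
  const int batch = X.size();
  double loss_sum = 0.0;
  List preds(want_pred ? batch : 0);

  std::vector<arma::fmat> val(n_nodes);
  std::vector<std::array<int, 3>> nd(n_nodes);
  std::vector<arma::Mat<arma::uword>> pidx(n_nodes);

  for (int s = 0; s < batch; ++s) {
    // forward
    for (int i = 0; i < n_nodes; ++i) {
      const int op = nodes(i, 0);
      const int j = nodes(i, 1) - 1, j2 = nodes(i, 2) - 1;
      const int wi = nodes(i, 3) - 1, bi = nodes(i, 4) - 1;
      if (op == OP_INPUT) {
        val[i] = as_fmat(NumericMatrix(SEXP(X[s])));
        nd[i] = {dims0[0], dims0[1], dims0[2]};
        continue;
      }
      const auto& di = nd[j];
      switch (op) {
      case OP_CONV: {
        const int kd = nodes(i, 5), kh = nodes(i, 6), kw = nodes(i, 7);
        nd[i] = di;
        if (kd == 1 && kh == 1 && kw == 1) val[i] = W[wi] * val[j];
        else {
          arma::fmat cols = im2col(val[j], val[j].n_rows, di[0], di[1], di[2],
                                   kd, kh, kw);
          val[i] = W[wi] * cols;
        }
        val[i].each_col() += B[bi];
        break;
      }
      case OP_CONVT2:
        nd[i] = {di[0], 2 * di[1], 2 * di[2]};
        val[i] = convT2_fwd_f(val[j], W[wi], B[bi], di[0], di[1], di[2]);
        break;
      case OP_RELU:
        nd[i] = di;
        val[i] = val[j];
        val[i].transform([](float v) { return v > 0.0f ? v : 0.0f; });
        break;
      case OP_POOL:
        nd[i] = {di[0], di[1] / 2, di[2] / 2};
        pool2_fwd_f(val[j], di[0], di[1], di[2], val[i], pidx[i]);
        break;
      case OP_UP2:
        nd[i] = {di[0], 2 * di[1], 2 * di[2]};
        val[i] = up2_fwd_f(val[j], di[0], di[1], di[2]);
        break;
      case OP_CONCAT:
        nd[i] = di;
        val[i] = arma::join_cols(val[j], val[j2]);
        break;
      case OP_ADD:
        nd[i] = di;
        val[i] = val[j] + val[j2];
        break;
      default: stop("unknown op");
      }
    }
    const arma::fmat& out = val[n_nodes - 1];
    if (want_pred) preds[s] = as_rmat(out);

    arma::fmat dout;
    if (has_y && loss_type > 0) {
      arma::fmat y = as_fmat(NumericMatrix(SEXP(Yl[s])));
      arma::fmat d = out - y;
      const double n = (double)d.n_elem;
      if (loss_type == 1) {
        loss_sum += arma::accu(arma::abs(arma::conv_to<arma::mat>::from(d))) / n;
        if (want_grads) {
          dout = d;
          dout.transform([](float v) {
            return v > 0.0f ? 1.0f : (v < 0.0f ? -1.0f : 0.0f); });
          dout /= (float)n;
        }
      } else {
        loss_sum += arma::accu(arma::square(arma::conv_to<arma::mat>::from(d))) / n;
        if (want_grads) dout = d * (2.0f / (float)n);
      }
    }
    if (!want_grads || dout.n_elem == 0) continue;

    // backward
    std::vector<arma::fmat> dval(n_nodes);
    dval[n_nodes - 1] = dout;
    for (int i = n_nodes - 1; i >= 0; --i) {
      if (dval[i].n_elem == 0) continue;
      const int op = nodes(i, 0);
      if (op == OP_INPUT) continue;
      const int j = nodes(i, 1) - 1, j2 = nodes(i, 2) - 1;
      const int wi = nodes(i, 3) - 1, bi = nodes(i, 4) - 1;
      const auto& dj = nd[j];
      arma::fmat& dy = dval[i];
      auto acc = [&](int k, arma::fmat&& g) {
        if (dval[k].n_elem == 0) dval[k] = std::move(g);
        else dval[k] += g;
      };
      switch (op) {
      case OP_CONV: {
        const int kd = nodes(i, 5), kh = nodes(i, 6), kw = nodes(i, 7);
        if (kd == 1 && kh == 1 && kw == 1) {
          GW[wi] += dy * val[j].t();
          acc(j, W[wi].t() * dy);
        } else {
          arma::fmat cols = im2col(val[j], val[j].n_rows, dj[0], dj[1], dj[2],
                                   kd, kh, kw);
          GW[wi] += dy * cols.t();
          arma::fmat dcols = W[wi].t() * dy;
          acc(j, col2im(dcols, val[j].n_rows, dj[0], dj[1], dj[2],
                        kd, kh, kw));
        }
        GB[bi] += arma::sum(dy, 1);
        break;
      }
      case OP_CONVT2: {
        arma::fmat dx;
        convT2_bwd_f(val[j], W[wi], dy, dj[0], dj[1], dj[2], dx, GW[wi],
                     GB[bi]);
        acc(j, std::move(dx));
        break;
      }
      case OP_RELU: {
        arma::fmat g = dy;
        const arma::fmat& yv = val[i];
        for (arma::uword k = 0; k < g.n_elem; ++k)
          if (yv[k] <= 0.0f) g[k] = 0.0f;
        acc(j, std::move(g));
        break;
      }
      case OP_POOL: {
        arma::fmat dx(val[j].n_rows, val[j].n_cols, arma::fill::zeros);
        const auto& ix = pidx[i];
        for (arma::uword n = 0; n < dy.n_cols; ++n)
          for (arma::uword c = 0; c < dy.n_rows; ++c)
            dx(c, ix(c, n)) += dy(c, n);
        acc(j, std::move(dx));
        break;
      }
      case OP_UP2:
        acc(j, up2_bwd_f(dy, dj[0], dj[1], dj[2]));
        break;
      case OP_CONCAT: {
        const arma::uword c1 = val[j].n_rows;
        acc(j, dy.rows(0, c1 - 1));
        acc(j2, dy.rows(c1, dy.n_rows - 1));
        break;
      }
      case OP_ADD:
        acc(j, arma::fmat(dy));
        acc(j2, std::move(dy));
        break;
      }
      dval[i].reset();
    }
  }

  List grads(want_grads ? n_par : 0);
  if (want_grads)
    for (int i = 0; i < n_par; ++i) {
      if (is_vec[i])
        grads[i] = NumericVector(GB[i].begin(), GB[i].end());
      else
        grads[i] = as_rmat(GW[i]);
    }
  return List::create(_["loss"] = loss_sum, _["grads"] = grads,
                      _["preds"] = preds);
}
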