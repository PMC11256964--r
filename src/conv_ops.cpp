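// 2D convolution primitives for the pairwise co-membership network.
// Activations are (L1, L2, C) cubes (channels last, column-major slices);
// weights are (C_out x C_in*k*k) matrices so both directions reduce to GEMM
// via im2col / col2im. Zero padding keeps the output the same size as the
// input ("same" padding at every dilation), which is what makes the network
// fully convolutional: one weight set serves any L.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Row layout of the patch matrix: r = ch*k*k + b*k + a, where (a, b) indexes
// the kernel grid and ch the input channel. col2im below must match exactly.
// For a fixed kernel offset the valid source rows form one contiguous span
// per column, so the inner loop is a memcpy.
static void im2col(const cube& x, const int k, const int d, mat& col) {
  const int L1 = x.n_rows, L2 = x.n_cols, C = x.n_slices;
  const int c0 = (k - 1) / 2;
  const int R = C * k * k;
  col.zeros(R, L1 * L2);
  double* cp = col.memptr();
  for (int ch = 0; ch < C; ++ch) {
    const double* xs = x.slice(ch).memptr();
    for (int b = 0; b < k; ++b) {
      const int dj = (b - c0) * d;
      for (int a = 0; a < k; ++a) {
        const int di = (a - c0) * d;
        const int r = ch * k * k + b * k + a;
        const int i_lo = std::max(0, -di);
        const int i_hi = std::min(L1, L1 - di);  // exclusive
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < L2; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= L2) continue;
          const double* src = xs + (size_t)sj * L1 + (i_lo + di);
          double* dst = cp + ((size_t)j * L1 + i_lo) * R + r;
          for (int i = i_lo; i < i_hi; ++i) {
            *dst = *src++;
            dst += R;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int kernel,
                      const int dilation) {
  const int L1 = x.n_rows, L2 = x.n_cols;
  const int Cout = W.n_rows;
  mat col;
  im2col(x, kernel, dilation, col);
  mat out = W * col;
  out.each_col() += b;
  cube y(L1, L2, Cout);
  const double* op = out.memptr();
  for (int c = 0; c < Cout; ++c) {
    double* ys = y.slice(c).memptr();
    const double* src = op + c;
    for (size_t t = 0; t < (size_t)L1 * L2; ++t) {
      ys[t] = *src;
      src += Cout;
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int kernel,
                      const int dilation) {
  const int L1 = x.n_rows, L2 = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat col;
  im2col(x, kernel, dilation, col);
  mat gy_mat(Cout, (size_t)L1 * L2);
  double* gp = gy_mat.memptr();
  for (int c = 0; c < Cout; ++c) {
    const double* gs = gy.slice(c).memptr();
    double* dst = gp + c;
    for (size_t t = 0; t < (size_t)L1 * L2; ++t) {
      *dst = gs[t];
      dst += Cout;
    }
  }
  mat gW = gy_mat * col.t();
  vec gb = sum(gy_mat, 1);
  mat gcol = W.t() * gy_mat;
  cube gx(L1, L2, Cin, fill::zeros);
  const int c0 = (kernel - 1) / 2;
  const int R = Cin * kernel * kernel;
  const double* gc = gcol.memptr();
  for (int ch = 0; ch < Cin; ++ch) {
    double* gxs = gx.slice(ch).memptr();
    for (int b = 0; b < kernel; ++b) {
      const int dj = (b - c0) * dilation;
      for (int a = 0; a < kernel; ++a) {
        const int di = (a - c0) * dilation;
        const int r = ch * kernel * kernel + b * kernel + a;
        const int i_lo = std::max(0, -di);
        const int i_hi = std::min(L1, L1 - di);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < L2; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= L2) continue;
          double* dst = gxs + (size_t)sj * L1 + (i_lo + di);
          const double* src = gc + ((size_t)j * L1 + i_lo) * R + r;
          for (int i = i_lo; i < i_hi; ++i) {
            *dst++ += *src;
            src += R;
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::NumericVector elu_cpp(const Rcpp::NumericVector& x) {
  Rcpp::NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = x.size();
  for (size_t t = 0; t < n; ++t) {
    yp[t] = xp[t] > 0 ? xp[t] : std::expm1(xp[t]);
  }
  return y;
}

// gradient through ELU expressed via its output: d = y > 0 ? 1 : y + 1
// [[Rcpp::export]]
Rcpp::NumericVector elu_grad_cpp(const Rcpp::NumericVector& gy,
                                 const Rcpp::NumericVector& y) {
  Rcpp::NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin();
  const double* yp = y.begin();
  double* op = g.begin();
  const size_t n = gy.size();
  for (size_t t = 0; t < n; ++t) {
    op[t] = yp[t] > 0 ? gp[t] : gp[t] * (yp[t] + 1.0);
  }
  return g;
}

// instance norm over an (n x C) matrix: per-column standardize, then
// scale/shift by g and be
// [[Rcpp::export]]
Rcpp::List inorm_fwd_cpp(const arma::mat& xm, const arma::vec& g,
                         const arma::vec& be, const double eps) {
  const int n = xm.n_rows, C = xm.n_cols;
  mat xhat(n, C), y(n, C);
  vec sd(C);
  for (int c = 0; c < C; ++c) {
    const double* xp = xm.colptr(c);
    double mu = 0;
    for (int t = 0; t < n; ++t) mu += xp[t];
    mu /= n;
    double v = 0;
    for (int t = 0; t < n; ++t) {
      const double d = xp[t] - mu;
      v += d * d;
    }
    const double s = std::sqrt(v / n + eps);
    sd[c] = s;
    double* hp = xhat.colptr(c);
    double* yp = y.colptr(c);
    const double gc = g[c], bc = be[c];
    for (int t = 0; t < n; ++t) {
      hp[t] = (xp[t] - mu) / s;
      yp[t] = gc * hp[t] + bc;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("sd") = sd);
}

// [[Rcpp::export]]
Rcpp::List inorm_bwd_cpp(const arma::mat& gym, const arma::mat& xhat,
                         const arma::vec& sd, const arma::vec& g) {
  const int n = gym.n_rows, C = gym.n_cols;
  mat gx(n, C);
  vec gg(C), gbe(C);
  for (int c = 0; c < C; ++c) {
    const double* gp = gym.colptr(c);
    const double* hp = xhat.colptr(c);
    double s_g = 0, s_gh = 0;
    for (int t = 0; t < n; ++t) {
      s_g += gp[t];
      s_gh += gp[t] * hp[t];
    }
    gg[c] = s_gh;
    gbe[c] = s_g;
    const double gc = g[c];
    const double m1 = gc * s_g / n;
    const double m2 = gc * s_gh / n;
    const double inv_sd = 1.0 / sd[c];
    double* op = gx.colptr(c);
    for (int t = 0; t < n; ++t) {
      op[t] = (gc * gp[t] - m1 - hp[t] * m2) * inv_sd;
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gg") = gg,
                            Rcpp::Named("gbe") = gbe);
}

// training-path variants: the forward pass returns the im2col patch matrix
// so the backward pass can skip rebuilding it

// [[Rcpp::export]]
Rcpp::List conv2d_fwd_cache(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, const int kernel,
                            const int dilation) {
  const int L1 = x.n_rows, L2 = x.n_cols;
  const int Cout = W.n_rows;
  mat col;
  im2col(x, kernel, dilation, col);
  mat out = W * col;
  out.each_col() += b;
  cube y(L1, L2, Cout);
  const double* op = out.memptr();
  for (int c = 0; c < Cout; ++c) {
    double* ys = y.slice(c).memptr();
    const double* src = op + c;
    for (size_t t = 0; t < (size_t)L1 * L2; ++t) {
      ys[t] = *src;
      src += Cout;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("col") = col);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cached(const arma::mat& col, const arma::mat& W,
                             const arma::cube& gy, const int kernel,
                             const int dilation, const int Cin) {
  const int L1 = gy.n_rows, L2 = gy.n_cols;
  const int Cout = gy.n_slices;
  mat gy_mat(Cout, (size_t)L1 * L2);
  double* gp = gy_mat.memptr();
  for (int c = 0; c < Cout; ++c) {
    const double* gs = gy.slice(c).memptr();
    double* dst = gp + c;
    for (size_t t = 0; t < (size_t)L1 * L2; ++t) {
      *dst = gs[t];
      dst += Cout;
    }
  }
  mat gW = gy_mat * col.t();
  vec gb = sum(gy_mat, 1);
  mat gcol = W.t() * gy_mat;
  cube gx(L1, L2, Cin, fill::zeros);
  const int c0 = (kernel - 1) / 2;
  const int R = Cin * kernel * kernel;
  const double* gc = gcol.memptr();
  for (int ch = 0; ch < Cin; ++ch) {
    double* gxs = gx.slice(ch).memptr();
    for (int b = 0; b < kernel; ++b) {
      const int dj = (b - c0) * dilation;
      for (int a = 0; a < kernel; ++a) {
        const int di = (a - c0) * dilation;
        const int r = ch * kernel * kernel + b * kernel + a;
        const int i_lo = std::max(0, -di);
        const int i_hi = std::min(L1, L1 - di);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < L2; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= L2) continue;
          double* dst = gxs + (size_t)sj * L1 + (i_lo + di);
          const double* src = gc + ((size_t)j * L1 + i_lo) * R + r;
          for (int i = i_lo; i < i_hi; ++i) {
            *dst++ += *src;
            src += R;
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
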