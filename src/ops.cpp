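// Low-level kernels behind the network layers and surface metrics.
//
// Activation batches are stored as a C x (N*V) double matrix, V = D*H*W,
// column-major, with the column index inside a sample being
// d + D*(h + H*w) (depth fastest), matching an R array of dim c(C, D, H, W).
//
// Convolutions are im2col + GEMM computed in single precision (the unfolded
// patch matrix dominates memory traffic; weights and activations are well
// inside float range during training). The unfolded buffers live in
// persistent C++ scratch storage keyed by layer id, so the forward fill is
// reused by the immediately following backward pass and nothing large
// churns the R heap. Batch normalization, leaky ReLU and the SE channel
// scaling have fused double-precision kernels.

#include <RcppArmadillo.h>
#include <cstring>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static std::unordered_map<int, std::vector<float> > g_cols_cache;
static std::vector<float> g_xf, g_dyf, g_dcols, g_tmp;

struct ConvGeom {
  int C, D, H, W, kd, kh, kw, sd, sh, sw, pd, ph, pw, Do, Ho, Wo, K;
  size_t V, Vo;
};

static ConvGeom geom(int C, IntegerVector dims, IntegerVector kernel,
                     IntegerVector stride, IntegerVector pad) {
  ConvGeom g;
  g.C = C;
  g.D = dims[0]; g.H = dims[1]; g.W = dims[2];
  g.kd = kernel[0]; g.kh = kernel[1]; g.kw = kernel[2];
  g.sd = stride[0]; g.sh = stride[1]; g.sw = stride[2];
  g.pd = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  g.Do = (g.D + 2 * g.pd - g.kd) / g.sd + 1;
  g.Ho = (g.H + 2 * g.ph - g.kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.kw) / g.sw + 1;
  g.K = g.kd * g.kh * g.kw;
  g.V = (size_t)g.D * g.H * g.W;
  g.Vo = (size_t)g.Do * g.Ho * g.Wo;
  return g;
}

static void to_float(const double* src, size_t nn, std::vector<float>& dst) {
  dst.resize(nn);
  for (size_t i = 0; i < nn; ++i) dst[i] = (float)src[i];
}

// Unfold patches of x (float, C x n*V) into cols ((C*K) x n*Vo).
// Row order: c fastest, then kernel offsets (kd, kh, kw).
static void im2col_fill(const float* x, int n, const ConvGeom& g, float* cols) {
  const size_t CK = (size_t)g.C * g.K;
  for (int s = 0; s < n; ++s) {
    const float* xs = x + (size_t)s * g.V * g.C;
    float* os = cols + (size_t)s * g.Vo * CK;
    for (int ow = 0; ow < g.Wo; ++ow)
      for (int oh = 0; oh < g.Ho; ++oh)
        for (int od = 0; od < g.Do; ++od) {
          float* oc = os + ((size_t)od + (size_t)g.Do * (oh + (size_t)g.Ho * ow)) * CK;
          for (int kk = 0; kk < g.kw; ++kk) {
            const int iw = ow * g.sw + kk - g.pw;
            for (int kj = 0; kj < g.kh; ++kj) {
              const int ih = oh * g.sh + kj - g.ph;
              for (int ki = 0; ki < g.kd; ++ki) {
                const int id = od * g.sd + ki - g.pd;
                float* dst = oc + (size_t)g.C * (ki + g.kd * (kj + (size_t)g.kh * kk));
                if (id >= 0 && id < g.D && ih >= 0 && ih < g.H && iw >= 0 && iw < g.W) {
                  const float* src = xs + ((size_t)id + (size_t)g.D * (ih + (size_t)g.H * iw)) * g.C;
                  std::memcpy(dst, src, g.C * sizeof(float));
                } else {
                  std::memset(dst, 0, g.C * sizeof(float));
                }
              }
            }
          }
        }
  }
}

// Adjoint: fold cols back into x (accumulating); x must be zeroed by caller.
static void col2im_acc(const float* cols, int n, const ConvGeom& g, float* x) {
  const size_t CK = (size_t)g.C * g.K;
  for (int s = 0; s < n; ++s) {
    float* xs = x + (size_t)s * g.V * g.C;
    const float* os = cols + (size_t)s * g.Vo * CK;
    for (int ow = 0; ow < g.Wo; ++ow)
      for (int oh = 0; oh < g.Ho; ++oh)
        for (int od = 0; od < g.Do; ++od) {
          const float* oc = os + ((size_t)od + (size_t)g.Do * (oh + (size_t)g.Ho * ow)) * CK;
          for (int kk = 0; kk < g.kw; ++kk) {
            const int iw = ow * g.sw + kk - g.pw;
            if (iw < 0 || iw >= g.W) continue;
            for (int kj = 0; kj < g.kh; ++kj) {
              const int ih = oh * g.sh + kj - g.ph;
              if (ih < 0 || ih >= g.H) continue;
              for (int ki = 0; ki < g.kd; ++ki) {
                const int id = od * g.sd + ki - g.pd;
                if (id < 0 || id >= g.D) continue;
                float* dst = xs + ((size_t)id + (size_t)g.D * (ih + (size_t)g.H * iw)) * g.C;
                const float* src = oc + (size_t)g.C * (ki + g.kd * (kj + (size_t)g.kh * kk));
                for (int c = 0; c < g.C; ++c) dst[c] += src[c];
              }
            }
          }
        }
  }
}

static bool is_identity_unfold(const ConvGeom& g) {
  return g.K == 1 && g.sd == 1 && g.sh == 1 && g.sw == 1 &&
         g.pd == 0 && g.ph == 0 && g.pw == 0;
}

// y = W %*% im2col(x) + b; the unfolded buffer is cached under `id`.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(int id, const NumericMatrix& x, const NumericMatrix& W,
                           const NumericVector& b, int n, IntegerVector dims,
                           IntegerVector kernel, IntegerVector stride,
                           IntegerVector pad) {
  ConvGeom g = geom(x.nrow(), dims, kernel, stride, pad);
  const size_t M = (size_t)n * g.Vo, CK = (size_t)g.C * g.K;
  const int Cout = W.nrow();
  std::vector<float>& cols = g_cols_cache[id];
  if (is_identity_unfold(g)) {
    to_float(REAL(x), (size_t)g.C * x.ncol(), cols);
  } else {
    to_float(REAL(x), (size_t)g.C * x.ncol(), g_xf);
    cols.resize(CK * M);
    im2col_fill(g_xf.data(), n, g, cols.data());
  }
  to_float(REAL(W), (size_t)Cout * CK, g_tmp);
  arma::fmat Wf(g_tmp.data(), Cout, CK, false, true);
  arma::fmat colsf(cols.data(), CK, M, false, true);
  arma::fmat yf = Wf * colsf;
  NumericMatrix y(no_init(Cout, M));
  double* yp = REAL(y);
  const float* yfp = yf.memptr();
  const double* bp = REAL(b);
  for (size_t j = 0; j < M; ++j)
    for (int c = 0; c < Cout; ++c)
      yp[j * Cout + c] = (double)yfp[j * Cout + c] + bp[c];
  return y;
}

// Backward for the same layer; reuses the cached unfold from the forward.
// [[Rcpp::export]]
List cpp_conv_bwd(int id, const NumericMatrix& x, const NumericMatrix& W,
                  const NumericMatrix& dy, int n, IntegerVector dims,
                  IntegerVector kernel, IntegerVector stride, IntegerVector pad) {
  ConvGeom g = geom(x.nrow(), dims, kernel, stride, pad);
  const size_t M = (size_t)n * g.Vo, CK = (size_t)g.C * g.K;
  const int Cout = W.nrow();
  std::vector<float>& cols = g_cols_cache[id];
  if (cols.size() != CK * M) {              // not cached: rebuild
    if (is_identity_unfold(g)) {
      to_float(REAL(x), (size_t)g.C * x.ncol(), cols);
    } else {
      to_float(REAL(x), (size_t)g.C * x.ncol(), g_xf);
      cols.resize(CK * M);
      im2col_fill(g_xf.data(), n, g, cols.data());
    }
  }
  to_float(REAL(dy), (size_t)Cout * M, g_dyf);
  arma::fmat dyf(g_dyf.data(), Cout, M, false, true);
  arma::fmat colsf(cols.data(), CK, M, false, true);
  arma::fmat dWf = dyf * colsf.t();
  to_float(REAL(W), (size_t)Cout * CK, g_tmp);
  arma::fmat Wf(g_tmp.data(), Cout, CK, false, true);

  NumericMatrix dx(no_init(g.C, (size_t)n * g.V));
  if (is_identity_unfold(g)) {
    arma::fmat dxf = Wf.t() * dyf;
    std::copy(dxf.memptr(), dxf.memptr() + dxf.n_elem, REAL(dx));
  } else {
    g_dcols.resize(CK * M);
    arma::fmat dcolsf(g_dcols.data(), CK, M, false, true);
    dcolsf = Wf.t() * dyf;
    std::vector<float> dxf((size_t)g.C * n * g.V, 0.0f);
    col2im_acc(g_dcols.data(), n, g, dxf.data());
    std::copy(dxf.begin(), dxf.end(), REAL(dx));
  }
  NumericMatrix dW(no_init(Cout, CK));
  std::copy(dWf.memptr(), dWf.memptr() + dWf.n_elem, REAL(dW));
  NumericVector db(Cout);
  const double* dyp = REAL(dy);
  for (size_t j = 0; j < M; ++j)
    for (int c = 0; c < Cout; ++c) db[c] += dyp[j * Cout + c];
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// Transpose convolution with kernel = stride (non-overlapping upsampling).
// A is (Cout*K) x Cin; y = fold(A %*% x) + b, output dims = dims * stride.
// [[Rcpp::export]]
NumericMatrix cpp_tconv_fwd(const NumericMatrix& x, const NumericMatrix& A,
                            const NumericVector& b, int n, IntegerVector in_dims,
                            IntegerVector stride) {
  IntegerVector od(3);
  for (int i = 0; i < 3; ++i) od[i] = in_dims[i] * stride[i];
  IntegerVector pad = IntegerVector::create(0, 0, 0);
  const int K = stride[0] * stride[1] * stride[2];
  const int Cout = A.nrow() / K, Cin = x.nrow();
  const size_t Min = x.ncol();
  ConvGeom g = geom(Cout, od, stride, stride, pad);
  to_float(REAL(x), (size_t)Cin * Min, g_xf);
  to_float(REAL(A), (size_t)A.nrow() * Cin, g_tmp);
  arma::fmat xf(g_xf.data(), Cin, Min, false, true);
  arma::fmat Af(g_tmp.data(), A.nrow(), Cin, false, true);
  g_dcols.resize((size_t)A.nrow() * Min);
  arma::fmat colsf(g_dcols.data(), A.nrow(), Min, false, true);
  colsf = Af * xf;
  std::vector<float> yf((size_t)Cout * n * g.V, 0.0f);
  col2im_acc(g_dcols.data(), n, g, yf.data());
  NumericMatrix y(no_init(Cout, (size_t)n * g.V));
  double* yp = REAL(y);
  const double* bp = REAL(b);
  const size_t My = (size_t)n * g.V;
  for (size_t j = 0; j < My; ++j)
    for (int c = 0; c < Cout; ++c)
      yp[j * Cout + c] = (double)yf[j * Cout + c] + bp[c];
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(const NumericMatrix& x, const NumericMatrix& A,
                   const NumericMatrix& dy, int n, IntegerVector in_dims,
                   IntegerVector stride) {
  IntegerVector od(3);
  for (int i = 0; i < 3; ++i) od[i] = in_dims[i] * stride[i];
  IntegerVector pad = IntegerVector::create(0, 0, 0);
  const int K = stride[0] * stride[1] * stride[2];
  const int Cout = A.nrow() / K, Cin = x.nrow();
  const size_t Min = x.ncol();
  ConvGeom g = geom(Cout, od, stride, stride, pad);
  to_float(REAL(dy), (size_t)Cout * dy.ncol(), g_dyf);
  g_dcols.resize((size_t)A.nrow() * Min);
  im2col_fill(g_dyf.data(), n, g, g_dcols.data());
  arma::fmat dcolsf(g_dcols.data(), A.nrow(), Min, false, true);
  to_float(REAL(x), (size_t)Cin * Min, g_xf);
  arma::fmat xf(g_xf.data(), Cin, Min, false, true);
  arma::fmat dAf = dcolsf * xf.t();
  to_float(REAL(A), (size_t)A.nrow() * Cin, g_tmp);
  arma::fmat Af(g_tmp.data(), A.nrow(), Cin, false, true);
  arma::fmat dxf = Af.t() * dcolsf;
  NumericMatrix dx(no_init(Cin, Min)), dA(no_init(A.nrow(), Cin));
  std::copy(dxf.memptr(), dxf.memptr() + dxf.n_elem, REAL(dx));
  std::copy(dAf.memptr(), dAf.memptr() + dAf.n_elem, REAL(dA));
  NumericVector db(Cout);
  const double* dyp = REAL(dy);
  const size_t My = dy.ncol();
  for (size_t j = 0; j < My; ++j)
    for (int c = 0; c < Cout; ++c) db[c] += dyp[j * Cout + c];
  return List::create(Named("dx") = dx, Named("dA") = dA, Named("db") = db);
}

// Release the persistent scratch buffers (e.g. after training).
// [[Rcpp::export]]
void cpp_free_buffers() {
  g_cols_cache.clear();
  std::vector<float>().swap(g_xf);
  std::vector<float>().swap(g_dyf);
  std::vector<float>().swap(g_dcols);
  std::vector<float>().swap(g_tmp);
}

// ---- fused batch-norm kernels (double precision) ---------------------------

// training: per-row mean/biased variance over all columns, then normalize.
// eval: normalize with the provided running statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& x, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& mu_in,
                const NumericVector& var_in, bool training, double eps) {
  const int C = x.nrow();
  const size_t M = x.ncol();
  const double* xp = REAL(x);
  NumericVector mu(C), var(C);
  if (training) {
    std::vector<double> s(C, 0.0), s2(C, 0.0);
    for (size_t j = 0; j < M; ++j) {
      const double* col = xp + j * C;
      for (int c = 0; c < C; ++c) { s[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s[c] / M;
      var[c] = s2[c] / M - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    mu = clone(mu_in); var = clone(var_in);
  }
  std::vector<double> a(C), bb(C);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    a[c] = gamma[c] * invstd;
    bb[c] = beta[c] - gamma[c] * invstd * mu[c];
  }
  NumericMatrix y(no_init(C, M));
  double* yp = REAL(y);
  for (size_t j = 0; j < M; ++j) {
    const double* col = xp + j * C;
    double* out = yp + j * C;
    for (int c = 0; c < C; ++c) out[c] = a[c] * col[c] + bb[c];
  }
  return List::create(Named("y") = y, Named("mu") = mu, Named("var") = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& x, const NumericMatrix& dy,
                const NumericVector& gamma, const NumericVector& mu,
                const NumericVector& var, bool training, double eps) {
  const int C = x.nrow();
  const size_t M = x.ncol();
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  std::vector<double> invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> m1(C, 0.0), m2(C, 0.0);   // mean(dxhat), mean(dxhat*xhat)
  for (size_t j = 0; j < M; ++j) {
    const double* xc = xp + j * C;
    const double* dc = dyp + j * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xc[c] - mu[c]) * invstd[c];
      dgamma[c] += dc[c] * xhat;
      dbeta[c] += dc[c];
      const double dxhat = dc[c] * gamma[c];
      m1[c] += dxhat; m2[c] += dxhat * xhat;
    }
  }
  for (int c = 0; c < C; ++c) { m1[c] /= M; m2[c] /= M; }
  NumericMatrix dx(no_init(C, M));
  double* dxp = REAL(dx);
  for (size_t j = 0; j < M; ++j) {
    const double* xc = xp + j * C;
    const double* dc = dyp + j * C;
    double* o = dxp + j * C;
    if (training) {
      for (int c = 0; c < C; ++c) {
        const double xhat = (xc[c] - mu[c]) * invstd[c];
        o[c] = invstd[c] * (dc[c] * gamma[c] - m1[c] - xhat * m2[c]);
      }
    } else {
      for (int c = 0; c < C; ++c) o[c] = dc[c] * gamma[c] * invstd[c];
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// ---- leaky ReLU -------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_fwd(const NumericMatrix& x, double slope) {
  NumericMatrix y(no_init(x.nrow(), x.ncol()));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const size_t nn = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < nn; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(const NumericMatrix& x, const NumericMatrix& dy,
                            double slope) {
  NumericMatrix dx(no_init(x.nrow(), x.ncol()));
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  const size_t nn = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < nn; ++i) dxp[i] = xp[i] > 0 ? dyp[i] : slope * dyp[i];
  return dx;
}

// ---- squeeze-and-excitation helpers ----------------------------------------

// Per-sample global average pool: x (C x n*V) -> (C x n).
// [[Rcpp::export]]
NumericMatrix cpp_block_rowmeans(const NumericMatrix& x, int n) {
  const int C = x.nrow();
  const size_t V = x.ncol() / n;
  NumericMatrix s(C, n);
  const double* xp = REAL(x);
  for (int i = 0; i < n; ++i) {
    double* sc = REAL(s) + (size_t)i * C;
    for (size_t j = 0; j < V; ++j) {
      const double* col = xp + ((size_t)i * V + j) * C;
      for (int c = 0; c < C; ++c) sc[c] += col[c];
    }
    for (int c = 0; c < C; ++c) sc[c] /= V;
  }
  return s;
}

// y[c, (i,j)] = x[c, (i,j)] * w[c, i]
// [[Rcpp::export]]
NumericMatrix cpp_scale_blocks(const NumericMatrix& x, const NumericMatrix& w) {
  const int C = x.nrow(), n = w.ncol();
  const size_t V = x.ncol() / n;
  NumericMatrix y(no_init(C, x.ncol()));
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  for (int i = 0; i < n; ++i) {
    const double* wc = wp + (size_t)i * C;
    for (size_t j = 0; j < V; ++j) {
      const size_t off = ((size_t)i * V + j) * C;
      for (int c = 0; c < C; ++c) yp[off + c] = xp[off + c] * wc[c];
    }
  }
  return y;
}

// dw[c, i] = sum_j dy[c, (i,j)] * x[c, (i,j)]
// [[Rcpp::export]]
NumericMatrix cpp_se_grad_w(const NumericMatrix& x, const NumericMatrix& dy, int n) {
  const int C = x.nrow();
  const size_t V = x.ncol() / n;
  NumericMatrix dw(C, n);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  for (int i = 0; i < n; ++i) {
    double* dc = REAL(dw) + (size_t)i * C;
    for (size_t j = 0; j < V; ++j) {
      const size_t off = ((size_t)i * V + j) * C;
      for (int c = 0; c < C; ++c) dc[c] += dyp[off + c] * xp[off + c];
    }
  }
  return dw;
}

// dx[c, (i,j)] = dy[c, (i,j)] * w[c, i] + add[c, i]
// [[Rcpp::export]]
NumericMatrix cpp_se_grad_x(const NumericMatrix& dy, const NumericMatrix& w,
                            const NumericMatrix& add) {
  const int C = dy.nrow(), n = w.ncol();
  const size_t V = dy.ncol() / n;
  NumericMatrix dx(no_init(C, dy.ncol()));
  const double* dyp = REAL(dy);
  const double* wp = REAL(w);
  const double* ap = REAL(add);
  double* dxp = REAL(dx);
  for (int i = 0; i < n; ++i) {
    const double* wc = wp + (size_t)i * C;
    const double* ac = ap + (size_t)i * C;
    for (size_t j = 0; j < V; ++j) {
      const size_t off = ((size_t)i * V + j) * C;
      for (int c = 0; c < C; ++c) dxp[off + c] = dyp[off + c] * wc[c] + ac[c];
    }
  }
  return dx;
}

// ---- surface distances ------------------------------------------------------

// For each point (row) of a, the minimum Euclidean distance to the points of
// b. Coordinates are already in physical units (mm).
// [[Rcpp::export]]
NumericVector cpp_min_dists(const arma::mat& a, const arma::mat& b) {
  const size_t na = a.n_rows, nb = b.n_rows;
  NumericVector out(na);
  for (size_t i = 0; i < na; ++i) {
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    double best = R_PosInf;
    for (size_t j = 0; j < nb; ++j) {
      const double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
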