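// Hot numerical kernels for the GAN: dense and im2col convolution layers in
// single precision (the training signal sits far above float resolution),
// batch-norm, leaky ReLU and the RMSprop step.
//
// Layout conventions, matching the R driver:
//  - "cmat": conv activations as (P*N) x C, P spatial positions fastest,
//    then batch sample n, channels as columns;
//  - "pm": per-sample flat (H*W*C) x N, channel-major blocks of positions
//    (this is t() of a dense layer's N x (H*W*C) output).
// The spatial gather index sidx is (P_out x 9), 1-based positions into the
// H*W input plane with 0 marking padding, kernel offsets ordered to match
// the weight-row order (channel-major, then the 9 offsets).

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat as_f(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* p = x.begin();
  float* q = out.memptr();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericMatrix as_d(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* p = x.memptr();
  double* q = out.begin();
  const R_xlen_t n = (R_xlen_t)x.n_rows * x.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (double)p[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dense_fwd(NumericMatrix x, NumericMatrix W, NumericVector b) {
  arma::fmat X = as_f(x), Wf = as_f(W);
  arma::fmat Y = X * Wf;
  for (arma::uword j = 0; j < Y.n_cols; ++j) Y.col(j) += (float)b[j];
  return as_d(Y);
}

// [[Rcpp::export]]
List cpp_dense_bwd(NumericMatrix x, NumericMatrix W, NumericMatrix dy) {
  arma::fmat X = as_f(x), Wf = as_f(W), dY = as_f(dy);
  arma::fmat dX = dY * Wf.t();
  arma::fmat dW = X.t() * dY;
  arma::frowvec db = arma::sum(dY, 0);
  return List::create(_["dx"] = as_d(dX), _["W"] = as_d(dW),
                      _["b"] = NumericVector(db.begin(), db.end()));
}

// im2col gather into an (P*N) x (9*Cin) float matrix
static arma::fmat gather_cols(const arma::fmat& X, const IntegerMatrix& sidx,
                              int Cin, int N, int HW, bool pm_mode) {
  const int P = sidx.nrow();
  arma::fmat xc((arma::uword)P * N, (arma::uword)9 * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int o = 0; o < 9; ++o) {
      float* out = xc.colptr((arma::uword)c * 9 + o);
      const int* id = &sidx(0, o);
      for (int n = 0; n < N; ++n) {
        const float* src = pm_mode ? X.colptr(n) + (R_xlen_t)c * HW
                                   : X.colptr(c) + (R_xlen_t)n * HW;
        float* dst = out + (R_xlen_t)n * P;
        for (int p = 0; p < P; ++p) {
          const int s = id[p];
          dst[p] = s > 0 ? src[s - 1] : 0.0f;
        }
      }
    }
  }
  return xc;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(NumericMatrix x, IntegerMatrix sidx, int Cin,
                           int N, int HW, bool pm_mode,
                           NumericMatrix W, NumericVector b) {
  arma::fmat X = as_f(x), Wf = as_f(W);
  arma::fmat xc = gather_cols(X, sidx, Cin, N, HW, pm_mode);
  arma::fmat Y = xc * Wf;
  for (arma::uword j = 0; j < Y.n_cols; ++j) Y.col(j) += (float)b[j];
  return as_d(Y);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix x, IntegerMatrix sidx, int Cin, int N,
                  int HW, bool pm_mode, NumericMatrix W, NumericMatrix dy) {
  arma::fmat X = as_f(x), Wf = as_f(W), dY = as_f(dy);
  arma::fmat xc = gather_cols(X, sidx, Cin, N, HW, pm_mode);  // regathered
  arma::fmat dW = xc.t() * dY;
  arma::frowvec db = arma::sum(dY, 0);
  arma::fmat dxc = dY * Wf.t();                               // (P*N) x 9Cin
  const int P = sidx.nrow();
  arma::fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int o = 0; o < 9; ++o) {
      const float* dcol = dxc.colptr((arma::uword)c * 9 + o);
      const int* id = &sidx(0, o);
      for (int n = 0; n < N; ++n) {
        float* dst = pm_mode ? dX.colptr(n) + (R_xlen_t)c * HW
                             : dX.colptr(c) + (R_xlen_t)n * HW;
        const float* d = dcol + (R_xlen_t)n * P;
        for (int p = 0; p < P; ++p) {
          const int s = id[p];
          if (s > 0) dst[s - 1] += d[p];
        }
      }
    }
  }
  return List::create(_["dx"] = as_d(dX), _["W"] = as_d(dW),
                      _["b"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                NumericVector rm, NumericVector rv, bool train,
                double momentum, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xhat(n, C);
  NumericVector inv(C), nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    const double* col = &x(0, c);
    double mu, var;
    if (train && n > 1) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += col[i];
      mu = s / n;
      double s2 = 0;
      for (int i = 0; i < n; ++i) { const double d = col[i] - mu; s2 += d * d; }
      var = s2 / n;
      nrm[c] = momentum * rm[c] + (1 - momentum) * mu;
      nrv[c] = momentum * rv[c] + (1 - momentum) * var;
    } else {
      mu = rm[c]; var = rv[c];
      nrm[c] = rm[c]; nrv[c] = rv[c];
    }
    const double iv = 1.0 / std::sqrt(var + eps);
    inv[c] = iv;
    const double g = gamma[c], bb = beta[c];
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) {
      xh[i] = (col[i] - mu) * iv;
      o[i] = xh[i] * g + bb;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["rm"] = nrm, _["rv"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix xhat, NumericVector inv, NumericVector gamma,
                NumericMatrix dy) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xh = &xhat(0, c);
    const double* d = &dy(0, c);
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s1 += d[i]; s2 += d[i] * xh[i]; }
    dbeta[c] = s1; dgamma[c] = s2;
    const double m1 = s1 / n, m2 = s2 / n, gi = gamma[c] * inv[c];
    double* o = &dx(0, c);
    for (int i = 0; i < n; ++i) o[i] = (d[i] - m1 - xh[i] * m2) * gi;
  }
  return List::create(_["dx"] = dx, _["gamma"] = dgamma, _["beta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_fwd(NumericMatrix x, double slope) {
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const double* p = x.begin();
  double* q = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? p[i] : slope * p[i];
  return out;
}

// backward from the forward OUTPUT: a positive slope preserves sign
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(NumericMatrix out, NumericMatrix dy, double slope) {
  NumericMatrix dx(dy.nrow(), dy.ncol());
  const R_xlen_t n = (R_xlen_t)dy.nrow() * dy.ncol();
  const double* o = out.begin();
  const double* d = dy.begin();
  double* q = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = o[i] > 0 ? d[i] : slope * d[i];
  return dx;
}

// fused RMSprop step; preserves the parameter's dim attribute
// [[Rcpp::export]]
List cpp_rmsprop(NumericVector p, NumericVector s, NumericVector g,
                 double lr, double rho, double eps) {
  const R_xlen_t n = p.size();
  NumericVector np(n), ns(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    ns[i] = rho * s[i] + (1 - rho) * g[i] * g[i];
    np[i] = p[i] - lr * g[i] / (std::sqrt(ns[i]) + eps);
  }
  np.attr("dim") = p.attr("dim");
  return List::create(_["p"] = np, _["s"] = ns);
}
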