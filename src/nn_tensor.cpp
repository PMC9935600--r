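// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Tensor-handle kernels for the 3D U-Net GAN.
//
// Feature maps live on the C++ side as external pointers to dense matrices
// [B*N x C]: B samples of N = d1*d2*d3 voxels (column-major spatial order,
// sample-major rows), C channels. Keeping them native avoids a
// double<->float round trip at every layer; R only converts at the network
// input/output and for the (small) parameter arrays. Training runs in
// single precision; `dbl = TRUE` switches every op to double precision for
// the finite-difference gradient checks.
//
// Stride-1 convolutions are evaluated as one fat gemm against rearranged
// weights W2 [Cin x k^3*Cout] followed by a shifted accumulation over the
// kernel offsets; strided convolutions use classic im2col (their output
// grids are small). Dropout draws its mask from R's RNG so training remains
// reproducible from set.seed().

static inline int outlen(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

template <typename MT> MT *get_h(SEXP s) {
  XPtr<MT> p(s);
  return p.get();
}
template <typename MT> SEXP make_h(MT *m) {
  return XPtr<MT>(m, true);
}

// reusable scratch arena for the large per-call intermediates (offset-gemm
// and im2col buffers); two independent slots, per precision
template <typename T, int SLOT> T *scratch(size_t n) {
  static std::vector<T> buf;
  if (buf.size() < n) buf.resize(n);
  return buf.data();
}

template <typename F>
static void offset_runs(int d1, int d2, int d3, int k, int s, int p,
                        int a1, int a2, int a3, F f) {
  int o1 = outlen(d1, k, s, p), o2 = outlen(d2, k, s, p), o3 = outlen(d3, k, s, p);
  int lo = 0, hi = o1 - 1;
  while (lo < o1 && lo * s - p + a1 < 0) ++lo;
  while (hi >= 0 && hi * s - p + a1 >= d1) --hi;
  if (hi < lo) return;
  int ylo = 0, yhi = o2 - 1;
  while (ylo < o2 && ylo * s - p + a2 < 0) ++ylo;
  while (yhi >= 0 && yhi * s - p + a2 >= d2) --yhi;
  if (yhi < ylo) return;
  bool fullx = (s == 1 && lo == 0 && hi == o1 - 1 && o1 == d1);
  for (int z = 0; z < o3; ++z) {
    int sz = z * s - p + a3;
    if (sz < 0 || sz >= d3) continue;
    if (fullx) {
      size_t orow = (size_t)o1 * (ylo + (size_t)o2 * z);
      size_t srow = (size_t)d1 * ((ylo - p + a2) + (size_t)d2 * sz);
      f(orow, srow, o1 * (yhi - ylo + 1));
    } else {
      for (int y = ylo; y <= yhi; ++y) {
        size_t orow = lo + (size_t)o1 * (y + (size_t)o2 * z);
        size_t srow = (lo * s - p + a1) +
          (size_t)d1 * ((y * s - p + a2) + (size_t)d2 * sz);
        f(orow, srow, hi - lo + 1);
      }
    }
  }
}

// ---- handle construction / retrieval --------------------------------------

template <typename MT, typename T>
SEXP new_impl(NumericMatrix x) {
  MT *m = new MT(x.nrow(), x.ncol());
  const double *src = REAL(x);
  T *dst = m->memptr();
  for (size_t i = 0; i < m->n_elem; ++i) dst[i] = (T)src[i];
  return make_h<MT>(m);
}

// [[Rcpp::export]]
SEXP tz_new(NumericMatrix x, bool dbl) {
  return dbl ? new_impl<arma::mat, double>(x) : new_impl<arma::fmat, float>(x);
}

template <typename MT>
NumericMatrix get_impl(SEXP h) {
  MT *m = get_h<MT>(h);
  NumericMatrix out(m->n_rows, m->n_cols);
  for (size_t i = 0; i < m->n_elem; ++i) REAL(out)[i] = (double)m->memptr()[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix tz_get(SEXP h, bool dbl) {
  return dbl ? get_impl<arma::mat>(h) : get_impl<arma::fmat>(h);
}

// ---- convolution -----------------------------------------------------------

template <typename MT, typename T>
static void rearrange_W(const double *W, int k3, int Cin, int Cout, MT &W2) {
  W2.set_size(Cin, k3 * Cout);
  for (int cout = 0; cout < Cout; ++cout)
    for (int cin = 0; cin < Cin; ++cin)
      for (int off = 0; off < k3; ++off)
        W2(cin, off * Cout + cout) =
          (T)W[(off + (size_t)k3 * cin) + (size_t)k3 * Cin * cout];
}

template <typename MT, typename T>
static void im2col(const MT &x, int col0, int d1, int d2, int d3, int Cin,
                   int k, int s, int p, MT &col, size_t row0, size_t No,
                   size_t xrow0) {
  int k3 = k * k * k;
  for (int c = 0; c < Cin; ++c) {
    const T *xc = x.colptr(col0 + c) + xrow0;
    for (int a3 = 0; a3 < k; ++a3)
      for (int a2 = 0; a2 < k; ++a2)
        for (int a1 = 0; a1 < k; ++a1) {
          int off = a1 + k * (a2 + k * a3);
          T *cc = col.colptr(off + (size_t)k3 * c) + row0;
          std::fill(cc, cc + No, (T)0);
          offset_runs(d1, d2, d3, k, s, p, a1, a2, a3,
                      [&](size_t orow, size_t srow, int len) {
            for (int i = 0; i < len; ++i)
              cc[orow + i] = xc[srow + (size_t)i * s];
          });
        }
  }
}

template <typename MT, typename T>
SEXP conv_fwd_impl(SEXP hx, IntegerVector dims, int B, NumericMatrix W,
                   NumericVector b, int k, int s, int p) {
  MT &x = *get_h<MT>(hx);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int Cin = x.n_cols, Cout = W.ncol(), k3 = k * k * k;
  if ((int)W.nrow() != k3 * Cin) stop("weight/input channel mismatch");
  int o1 = outlen(d1, k, s, p), o2 = outlen(d2, k, s, p), o3 = outlen(d3, k, s, p);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("input too small for this convolution");
  size_t N = (size_t)d1 * d2 * d3, No = (size_t)o1 * o2 * o3;
  MT *y = new MT((size_t)B * No, Cout);
  // offset-gemm traffic scales with Cout, im2col traffic with Cin:
  // take the cheaper route
  if (s == 1 && Cin >= Cout) {
    MT W2;
    rearrange_W<MT, T>(REAL(W), k3, Cin, Cout, W2);
    MT Yall(scratch<T, 0>((size_t)B * N * k3 * Cout), (size_t)B * N,
            (size_t)k3 * Cout, false, true);
    Yall = x * W2;
    for (int c = 0; c < Cout; ++c) y->col(c).fill((T)b[c]);
    for (int a3 = 0; a3 < k; ++a3)
      for (int a2 = 0; a2 < k; ++a2)
        for (int a1 = 0; a1 < k; ++a1) {
          int off = a1 + k * (a2 + k * a3);
          for (int c = 0; c < Cout; ++c)
            for (int bb = 0; bb < B; ++bb) {
              T *yc = y->colptr(c) + bb * N;
              const T *src = Yall.colptr(off * Cout + c) + bb * N;
              offset_runs(d1, d2, d3, k, s, p, a1, a2, a3,
                          [&](size_t orow, size_t srow, int len) {
                for (int i = 0; i < len; ++i) yc[orow + i] += src[srow + i];
              });
            }
        }
  } else {
    MT col(scratch<T, 0>((size_t)B * No * k3 * Cin), (size_t)B * No,
           (size_t)k3 * Cin, false, true);
    for (int bb = 0; bb < B; ++bb)
      im2col<MT, T>(x, 0, d1, d2, d3, Cin, k, s, p, col, bb * No, No, bb * N);
    MT Wm(k3 * Cin, Cout);
    for (size_t i = 0; i < Wm.n_elem; ++i) Wm.memptr()[i] = (T)REAL(W)[i];
    *y = col * Wm;
    for (int c = 0; c < Cout; ++c) y->col(c) += (T)b[c];
  }
  return make_h<MT>(y);
}

// [[Rcpp::export]]
SEXP tz_conv_fwd(SEXP hx, IntegerVector dims, int B, NumericMatrix W,
                 NumericVector b, int k, int s, int p, bool dbl) {
  return dbl ? conv_fwd_impl<arma::mat, double>(hx, dims, B, W, b, k, s, p)
             : conv_fwd_impl<arma::fmat, float>(hx, dims, B, W, b, k, s, p);
}

template <typename MT, typename T>
List conv_bwd_impl(SEXP hx, IntegerVector dims, int B, NumericMatrix W,
                   SEXP hdy, int k, int s, int p, bool need_dx) {
  MT &x = *get_h<MT>(hx);
  MT &dy = *get_h<MT>(hdy);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int Cin = x.n_cols, Cout = W.ncol(), k3 = k * k * k;
  int o1 = outlen(d1, k, s, p), o2 = outlen(d2, k, s, p), o3 = outlen(d3, k, s, p);
  size_t N = (size_t)d1 * d2 * d3, No = (size_t)o1 * o2 * o3;
  if (dy.n_rows != (size_t)B * No || (int)dy.n_cols != Cout)
    stop("dy shape mismatch");
  NumericMatrix dW(k3 * Cin, Cout);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    double acc = 0;
    const T *dc = dy.colptr(c);
    for (size_t r = 0; r < (size_t)B * No; ++r) acc += (double)dc[r];
    db[c] = acc;
  }
  MT *dx = need_dx ? new MT((size_t)B * N, Cin) : nullptr;
  if (s == 1 && Cin >= Cout) {
    MT W2;
    rearrange_W<MT, T>(REAL(W), k3, Cin, Cout, W2);
    MT dYall(scratch<T, 0>((size_t)B * N * k3 * Cout), (size_t)B * N,
             (size_t)k3 * Cout, false, true);
    dYall.zeros();
    for (int a3 = 0; a3 < k; ++a3)
      for (int a2 = 0; a2 < k; ++a2)
        for (int a1 = 0; a1 < k; ++a1) {
          int off = a1 + k * (a2 + k * a3);
          for (int c = 0; c < Cout; ++c)
            for (int bb = 0; bb < B; ++bb) {
              const T *dyc = dy.colptr(c) + bb * N;
              T *dst = dYall.colptr(off * Cout + c) + bb * N;
              offset_runs(d1, d2, d3, k, s, p, a1, a2, a3,
                          [&](size_t orow, size_t srow, int len) {
                for (int i = 0; i < len; ++i) dst[srow + i] += dyc[orow + i];
              });
            }
        }
    MT dW2 = x.t() * dYall;
    for (int cout = 0; cout < Cout; ++cout)
      for (int cin = 0; cin < Cin; ++cin)
        for (int off = 0; off < k3; ++off)
          REAL(dW)[(off + (size_t)k3 * cin) + (size_t)k3 * Cin * cout] =
            (double)dW2(cin, off * Cout + cout);
    if (need_dx) *dx = dYall * W2.t();
  } else {
    MT col(scratch<T, 1>((size_t)B * No * k3 * Cin), (size_t)B * No,
           (size_t)k3 * Cin, false, true);
    for (int bb = 0; bb < B; ++bb)
      im2col<MT, T>(x, 0, d1, d2, d3, Cin, k, s, p, col, bb * No, No, bb * N);
    MT dWm = col.t() * dy;
    for (size_t i = 0; i < dWm.n_elem; ++i)
      REAL(dW)[i] = (double)dWm.memptr()[i];
    if (need_dx) {
      MT Wm(k3 * Cin, Cout);
      for (size_t i = 0; i < Wm.n_elem; ++i) Wm.memptr()[i] = (T)REAL(W)[i];
      MT dcol = dy * Wm.t();
      dx->zeros();
      for (int c = 0; c < Cin; ++c)
        for (int bb = 0; bb < B; ++bb) {
          T *xc = dx->colptr(c) + bb * N;
          for (int a3 = 0; a3 < k; ++a3)
            for (int a2 = 0; a2 < k; ++a2)
              for (int a1 = 0; a1 < k; ++a1) {
                int off = a1 + k * (a2 + k * a3);
                const T *cc = dcol.colptr(off + (size_t)k3 * c) + bb * No;
                offset_runs(d1, d2, d3, k, s, p, a1, a2, a3,
                            [&](size_t orow, size_t srow, int len) {
                  for (int i = 0; i < len; ++i)
                    xc[srow + (size_t)i * s] += cc[orow + i];
                });
              }
        }
    }
  }
  List out = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dx) out["dx"] = make_h<MT>(dx);
  return out;
}

// [[Rcpp::export]]
List tz_conv_bwd(SEXP hx, IntegerVector dims, int B, NumericMatrix W,
                 SEXP hdy, int k, int s, int p, bool need_dx, bool dbl) {
  return dbl
    ? conv_bwd_impl<arma::mat, double>(hx, dims, B, W, hdy, k, s, p, need_dx)
    : conv_bwd_impl<arma::fmat, float>(hx, dims, B, W, hdy, k, s, p, need_dx);
}

// ---- batch normalization ---------------------------------------------------

template <typename MT, typename T>
List bn_fwd_impl(SEXP hx, NumericVector gamma, NumericVector beta,
                 NumericVector run_mean, NumericVector run_var,
                 bool training, double momentum, double eps) {
  MT &x = *get_h<MT>(hx);
  size_t n = x.n_rows;
  int C = x.n_cols;
  NumericVector mu(C), va(C), istd(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      const T *xc = x.colptr(c);
      double s = 0, s2 = 0;
      for (size_t r = 0; r < n; ++r) { s += xc[r]; s2 += (double)xc[r] * xc[r]; }
      mu[c] = s / n;
      va[c] = std::max(0.0, s2 / n - mu[c] * mu[c]);
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = run_mean[c]; va[c] = run_var[c]; }
  }
  MT *xhat = new MT(n, C);
  MT *y = new MT(n, C);
  for (int c = 0; c < C; ++c) {
    istd[c] = 1.0 / std::sqrt(va[c] + eps);
    T a = (T)istd[c], m = (T)mu[c], g = (T)gamma[c], be = (T)beta[c];
    const T *xc = x.colptr(c);
    T *hc = xhat->colptr(c), *yc = y->colptr(c);
    for (size_t r = 0; r < n; ++r) {
      T h = (xc[r] - m) * a;
      hc[r] = h;
      yc[r] = g * h + be;
    }
  }
  NumericVector nrm = clone(run_mean), nrv = clone(run_var);
  if (training)
    for (int c = 0; c < C; ++c) {
      nrm[c] = momentum * nrm[c] + (1 - momentum) * mu[c];
      nrv[c] = momentum * nrv[c] + (1 - momentum) * va[c];
    }
  return List::create(_["y"] = make_h<MT>(y), _["xhat"] = make_h<MT>(xhat),
                      _["istd"] = istd, _["run_mean"] = nrm,
                      _["run_var"] = nrv);
}

// [[Rcpp::export]]
List tz_bn_fwd(SEXP hx, NumericVector gamma, NumericVector beta,
               NumericVector run_mean, NumericVector run_var,
               bool training, double momentum, double eps, bool dbl) {
  return dbl
    ? bn_fwd_impl<arma::mat, double>(hx, gamma, beta, run_mean, run_var,
                                     training, momentum, eps)
    : bn_fwd_impl<arma::fmat, float>(hx, gamma, beta, run_mean, run_var,
                                     training, momentum, eps);
}

template <typename MT, typename T>
List bn_bwd_impl(SEXP hdy, SEXP hxhat, NumericVector gamma,
                 NumericVector istd) {
  MT &dy = *get_h<MT>(hdy);
  MT &xhat = *get_h<MT>(hxhat);
  size_t n = dy.n_rows;
  int C = dy.n_cols;
  NumericVector dgamma(C), dbeta(C);
  MT *dx = new MT(n, C);
  for (int c = 0; c < C; ++c) {
    const T *dc = dy.colptr(c), *hc = xhat.colptr(c);
    double sg = 0, sb = 0;
    for (size_t r = 0; r < n; ++r) { sg += (double)dc[r] * hc[r]; sb += dc[r]; }
    dgamma[c] = sg; dbeta[c] = sb;
    T g = (T)gamma[c], a = (T)istd[c];
    T s1 = (T)(sb * gamma[c] / n), s2 = (T)(sg * gamma[c] / n);
    T *oc = dx->colptr(c);
    for (size_t r = 0; r < n; ++r)
      oc[r] = (g * dc[r] - s1 - hc[r] * s2) * a;
  }
  return List::create(_["dx"] = make_h<MT>(dx), _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List tz_bn_bwd(SEXP hdy, SEXP hxhat, NumericVector gamma, NumericVector istd,
               bool dbl) {
  return dbl ? bn_bwd_impl<arma::mat, double>(hdy, hxhat, gamma, istd)
             : bn_bwd_impl<arma::fmat, float>(hdy, hxhat, gamma, istd);
}

// ---- activations and dropout ----------------------------------------------

template <typename MT, typename T>
SEXP lrelu_fwd_impl(SEXP hx, double alpha) {
  MT &x = *get_h<MT>(hx);
  MT *y = new MT(x.n_rows, x.n_cols);
  const T *xp = x.memptr(); T *yp = y->memptr();
  T al = (T)alpha;
  for (size_t i = 0; i < x.n_elem; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : al * xp[i];
  return make_h<MT>(y);
}

// leaky ReLU; alpha = 0 gives plain ReLU. Backward recovers the mask from
// the forward output's sign (valid for alpha >= 0).
// [[Rcpp::export]]
SEXP tz_lrelu_fwd(SEXP hx, double alpha, bool dbl) {
  return dbl ? lrelu_fwd_impl<arma::mat, double>(hx, alpha)
             : lrelu_fwd_impl<arma::fmat, float>(hx, alpha);
}

template <typename MT, typename T>
SEXP lrelu_bwd_impl(SEXP hdy, SEXP hy, double alpha) {
  MT &dy = *get_h<MT>(hdy);
  MT &y = *get_h<MT>(hy);
  MT *dx = new MT(dy.n_rows, dy.n_cols);
  const T *dp = dy.memptr(), *yp = y.memptr();
  T *op = dx->memptr();
  T al = (T)alpha;
  for (size_t i = 0; i < dy.n_elem; ++i)
    op[i] = yp[i] > 0 ? dp[i] : al * dp[i];
  return make_h<MT>(dx);
}

// [[Rcpp::export]]
SEXP tz_lrelu_bwd(SEXP hdy, SEXP hy, double alpha, bool dbl) {
  return dbl ? lrelu_bwd_impl<arma::mat, double>(hdy, hy, alpha)
             : lrelu_bwd_impl<arma::fmat, float>(hdy, hy, alpha);
}

template <typename MT, typename T>
List dropout_fwd_impl(SEXP hx, double rate) {
  MT &x = *get_h<MT>(hx);
  MT *y = new MT(x.n_rows, x.n_cols);
  MT *mask = new MT(x.n_rows, x.n_cols);
  const T *xp = x.memptr(); T *yp = y->memptr(); T *mp = mask->memptr();
  T scale = (T)(1.0 / (1.0 - rate));
  for (size_t i = 0; i < x.n_elem; ++i) {
    T m = (unif_rand() >= rate) ? scale : (T)0; // R's RNG: reproducible
    mp[i] = m;
    yp[i] = xp[i] * m;
  }
  return List::create(_["y"] = make_h<MT>(y), _["mask"] = make_h<MT>(mask));
}

// [[Rcpp::export]]
List tz_dropout_fwd(SEXP hx, double rate, bool dbl) {
  return dbl ? dropout_fwd_impl<arma::mat, double>(hx, rate)
             : dropout_fwd_impl<arma::fmat, float>(hx, rate);
}

template <typename MT, typename T>
SEXP mul_impl(SEXP ha, SEXP hb) {
  MT &a = *get_h<MT>(ha);
  MT &b = *get_h<MT>(hb);
  MT *y = new MT(a.n_rows, a.n_cols);
  for (size_t i = 0; i < a.n_elem; ++i)
    y->memptr()[i] = a.memptr()[i] * b.memptr()[i];
  return make_h<MT>(y);
}

// elementwise product (dropout backward etc.)
// [[Rcpp::export]]
SEXP tz_mul(SEXP ha, SEXP hb, bool dbl) {
  return dbl ? mul_impl<arma::mat, double>(ha, hb)
             : mul_impl<arma::fmat, float>(ha, hb);
}

template <typename MT, typename T>
SEXP add_impl(SEXP ha, SEXP hb) {
  MT &a = *get_h<MT>(ha);
  MT &b = *get_h<MT>(hb);
  MT *y = new MT(a);
  *y += b;
  return make_h<MT>(y);
}

// [[Rcpp::export]]
SEXP tz_add(SEXP ha, SEXP hb, bool dbl) {
  return dbl ? add_impl<arma::mat, double>(ha, hb)
             : add_impl<arma::fmat, float>(ha, hb);
}

// ---- pooling / upsampling / concat ----------------------------------------

template <typename MT, typename T>
List maxpool_fwd_impl(SEXP hx, IntegerVector dims, int B) {
  MT &x = *get_h<MT>(hx);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = x.n_cols;
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("max-pool needs even dims");
  int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  size_t No = (size_t)o1 * o2 * o3, N = (size_t)d1 * d2 * d3;
  MT *y = new MT((size_t)B * No, C);
  std::vector<int> *idx = new std::vector<int>((size_t)B * No * C);
  for (int c = 0; c < C; ++c) {
    const T *xc = x.colptr(c);
    T *yc = y->colptr(c);
    int *ic = idx->data() + (size_t)c * B * No;
    for (int bb = 0; bb < B; ++bb) {
      size_t r = bb * No;
      for (int z = 0; z < o3; ++z)
        for (int yy = 0; yy < o2; ++yy)
          for (int xx = 0; xx < o1; ++xx, ++r) {
            T best = (T)-1e30; size_t bi = 0;
            for (int az = 0; az < 2; ++az)
              for (int ay = 0; ay < 2; ++ay)
                for (int ax = 0; ax < 2; ++ax) {
                  size_t si = bb * N + (2 * xx + ax) +
                    (size_t)d1 * ((2 * yy + ay) + (size_t)d2 * (2 * z + az));
                  if (xc[si] > best) { best = xc[si]; bi = si; }
                }
            yc[r] = best; ic[r] = (int)bi;
          }
    }
  }
  return List::create(_["y"] = make_h<MT>(y),
                      _["idx"] = XPtr<std::vector<int>>(idx, true),
                      _["outdims"] = IntegerVector::create(o1, o2, o3));
}

// [[Rcpp::export]]
List tz_maxpool_fwd(SEXP hx, IntegerVector dims, int B, bool dbl) {
  return dbl ? maxpool_fwd_impl<arma::mat, double>(hx, dims, B)
             : maxpool_fwd_impl<arma::fmat, float>(hx, dims, B);
}

template <typename MT, typename T>
SEXP maxpool_bwd_impl(SEXP hdy, SEXP hidx, int NB) {
  MT &dy = *get_h<MT>(hdy);
  std::vector<int> &idx = *XPtr<std::vector<int>>(hidx);
  size_t No = dy.n_rows;
  int C = dy.n_cols;
  MT *dx = new MT((size_t)NB, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const T *dc = dy.colptr(c);
    const int *ic = idx.data() + (size_t)c * No;
    T *xc = dx->colptr(c);
    for (size_t r = 0; r < No; ++r) xc[ic[r]] += dc[r];
  }
  return make_h<MT>(dx);
}

// [[Rcpp::export]]
SEXP tz_maxpool_bwd(SEXP hdy, SEXP hidx, int NB, bool dbl) {
  return dbl ? maxpool_bwd_impl<arma::mat, double>(hdy, hidx, NB)
             : maxpool_bwd_impl<arma::fmat, float>(hdy, hidx, NB);
}

template <typename MT, typename T>
SEXP upsample_fwd_impl(SEXP hx, IntegerVector dims, int B) {
  MT &x = *get_h<MT>(hx);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = x.n_cols;
  int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  size_t N = (size_t)d1 * d2 * d3, No = (size_t)o1 * o2 * o3;
  MT *y = new MT((size_t)B * No, C);
  for (int c = 0; c < C; ++c)
    for (int bb = 0; bb < B; ++bb) {
      const T *xc = x.colptr(c) + bb * N;
      T *yc = y->colptr(c) + bb * No;
      for (int z = 0; z < o3; ++z)
        for (int yy = 0; yy < o2; ++yy) {
          const T *row = xc + (size_t)d1 * ((yy / 2) + (size_t)d2 * (z / 2));
          T *orow = yc + (size_t)o1 * (yy + (size_t)o2 * z);
          for (int xx = 0; xx < o1; ++xx) orow[xx] = row[xx / 2];
        }
    }
  return make_h<MT>(y);
}

// [[Rcpp::export]]
SEXP tz_upsample_fwd(SEXP hx, IntegerVector dims, int B, bool dbl) {
  return dbl ? upsample_fwd_impl<arma::mat, double>(hx, dims, B)
             : upsample_fwd_impl<arma::fmat, float>(hx, dims, B);
}

template <typename MT, typename T>
SEXP upsample_bwd_impl(SEXP hdy, IntegerVector indims, int B) {
  MT &dy = *get_h<MT>(hdy);
  int d1 = indims[0], d2 = indims[1], d3 = indims[2], C = dy.n_cols;
  int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  size_t N = (size_t)d1 * d2 * d3, No = (size_t)o1 * o2 * o3;
  MT *dx = new MT((size_t)B * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int bb = 0; bb < B; ++bb) {
      const T *dc = dy.colptr(c) + bb * No;
      T *xc = dx->colptr(c) + bb * N;
      for (int z = 0; z < o3; ++z)
        for (int yy = 0; yy < o2; ++yy) {
          const T *orow = dc + (size_t)o1 * (yy + (size_t)o2 * z);
          T *row = xc + (size_t)d1 * ((yy / 2) + (size_t)d2 * (z / 2));
          for (int xx = 0; xx < o1; ++xx) row[xx / 2] += orow[xx];
        }
    }
  return make_h<MT>(dx);
}

// [[Rcpp::export]]
SEXP tz_upsample_bwd(SEXP hdy, IntegerVector indims, int B, bool dbl) {
  return dbl ? upsample_bwd_impl<arma::mat, double>(hdy, indims, B)
             : upsample_bwd_impl<arma::fmat, float>(hdy, indims, B);
}

template <typename MT, typename T>
SEXP concat_impl(SEXP ha, SEXP hb) {
  MT &a = *get_h<MT>(ha);
  MT &b = *get_h<MT>(hb);
  MT *y = new MT(arma::join_rows(a, b));
  return make_h<MT>(y);
}

// channel concatenation [a | b]
// [[Rcpp::export]]
SEXP tz_concat(SEXP ha, SEXP hb, bool dbl) {
  return dbl ? concat_impl<arma::mat, double>(ha, hb)
             : concat_impl<arma::fmat, float>(ha, hb);
}

template <typename MT, typename T>
List split_impl(SEXP h, int c1) {
  MT &x = *get_h<MT>(h);
  MT *a = new MT(x.cols(0, c1 - 1));
  MT *b = new MT(x.cols(c1, x.n_cols - 1));
  return List::create(_["a"] = make_h<MT>(a), _["b"] = make_h<MT>(b));
}

// split channels into [1..c1] and [c1+1..C]
// [[Rcpp::export]]
List tz_split(SEXP h, int c1, bool dbl) {
  return dbl ? split_impl<arma::mat, double>(h, c1)
             : split_impl<arma::fmat, float>(h, c1);
}

// ---- attention gate ---------------------------------------------------------

template <typename MT, typename T>
List gate_fwd_impl(SEXP hx, SEXP hd, NumericMatrix Wg, NumericMatrix Wf,
                   double w, double b, int B) {
  MT &x = *get_h<MT>(hx);
  MT &d = *get_h<MT>(hd);
  if (x.n_rows != d.n_rows)
    stop("encoder/decoder feature maps must share their spatial size");
  size_t NB = x.n_rows, N = NB / B;
  int K = Wg.ncol();
  MT Wgm(x.n_cols, K), Wfm(d.n_cols, K);
  for (size_t i = 0; i < Wgm.n_elem; ++i) Wgm.memptr()[i] = (T)REAL(Wg)[i];
  for (size_t i = 0; i < Wfm.n_elem; ++i) Wfm.memptr()[i] = (T)REAL(Wf)[i];
  MT *g = new MT(x * Wgm);
  MT *f = new MT(d * Wfm);
  MT *alpha = new MT(NB, 1);
  {
    arma::Col<T> a = arma::sum((*f) % (*g), 1);
    std::copy(a.memptr(), a.memptr() + NB, alpha->memptr());
  }
  MT *r = new MT(NB, 1);
  for (int bb = 0; bb < B; ++bb) {
    const T *ap = alpha->memptr() + bb * N;
    T *rp = r->memptr() + bb * N;
    double mx = -1e300;
    for (size_t i = 0; i < N; ++i) {
      double s = w * std::max((double)ap[i], 0.0) + b;
      rp[i] = (T)s;
      if (s > mx) mx = s;
    }
    double tot = 0;
    for (size_t i = 0; i < N; ++i) { rp[i] = (T)std::exp((double)rp[i] - mx); tot += rp[i]; }
    for (size_t i = 0; i < N; ++i) rp[i] = (T)(rp[i] / tot);
  }
  MT *att = new MT(x.n_rows, x.n_cols);
  for (int c = 0; c < (int)x.n_cols; ++c) {
    const T *xc = x.colptr(c);
    T *ac = att->colptr(c);
    const T *rp = r->memptr();
    for (size_t i = 0; i < NB; ++i) ac[i] = (T)N * rp[i] * xc[i];
  }
  return List::create(_["att"] = make_h<MT>(att), _["r"] = make_h<MT>(r),
                      _["g"] = make_h<MT>(g), _["f"] = make_h<MT>(f),
                      _["alpha"] = make_h<MT>(alpha));
}

// [[Rcpp::export]]
List tz_gate_fwd(SEXP hx, SEXP hd, NumericMatrix Wg, NumericMatrix Wf,
                 double w, double b, int B, bool dbl) {
  return dbl ? gate_fwd_impl<arma::mat, double>(hx, hd, Wg, Wf, w, b, B)
             : gate_fwd_impl<arma::fmat, float>(hx, hd, Wg, Wf, w, b, B);
}

template <typename MT, typename T>
List gate_bwd_impl(SEXP hdatt, SEXP hx, SEXP hd, SEXP hg, SEXP hf,
                   SEXP halpha, SEXP hr, NumericMatrix Wg, NumericMatrix Wf,
                   double w, int B) {
  MT &datt = *get_h<MT>(hdatt);
  MT &x = *get_h<MT>(hx);
  MT &d = *get_h<MT>(hd);
  MT &g = *get_h<MT>(hg);
  MT &f = *get_h<MT>(hf);
  MT &alpha = *get_h<MT>(halpha);
  MT &r = *get_h<MT>(hr);
  size_t NB = x.n_rows, N = NB / B;
  MT Wgm(x.n_cols, Wg.ncol()), Wfm(d.n_cols, Wf.ncol());
  for (size_t i = 0; i < Wgm.n_elem; ++i) Wgm.memptr()[i] = (T)REAL(Wg)[i];
  for (size_t i = 0; i < Wfm.n_elem; ++i) Wfm.memptr()[i] = (T)REAL(Wf)[i];
  // dr_i = N * sum_c datt_ic x_ic ; dx (direct part) = N r_i datt_ic
  MT *dx = new MT(x.n_rows, x.n_cols);
  arma::Col<T> dr(NB, arma::fill::zeros);
  for (int c = 0; c < (int)x.n_cols; ++c) {
    const T *xc = x.colptr(c), *dc = datt.colptr(c), *rp = r.memptr();
    T *oc = dx->colptr(c);
    for (size_t i = 0; i < NB; ++i) {
      dr[i] += dc[i] * xc[i];
      oc[i] = (T)N * rp[i] * dc[i];
    }
  }
  dr *= (T)N;
  // softmax backward per sample, then psi (w) and ReLU
  arma::Col<T> ds(NB);
  double dw = 0, db = 0;
  const T *ap = alpha.memptr(), *rp = r.memptr();
  for (int bb = 0; bb < B; ++bb) {
    double rdr = 0;
    for (size_t i = bb * N; i < (bb + 1) * N; ++i) rdr += (double)rp[i] * dr[i];
    for (size_t i = bb * N; i < (bb + 1) * N; ++i) {
      ds[i] = (T)(rp[i] * ((double)dr[i] - rdr));
      double e = std::max((double)ap[i], 0.0);
      dw += (double)ds[i] * e;
      db += (double)ds[i];
    }
  }
  arma::Col<T> dalpha(NB);
  for (size_t i = 0; i < NB; ++i)
    dalpha[i] = ap[i] > 0 ? (T)w * ds[i] : (T)0;
  MT dg = f; dg.each_col() %= dalpha;
  MT df = g; df.each_col() %= dalpha;
  MT dWg = x.t() * dg;
  MT dWf = d.t() * df;
  *dx += dg * Wgm.t();
  MT *dd = new MT(df * Wfm.t());
  NumericMatrix dWg_r(Wg.nrow(), Wg.ncol()), dWf_r(Wf.nrow(), Wf.ncol());
  for (size_t i = 0; i < dWg.n_elem; ++i) REAL(dWg_r)[i] = (double)dWg.memptr()[i];
  for (size_t i = 0; i < dWf.n_elem; ++i) REAL(dWf_r)[i] = (double)dWf.memptr()[i];
  return List::create(_["dx"] = make_h<MT>(dx), _["dd"] = make_h<MT>(dd),
                      _["dWg"] = dWg_r, _["dWf"] = dWf_r,
                      _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List tz_gate_bwd(SEXP hdatt, SEXP hx, SEXP hd, SEXP hg, SEXP hf, SEXP halpha,
                 SEXP hr, NumericMatrix Wg, NumericMatrix Wf, double w,
                 int B, bool dbl) {
  return dbl
    ? gate_bwd_impl<arma::mat, double>(hdatt, hx, hd, hg, hf, halpha, hr,
                                       Wg, Wf, w, B)
    : gate_bwd_impl<arma::fmat, float>(hdatt, hx, hd, hg, hf, halpha, hr,
                                       Wg, Wf, w, B);
}

// per-sample spatial mean over the single final channel (PatchGAN logit)
// [[Rcpp::export]]
NumericVector tz_sample_means(SEXP h, int B, bool dbl) {
  NumericVector out(B);
  if (dbl) {
    arma::mat &x = *get_h<arma::mat>(h);
    size_t N = x.n_rows / B;
    for (int bb = 0; bb < B; ++bb) {
      double s = 0;
      for (size_t i = bb * N; i < (bb + 1) * N; ++i) s += x.memptr()[i];
      out[bb] = s / N;
    }
  } else {
    arma::fmat &x = *get_h<arma::fmat>(h);
    size_t N = x.n_rows / B;
    for (int bb = 0; bb < B; ++bb) {
      double s = 0;
      for (size_t i = bb * N; i < (bb + 1) * N; ++i) s += x.memptr()[i];
      out[bb] = s / N;
    }
  }
  return out;
}

// fused Adam leaf update: one pass, minimal allocations
// [[Rcpp::export]]
List tz_adam_leaf(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double lr, double c1, double c2,
                  double beta1, double beta2, double eps) {
  R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  const double *pp = REAL(p), *gp = REAL(g), *mp = REAL(m), *vp = REAL(v);
  double *po = REAL(p2), *mo = REAL(m2), *vo = REAL(v2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = beta1 * mp[i] + (1 - beta1) * gp[i];
    double vi = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    mo[i] = mi; vo[i] = vi;
    po[i] = pp[i] - (lr / c1) * mi / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
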