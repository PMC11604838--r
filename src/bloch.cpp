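#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hard-pulse Bloch propagation. Each dwell applies the exact rotation
//   m' = R(v) m,  v = -2*pi*dt * (gamma*c*b1x, gamma*c*b1y, db0)   [Hz]
// (right-handed Rodrigues rotation; the sign encodes the precession
// convention dM/dt = 2*pi * M x B with B in Hz). db0 collects the static
// offset of the point, any B0-map value, and the instantaneous gradient
// field gamma*G(t).r.

static inline void rodrigues(const double v[3], const double m[3], double out[3]) {
  double th2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  if (th2 < 1e-32) {
    // v x m to first order
    out[0] = m[0] + (v[1] * m[2] - v[2] * m[1]);
    out[1] = m[1] + (v[2] * m[0] - v[0] * m[2]);
    out[2] = m[2] + (v[0] * m[1] - v[1] * m[0]);
    return;
  }
  double th = std::sqrt(th2);
  double u0 = v[0] / th, u1 = v[1] / th, u2 = v[2] / th;
  double c = std::cos(th), s = std::sin(th), omc = 1.0 - c;
  double dot = u0 * m[0] + u1 * m[1] + u2 * m[2];
  double cx0 = u1 * m[2] - u2 * m[1];
  double cx1 = u2 * m[0] - u0 * m[2];
  double cx2 = u0 * m[1] - u1 * m[0];
  out[0] = c * m[0] + s * cx0 + omc * dot * u0;
  out[1] = c * m[1] + s * cx1 + omc * dot * u1;
  out[2] = c * m[2] + s * cx2 + omc * dot * u2;
}

// columns of R(v) (applies rodrigues to the basis vectors)
static inline void rot_columns(const double v[3], double R[9]) {
  double e[3], col[3];
  for (int j = 0; j < 3; ++j) {
    e[0] = e[1] = e[2] = 0.0; e[j] = 1.0;
    rodrigues(v, e, col);
    R[3 * j + 0] = col[0];
    R[3 * j + 1] = col[1];
    R[3 * j + 2] = col[2];
  }
}

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// d(R(v) m)/dv_i contracted with adjoint a: returns g[i] = a . dR/dv_i . m
// Uses dR/dv_i = ((v_i [v]x + [v x (I - R) e_i]x) / |v|^2) R  (exact), with the
// small-angle limit dR/dv_i -> [e_i]x.
static inline void rot_vjp(const double v[3], const double m1[3],
                           const double a[3], const double R[9], double g[3]) {
  double th2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  if (th2 < 1e-16) {
    // g_i = a . (e_i x m1)
    double c[3];
    for (int i = 0; i < 3; ++i) {
      double e[3] = {0.0, 0.0, 0.0}; e[i] = 1.0;
      cross3(e, m1, c);
      g[i] = a[0] * c[0] + a[1] * c[1] + a[2] * c[2];
    }
    return;
  }
  double vxm[3];
  cross3(v, m1, vxm);
  for (int i = 0; i < 3; ++i) {
    double imr[3]; // (I - R) e_i
    imr[0] = (i == 0 ? 1.0 : 0.0) - R[3 * i + 0];
    imr[1] = (i == 1 ? 1.0 : 0.0) - R[3 * i + 1];
    imr[2] = (i == 2 ? 1.0 : 0.0) - R[3 * i + 2];
    double w[3], wxm[3];
    cross3(v, imr, w);
    cross3(w, m1, wxm);
    double d0 = (v[i] * vxm[0] + wxm[0]) / th2;
    double d1 = (v[i] * vxm[1] + wxm[1]) / th2;
    double d2 = (v[i] * vxm[2] + wxm[2]) / th2;
    g[i] = a[0] * d0 + a[1] * d1 + a[2] * d2;
  }
}

struct SimArgs {
  int n, npts;
  const double *re, *im;
  const double *gx, *gy, *gz; // may be null
  const double *px, *py, *pz;
  const double *offs, *cvec, *db0map;
  double dt, rewind, gam_ut, gam_grad;
};

static inline void point_fields(const SimArgs &A, int p, int j,
                                double &bx, double &by, double &bz) {
  double c = A.cvec[p];
  bx = A.gam_ut * c * A.re[j];
  by = A.gam_ut * c * A.im[j];
  bz = A.offs[p] + A.db0map[p];
  if (A.gx) bz += A.gam_grad * (A.gx[j] * A.px[p] + A.gy[j] * A.py[p] + A.gz[j] * A.pz[p]);
}

// [[Rcpp::export(name = ".bloch_forward_cpp")]]
List bloch_forward_cpp(NumericVector re, NumericVector im,
                       Nullable<NumericMatrix> grad,
                       NumericMatrix pos, NumericVector offs,
                       NumericVector cvec, NumericVector db0map,
                       NumericMatrix minit,
                       double dwell, double rewind,
                       double gamma_hz_per_ut, double gamma_hz_per_mtm,
                       bool save_traj) {
  const int n = re.size(), npts = offs.size();
  SimArgs A;
  A.n = n; A.npts = npts;
  A.re = re.begin(); A.im = im.begin();
  A.gx = A.gy = A.gz = nullptr;
  NumericMatrix gmat;
  if (grad.isNotNull()) {
    gmat = NumericMatrix(grad);
    A.gx = &gmat(0, 0); A.gy = &gmat(0, 1); A.gz = &gmat(0, 2);
  }
  A.px = &pos(0, 0); A.py = &pos(0, 1); A.pz = &pos(0, 2);
  A.offs = offs.begin(); A.cvec = cvec.begin(); A.db0map = db0map.begin();
  A.dt = dwell; A.rewind = rewind;
  A.gam_ut = gamma_hz_per_ut; A.gam_grad = gamma_hz_per_mtm;

  const int nst = n + (rewind != 0.0 ? 1 : 0);
  NumericMatrix M(npts, 3);
  NumericVector traj;
  double *tr = nullptr;
  if (save_traj) {
    traj = NumericVector((R_xlen_t)3 * npts * (nst + 1));
    tr = traj.begin();
  }
  const double twopidt = -2.0 * M_PI * dwell;

  for (int p = 0; p < npts; ++p) {
    double m[3] = {minit(p, 0), minit(p, 1), minit(p, 2)};
    if (tr) {
      tr[(R_xlen_t)3 * p + 0] = m[0];
      tr[(R_xlen_t)3 * p + 1] = m[1];
      tr[(R_xlen_t)3 * p + 2] = m[2];
    }
    double out[3];
    for (int j = 0; j < n; ++j) {
      double bx, by, bz;
      point_fields(A, p, j, bx, by, bz);
      double v[3] = {twopidt * bx, twopidt * by, twopidt * bz};
      rodrigues(v, m, out);
      m[0] = out[0]; m[1] = out[1]; m[2] = out[2];
      if (tr) {
        R_xlen_t base = ((R_xlen_t)(j + 1) * npts + p) * 3;
        tr[base] = m[0]; tr[base + 1] = m[1]; tr[base + 2] = m[2];
      }
    }
    if (rewind != 0.0) {
      double bz = A.offs[p];
      double v[3] = {0.0, 0.0, -2.0 * M_PI * rewind * bz};
      rodrigues(v, m, out);
      m[0] = out[0]; m[1] = out[1]; m[2] = out[2];
      if (tr) {
        R_xlen_t base = ((R_xlen_t)(n + 1) * npts + p) * 3;
        tr[base] = m[0]; tr[base + 1] = m[1]; tr[base + 2] = m[2];
      }
    }
    M(p, 0) = m[0]; M(p, 1) = m[1]; M(p, 2) = m[2];
  }
  if (save_traj) return List::create(_["M"] = M, _["traj"] = traj);
  return List::create(_["M"] = M);
}

// Reverse-mode pass: given dL/dM_final, accumulate dL/d re_j and dL/d im_j.
// [[Rcpp::export(name = ".bloch_backward_cpp")]]
List bloch_backward_cpp(NumericVector re, NumericVector im,
                        Nullable<NumericMatrix> grad,
                        NumericMatrix pos, NumericVector offs,
                        NumericVector cvec, NumericVector db0map,
                        double dwell, double rewind,
                        double gamma_hz_per_ut, double gamma_hz_per_mtm,
                        NumericVector traj, NumericMatrix gM) {
  const int n = re.size(), npts = offs.size();
  SimArgs A;
  A.n = n; A.npts = npts;
  A.re = re.begin(); A.im = im.begin();
  A.gx = A.gy = A.gz = nullptr;
  NumericMatrix gmat;
  if (grad.isNotNull()) {
    gmat = NumericMatrix(grad);
    A.gx = &gmat(0, 0); A.gy = &gmat(0, 1); A.gz = &gmat(0, 2);
  }
  A.px = &pos(0, 0); A.py = &pos(0, 1); A.pz = &pos(0, 2);
  A.offs = offs.begin(); A.cvec = cvec.begin(); A.db0map = db0map.begin();
  A.dt = dwell; A.rewind = rewind;
  A.gam_ut = gamma_hz_per_ut; A.gam_grad = gamma_hz_per_mtm;

  const double *tr = traj.begin();
  NumericVector gre(n), gim(n);
  const double twopidt = -2.0 * M_PI * dwell;

  for (int p = 0; p < npts; ++p) {
    double a[3] = {gM(p, 0), gM(p, 1), gM(p, 2)};
    if (rewind != 0.0) {
      double v[3] = {0.0, 0.0, -2.0 * M_PI * rewind * A.offs[p]};
      // a <- R^T a : rotate adjoint by -v
      double vm[3] = {-v[0], -v[1], -v[2]}, out[3];
      rodrigues(vm, a, out);
      a[0] = out[0]; a[1] = out[1]; a[2] = out[2];
    }
    const double cg = A.gam_ut * A.cvec[p] * twopidt;
    for (int j = n - 1; j >= 0; --j) {
      double bx, by, bz;
      point_fields(A, p, j, bx, by, bz);
      double v[3] = {twopidt * bx, twopidt * by, twopidt * bz};
      R_xlen_t base = ((R_xlen_t)(j + 1) * npts + p) * 3;
      double m1[3] = {tr[base], tr[base + 1], tr[base + 2]};
      double R[9];
      rot_columns(v, R);
      double g[3];
      rot_vjp(v, m1, a, R, g);
      gre[j] += g[0] * cg;
      gim[j] += g[1] * cg;
      // a <- R^T a
      double at[3];
      at[0] = R[0] * a[0] + R[1] * a[1] + R[2] * a[2];
      at[1] = R[3] * a[0] + R[4] * a[1] + R[5] * a[2];
      at[2] = R[6] * a[0] + R[7] * a[1] + R[8] * a[2];
      a[0] = at[0]; a[1] = at[1]; a[2] = at[2];
    }
  }
  return List::create(_["g_re"] = gre, _["g_im"] = gim);
}

// Fused AdamW step for a dense layer whose weight gradient is the rank-one
// outer product gy %o% x (single-design training: batch size is 1). Updates
// W, mW, vW in place; decoupled weight decay.
// [[Rcpp::export(name = ".adamw_dense_cpp")]]
void adamw_dense_cpp(NumericMatrix W, NumericMatrix mW, NumericMatrix vW,
                     NumericVector gy, NumericVector x,
                     double lr, double beta1, double beta2, double eps,
                     double wd, int step) {
  const int nr = W.nrow(), nc = W.ncol();
  double *w = W.begin(), *m = mW.begin(), *v = vW.begin();
  const double *g = gy.begin(), *xx = x.begin();
  const double bc1 = 1.0 - std::pow(beta1, step);
  const double bc2 = 1.0 - std::pow(beta2, step);
  for (int j = 0; j < nc; ++j) {
    const double xj = xx[j];
    const R_xlen_t off = (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const double gij = g[i] * xj;
      const R_xlen_t k = off + i;
      m[k] = beta1 * m[k] + (1.0 - beta1) * gij;
      v[k] = beta2 * v[k] + (1.0 - beta2) * gij * gij;
      const double mhat = m[k] / bc1;
      const double vhat = v[k] / bc2;
      w[k] -= lr * (mhat / (std::sqrt(vhat) + eps) + wd * w[k]);
    }
  }
}

// Same update for a bias (or any parameter vector with explicit gradient).
// [[Rcpp::export(name = ".adamw_vec_cpp")]]
void adamw_vec_cpp(NumericVector b, NumericVector mB, NumericVector vB,
                   NumericVector gb,
                   double lr, double beta1, double beta2, double eps,
                   double wd, int step) {
  const R_xlen_t nn = b.size();
  double *w = b.begin(), *m = mB.begin(), *v = vB.begin();
  const double *g = gb.begin();
  const double bc1 = 1.0 - std::pow(beta1, step);
  const double bc2 = 1.0 - std::pow(beta2, step);
  for (R_xlen_t k = 0; k < nn; ++k) {
    m[k] = beta1 * m[k] + (1.0 - beta1) * g[k];
    v[k] = beta2 * v[k] + (1.0 - beta2) * g[k] * g[k];
    w[k] -= lr * ((m[k] / bc1) / (std::sqrt(v[k] / bc2) + eps) + wd * w[k]);
  }
}
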