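#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "nfvm_kernels.h"
using namespace Rcpp;

// Prism-cell monolayer. Each cell is a pair of polygon loops over a shared 3D
// vertex set: apical loop (CCW viewed from +z) and basal loop in matching
// order (basal corner k lies beneath apical corner k). Flat storage:
//   avert/bvert[cell_ptr[c] .. cell_ptr[c+1]-1], 0-based vertex rows,
//   xoff[k]: per-corner x shift (periodic image along AP), same for both
//   loops.
// Energy per cell (dimensionless):
//   alpha*a_a + beta*a_b + 0.5*a_l + kp*(p_a - p0_c)^2 + kV*(v - 1)^2
// Faces are fan-triangulated about their vertex centroid; cell volume is the
// divergence-theorem sum (1/6) sum a.(b x c) over the outward-oriented
// closed triangulated surface. Inner kernels work on raw buffers.

#define MAXM 16  // maximum polygon loop length

static inline void cross3(const double* u, const double* v, double* w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}
static inline double dot3(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

// C1 smoothing (energy/gradient path only): triangle-area norms |n| ->
// sqrt(|n|^2 + eps2) and apical edge lengths likewise, so that collapsed
// apical edges of constricting cells are smooth stationary points instead
// of subgradient kinks. eps2 = 0 gives the exact observables.
#define NFVM_EPS2 1e-8

// area and signed 6*volume contribution of one fan-triangulated face given
// its outward-ordered corner loop P (m x 3, row-major)
static void face_measures(const double* P, int m, double* area,
                          double* vol6, double eps2) {
  double g[3] = {0, 0, 0};
  for (int j = 0; j < m; ++j)
    for (int d = 0; d < 3; ++d) g[d] += P[3 * j + d];
  for (int d = 0; d < 3; ++d) g[d] /= m;
  double A = 0.0, V6 = 0.0;
  for (int j = 0; j < m; ++j) {
    const double* b = P + 3 * j;
    const double* c = P + 3 * ((j + 1) % m);
    double u[3] = {b[0] - g[0], b[1] - g[1], b[2] - g[2]};
    double v[3] = {c[0] - g[0], c[1] - g[1], c[2] - g[2]};
    double n[3];
    cross3(u, v, n);
    A += 0.5 * std::sqrt(dot3(n, n) + eps2);
    double bc[3];
    cross3(b, c, bc);
    V6 += dot3(g, bc);
  }
  *area = A;
  *vol6 = V6;
}

// gradient of (w_area * face_area + w_vol * face_volume) wrt the face
// corners, accumulated into G (m x 3), including the centroid chain rule
static void face_grad(const double* P, int m, double w_area, double w_vol,
                      double* G, double eps2) {
  double g[3] = {0, 0, 0};
  for (int j = 0; j < m; ++j)
    for (int d = 0; d < 3; ++d) g[d] += P[3 * j + d];
  for (int d = 0; d < 3; ++d) g[d] /= m;
  double gsum[3] = {0, 0, 0};  // accumulated d/dg, spread over corners
  for (int j = 0; j < m; ++j) {
    const double* b = P + 3 * j;
    const double* c = P + 3 * ((j + 1) % m);
    double* Gb = G + 3 * j;
    double* Gc = G + 3 * ((j + 1) % m);
    double u[3] = {b[0] - g[0], b[1] - g[1], b[2] - g[2]};
    double v[3] = {c[0] - g[0], c[1] - g[1], c[2] - g[2]};
    double n[3];
    cross3(u, v, n);
    double nn = std::sqrt(dot3(n, n) + eps2);
    {
      double nh[3] = {n[0] / nn, n[1] / nn, n[2] / nn};
      double bc[3] = {b[0] - c[0], b[1] - c[1], b[2] - c[2]};
      double cg[3] = {c[0] - g[0], c[1] - g[1], c[2] - g[2]};
      double gb[3] = {g[0] - b[0], g[1] - b[1], g[2] - b[2]};
      double t[3];
      cross3(bc, nh, t);
      for (int d = 0; d < 3; ++d) gsum[d] += 0.5 * w_area * t[d];
      cross3(cg, nh, t);
      for (int d = 0; d < 3; ++d) Gb[d] += 0.5 * w_area * t[d];
      cross3(gb, nh, t);
      for (int d = 0; d < 3; ++d) Gc[d] += 0.5 * w_area * t[d];
    }
    double t[3];
    cross3(b, c, t);
    for (int d = 0; d < 3; ++d) gsum[d] += w_vol / 6.0 * t[d];
    double cxg[3];
    cross3(c, g, cxg);
    for (int d = 0; d < 3; ++d) Gb[d] += w_vol / 6.0 * cxg[d];
    double gxb[3];
    cross3(g, b, gxb);
    for (int d = 0; d < 3; ++d) Gc[d] += w_vol / 6.0 * gxb[d];
  }
  for (int j = 0; j < m; ++j)
    for (int d = 0; d < 3; ++d) G[3 * j + d] += gsum[d] / m;
}

// load a cell's apical/basal corner positions (with periodic x offsets)
static int load_cell(const double* px, const double* py, const double* pz,
                     const int* cptr, const int* av, const int* bv,
                     const double* xoff, int c,
                     double* A, double* B, int* ia, int* ib) {
  const int s = cptr[c], e = cptr[c + 1];
  const int m = e - s;
  for (int k = 0; k < m; ++k) {
    const int va = av[s + k], vb = bv[s + k];
    ia[k] = va;
    ib[k] = vb;
    A[3 * k + 0] = px[va] + xoff[s + k];
    A[3 * k + 1] = py[va];
    A[3 * k + 2] = pz[va];
    B[3 * k + 0] = px[vb] + xoff[s + k];
    B[3 * k + 1] = py[vb];
    B[3 * k + 2] = pz[vb];
  }
  return m;
}

// per-cell apical area, basal area, lateral area, apical perimeter, volume
static void measures3d_raw(const double* px, const double* py,
                           const double* pz, const int* cptr, const int* av,
                           const int* bv, const double* xoff, int nc,
                           double* out5, double eps2) {
  double A[3 * MAXM], B[3 * MAXM], F[3 * MAXM], Q[12];
  int ia[MAXM], ib[MAXM];
  for (int c = 0; c < nc; ++c) {
    const int m = load_cell(px, py, pz, cptr, av, bv, xoff, c, A, B, ia, ib);
    double a, v6, Aa, Ab, Al = 0.0, V6 = 0.0, pa = 0.0;
    face_measures(A, m, &Aa, &v6, eps2);
    V6 += v6;
    for (int k = 0; k < m; ++k)
      for (int d = 0; d < 3; ++d) F[3 * k + d] = B[3 * (m - 1 - k) + d];
    face_measures(F, m, &Ab, &v6, eps2);
    V6 += v6;
    for (int k = 0; k < m; ++k) {
      const int kn = (k + 1) % m;
      for (int d = 0; d < 3; ++d) {
        Q[0 + d] = A[3 * k + d];
        Q[3 + d] = B[3 * k + d];
        Q[6 + d] = B[3 * kn + d];
        Q[9 + d] = A[3 * kn + d];
      }
      face_measures(Q, 4, &a, &v6, eps2);
      Al += a;
      V6 += v6;
      const double dx = A[3 * kn + 0] - A[3 * k + 0];
      const double dy = A[3 * kn + 1] - A[3 * k + 1];
      const double dz = A[3 * kn + 2] - A[3 * k + 2];
      pa += std::sqrt(dx * dx + dy * dy + dz * dz + eps2);
    }
    out5[5 * c + 0] = Aa;
    out5[5 * c + 1] = Ab;
    out5[5 * c + 2] = Al;
    out5[5 * c + 3] = pa;
    out5[5 * c + 4] = V6 / 6.0;
  }
}

double energy3d_raw(const double* px, const double* py,
                           const double* pz, const int* cptr, const int* av,
                           const int* bv, const double* xoff, int nc,
                           const double* p0, double alpha, double beta,
                           double kp, double kV, double* scratch5) {
  measures3d_raw(px, py, pz, cptr, av, bv, xoff, nc, scratch5, NFVM_EPS2);
  double e = 0.0;
  for (int c = 0; c < nc; ++c) {
    const double dp = scratch5[5 * c + 3] - p0[c];
    const double dv = scratch5[5 * c + 4] - 1.0;
    e += alpha * scratch5[5 * c + 0] + beta * scratch5[5 * c + 1] +
         0.5 * scratch5[5 * c + 2] + kp * dp * dp + kV * dv * dv;
  }
  return e;
}

// gradient accumulated into gx/gy/gz (caller zeroes); needs per-cell
// measures in scratch5 (recomputed here)
double grad3d_raw(const double* px, const double* py, const double* pz,
                       const int* cptr, const int* av, const int* bv,
                       const double* xoff, int nc, const double* p0,
                       double alpha, double beta, double kp, double kV,
                       double* scratch5, double* gx, double* gy,
                       double* gz) {
  measures3d_raw(px, py, pz, cptr, av, bv, xoff, nc, scratch5, NFVM_EPS2);
  double etot = 0.0;
  for (int c = 0; c < nc; ++c) {
    const double dp = scratch5[5 * c + 3] - p0[c];
    const double dv = scratch5[5 * c + 4] - 1.0;
    etot += alpha * scratch5[5 * c + 0] + beta * scratch5[5 * c + 1] +
            0.5 * scratch5[5 * c + 2] + kp * dp * dp + kV * dv * dv;
  }
  double A[3 * MAXM], B[3 * MAXM], F[3 * MAXM], G[3 * MAXM], Q[12], GQ[12];
  int ia[MAXM], ib[MAXM];
  for (int c = 0; c < nc; ++c) {
    const int m = load_cell(px, py, pz, cptr, av, bv, xoff, c, A, B, ia, ib);
    const double cv = 2.0 * kV * (scratch5[5 * c + 4] - 1.0);
    const double cp = 2.0 * kp * (scratch5[5 * c + 3] - p0[c]);
    // apical face
    std::fill(G, G + 3 * m, 0.0);
    face_grad(A, m, alpha, cv, G, NFVM_EPS2);
    for (int k = 0; k < m; ++k) {
      gx[ia[k]] += G[3 * k + 0];
      gy[ia[k]] += G[3 * k + 1];
      gz[ia[k]] += G[3 * k + 2];
    }
    // basal face (reversed loop for outward -z orientation)
    for (int k = 0; k < m; ++k)
      for (int d = 0; d < 3; ++d) F[3 * k + d] = B[3 * (m - 1 - k) + d];
    std::fill(G, G + 3 * m, 0.0);
    face_grad(F, m, beta, cv, G, NFVM_EPS2);
    for (int k = 0; k < m; ++k) {
      const int i = ib[m - 1 - k];
      gx[i] += G[3 * k + 0];
      gy[i] += G[3 * k + 1];
      gz[i] += G[3 * k + 2];
    }
    // lateral quads (area weight 1/2) and apical perimeter edges
    for (int k = 0; k < m; ++k) {
      const int kn = (k + 1) % m;
      for (int d = 0; d < 3; ++d) {
        Q[0 + d] = A[3 * k + d];
        Q[3 + d] = B[3 * k + d];
        Q[6 + d] = B[3 * kn + d];
        Q[9 + d] = A[3 * kn + d];
      }
      std::fill(GQ, GQ + 12, 0.0);
      face_grad(Q, 4, 0.5, cv, GQ, NFVM_EPS2);
      gx[ia[k]] += GQ[0];
      gy[ia[k]] += GQ[1];
      gz[ia[k]] += GQ[2];
      gx[ib[k]] += GQ[3];
      gy[ib[k]] += GQ[4];
      gz[ib[k]] += GQ[5];
      gx[ib[kn]] += GQ[6];
      gy[ib[kn]] += GQ[7];
      gz[ib[kn]] += GQ[8];
      gx[ia[kn]] += GQ[9];
      gy[ia[kn]] += GQ[10];
      gz[ia[kn]] += GQ[11];
      double dx = A[3 * kn + 0] - A[3 * k + 0];
      double dy = A[3 * kn + 1] - A[3 * k + 1];
      double dz = A[3 * kn + 2] - A[3 * k + 2];
      double l = std::sqrt(dx * dx + dy * dy + dz * dz + NFVM_EPS2);
      gx[ia[k]] -= cp * dx / l;
      gy[ia[k]] -= cp * dy / l;
      gz[ia[k]] -= cp * dz / l;
      gx[ia[kn]] += cp * dx / l;
      gy[ia[kn]] += cp * dy / l;
      gz[ia[kn]] += cp * dz / l;
    }
  }
  return etot;
}

struct Tissue3DView {
  int nv, nc;
  std::vector<double> x, y, z;
  const int *cptr, *av, *bv;
  const double *xoff, *p0;
  void load(const NumericMatrix& pos, const IntegerVector& cell_ptr,
            const IntegerVector& avert, const IntegerVector& bvert,
            const NumericVector& xo, const NumericVector& p0v) {
    nv = pos.nrow();
    nc = cell_ptr.size() - 1;
    x.resize(nv);
    y.resize(nv);
    z.resize(nv);
    for (int i = 0; i < nv; ++i) {
      x[i] = pos(i, 0);
      y[i] = pos(i, 1);
      z[i] = pos(i, 2);
    }
    cptr = cell_ptr.begin();
    av = avert.begin();
    bv = bvert.begin();
    xoff = xo.begin();
    p0 = p0v.begin();
  }
};

// [[Rcpp::export]]
NumericMatrix cell_measures3d_cpp(const NumericMatrix& pos,
                                  const IntegerVector& cell_ptr,
                                  const IntegerVector& avert,
                                  const IntegerVector& bvert,
                                  const NumericVector& xoff) {
  Tissue3DView t;
  NumericVector dummy(cell_ptr.size() - 1);
  t.load(pos, cell_ptr, avert, bvert, xoff, dummy);
  std::vector<double> m(5 * t.nc);
  measures3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr, t.av, t.bv,
                 t.xoff, t.nc, m.data(), 0.0);
  NumericMatrix out(t.nc, 5);
  for (int c = 0; c < t.nc; ++c)
    for (int j = 0; j < 5; ++j) out(c, j) = m[5 * c + j];
  return out;
}

// [[Rcpp::export]]
double energy3d_cpp(const NumericMatrix& pos,
                    const IntegerVector& cell_ptr,
                    const IntegerVector& avert,
                    const IntegerVector& bvert,
                    const NumericVector& xoff,
                    const NumericVector& p0,
                    const double alpha, const double beta,
                    const double kp, const double kV) {
  Tissue3DView t;
  t.load(pos, cell_ptr, avert, bvert, xoff, p0);
  std::vector<double> s5(5 * t.nc);
  return energy3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr, t.av,
                      t.bv, t.xoff, t.nc, t.p0, alpha, beta, kp, kV,
                      s5.data());
}

// [[Rcpp::export]]
NumericMatrix grad3d_cpp(const NumericMatrix& pos,
                         const IntegerVector& cell_ptr,
                         const IntegerVector& avert,
                         const IntegerVector& bvert,
                         const NumericVector& xoff,
                         const NumericVector& p0,
                         const double alpha, const double beta,
                         const double kp, const double kV) {
  Tissue3DView t;
  t.load(pos, cell_ptr, avert, bvert, xoff, p0);
  std::vector<double> s5(5 * t.nc), gx(t.nv, 0.0), gy(t.nv, 0.0),
      gz(t.nv, 0.0);
  grad3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr, t.av, t.bv, t.xoff,
             t.nc, t.p0, alpha, beta, kp, kV, s5.data(), gx.data(),
             gy.data(), gz.data());
  NumericMatrix g(t.nv, 3);
  for (int i = 0; i < t.nv; ++i) {
    g(i, 0) = gx[i];
    g(i, 1) = gy[i];
    g(i, 2) = gz[i];
  }
  return g;
}

// [[Rcpp::export]]
List euler3d_cpp(const NumericMatrix& pos,
                 const IntegerVector& cell_ptr,
                 const IntegerVector& avert,
                 const IntegerVector& bvert,
                 const NumericVector& xoff,
                 const NumericVector& p0,
                 const double alpha, const double beta,
                 const double kp, const double kV,
                 const LogicalVector& freev,
                 const double dt,
                 const int nsteps,
                 const int check_every,
                 const double tol_rise) {
  Tissue3DView t;
  t.load(pos, cell_ptr, avert, bvert, xoff, p0);
  std::vector<double> s5(5 * t.nc), gx(t.nv), gy(t.nv), gz(t.nv);
  std::vector<int> freeidx;
  for (int i = 0; i < t.nv; ++i)
    if (freev[i]) freeidx.push_back(i);
  const int nrec = nsteps / check_every + 1;
  NumericVector e_trace(nrec), f_trace(nrec), t_trace(nrec);
  int rec = 0;
  bool unstable = false;
  double e_prev = energy3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr,
                               t.av, t.bv, t.xoff, t.nc, t.p0, alpha, beta,
                               kp, kV, s5.data());
  std::fill(gx.begin(), gx.end(), 0.0);
  std::fill(gy.begin(), gy.end(), 0.0);
  std::fill(gz.begin(), gz.end(), 0.0);
  grad3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr, t.av, t.bv, t.xoff,
             t.nc, t.p0, alpha, beta, kp, kV, s5.data(), gx.data(),
             gy.data(), gz.data());
  double mf = 0.0;
  for (int i : freeidx) {
    double f = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i]);
    if (f > mf) mf = f;
  }
  e_trace[rec] = e_prev;
  f_trace[rec] = mf;
  t_trace[rec] = 0.0;
  ++rec;
  for (int step = 1; step <= nsteps; ++step) {
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    grad3d_raw(t.x.data(), t.y.data(), t.z.data(), t.cptr, t.av, t.bv,
               t.xoff, t.nc, t.p0, alpha, beta, kp, kV, s5.data(), gx.data(),
               gy.data(), gz.data());
    for (int i : freeidx) {
      t.x[i] -= dt * gx[i];
      t.y[i] -= dt * gy[i];
      t.z[i] -= dt * gz[i];
    }
    if (step % check_every == 0 && rec < nrec) {
      const double e_now = energy3d_raw(t.x.data(), t.y.data(), t.z.data(),
                                        t.cptr, t.av, t.bv, t.xoff, t.nc,
                                        t.p0, alpha, beta, kp, kV,
                                        s5.data());
      if (e_now > e_prev + tol_rise * check_every) unstable = true;
      e_prev = e_now;
      mf = 0.0;
      for (int i : freeidx) {
        double f = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i] + gz[i] * gz[i]);
        if (f > mf) mf = f;
      }
      e_trace[rec] = e_now;
      f_trace[rec] = mf;
      t_trace[rec] = step * dt;
      ++rec;
    }
  }
  NumericMatrix cur(t.nv, 3);
  for (int i = 0; i < t.nv; ++i) {
    cur(i, 0) = t.x[i];
    cur(i, 1) = t.y[i];
    cur(i, 2) = t.z[i];
  }
  return List::create(_["pos"] = cur,
                      _["energy"] = e_trace[Range(0, rec - 1)],
                      _["max_force"] = f_trace[Range(0, rec - 1)],
                      _["time"] = t_trace[Range(0, rec - 1)],
                      _["unstable"] = unstable);
}
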