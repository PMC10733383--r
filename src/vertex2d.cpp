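#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "nfvm_kernels.h"
using namespace Rcpp;

// Cells are CCW vertex loops stored flat: cvert[cell_ptr[c] .. cell_ptr[c+1]-1]
// (0-based vertex indices). Energy per cell: (a-1)^2 + kp*(p - p0_c)^2.
// Inner kernels work on raw buffers so the Euler loop allocates nothing.

static void measures2d_raw(const double* x, const double* y,
                           const int* cptr, const int* cv, int nc,
                           double* area, double* perim) {
  for (int c = 0; c < nc; ++c) {
    const int s = cptr[c], e = cptr[c + 1];
    double a = 0.0, p = 0.0;
    for (int k = s; k < e; ++k) {
      const int i = cv[k];
      const int j = cv[(k + 1 < e) ? k + 1 : s];
      a += x[i] * y[j] - x[j] * y[i];
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      p += std::sqrt(dx * dx + dy * dy);
    }
    area[c] = 0.5 * a;
    perim[c] = p;
  }
}

// C1 smoothing of edge lengths: |e| -> sqrt(|e|^2 + EPS2). Constricting
// cells collapse edges to zero length (vertex mergers; T1s are disallowed),
// where the raw perimeter is non-smooth; the regularization (EPS = 1e-4
// cell lengths, far below any physical scale) turns those kinks into smooth
// stationary points so quasi-Newton descent can converge in force.
#define EPS2 1e-8

double energy2d_raw(const double* x, const double* y,
                           const int* cptr, const int* cv, int nc,
                           const double* p0, double kp) {
  double e = 0.0;
  for (int c = 0; c < nc; ++c) {
    const int s = cptr[c], en = cptr[c + 1];
    double a = 0.0, p = 0.0;
    for (int k = s; k < en; ++k) {
      const int i = cv[k];
      const int j = cv[(k + 1 < en) ? k + 1 : s];
      a += x[i] * y[j] - x[j] * y[i];
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      p += std::sqrt(dx * dx + dy * dy + EPS2);
    }
    a *= 0.5;
    const double dp = p - p0[c];
    e += (a - 1.0) * (a - 1.0) + kp * dp * dp;
  }
  return e;
}

// gradient accumulated into gx/gy (caller zeroes them); returns the energy
double grad2d_raw(const double* x, const double* y,
                       const int* cptr, const int* cv, int nc,
                       const double* p0, double kp,
                       double* gx, double* gy) {
  double etot = 0.0;
  for (int c = 0; c < nc; ++c) {
    const int s = cptr[c], en = cptr[c + 1];
    const int m = en - s;
    double a = 0.0, p = 0.0;
    for (int k = s; k < en; ++k) {
      const int i = cv[k];
      const int j = cv[(k + 1 < en) ? k + 1 : s];
      a += x[i] * y[j] - x[j] * y[i];
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      p += std::sqrt(dx * dx + dy * dy + EPS2);
    }
    a *= 0.5;
    const double dpp = p - p0[c];
    etot += (a - 1.0) * (a - 1.0) + kp * dpp * dpp;
    const double ca = 2.0 * (a - 1.0);
    const double cp = 2.0 * kp * dpp;
    for (int k = 0; k < m; ++k) {
      const int i = cv[s + k];
      const int ip = cv[s + ((k - 1 + m) % m)];
      const int in = cv[s + ((k + 1) % m)];
      // area term: da/dxi = (y_next - y_prev)/2, da/dyi = (x_prev - x_next)/2
      gx[i] += ca * 0.5 * (y[in] - y[ip]);
      gy[i] += ca * 0.5 * (x[ip] - x[in]);
      // perimeter term: unit vectors of the two incident edges, pointing at i
      double dxp = x[i] - x[ip], dyp = y[i] - y[ip];
      double lp = std::sqrt(dxp * dxp + dyp * dyp + EPS2);
      double dxn = x[i] - x[in], dyn = y[i] - y[in];
      double ln = std::sqrt(dxn * dxn + dyn * dyn + EPS2);
      gx[i] += cp * (dxp / lp + dxn / ln);
      gy[i] += cp * (dyp / lp + dyn / ln);
    }
  }
  return etot;
}

// [[Rcpp::export]]
NumericMatrix cell_measures2d_cpp(const NumericMatrix& pos,
                                  const IntegerVector& cell_ptr,
                                  const IntegerVector& cvert) {
  const int nc = cell_ptr.size() - 1;
  const int nv = pos.nrow();
  std::vector<double> x(nv), y(nv);
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  NumericMatrix out(nc, 2);
  std::vector<double> a(nc), p(nc);
  measures2d_raw(x.data(), y.data(), cell_ptr.begin(), cvert.begin(), nc,
                 a.data(), p.data());
  for (int c = 0; c < nc; ++c) {
    out(c, 0) = a[c];
    out(c, 1) = p[c];
  }
  return out;
}

// [[Rcpp::export]]
double energy2d_cpp(const NumericMatrix& pos,
                    const IntegerVector& cell_ptr,
                    const IntegerVector& cvert,
                    const NumericVector& p0,
                    const double kp) {
  const int nv = pos.nrow();
  std::vector<double> x(nv), y(nv);
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  return energy2d_raw(x.data(), y.data(), cell_ptr.begin(), cvert.begin(),
                      cell_ptr.size() - 1, p0.begin(), kp);
}

// [[Rcpp::export]]
NumericMatrix grad2d_cpp(const NumericMatrix& pos,
                         const IntegerVector& cell_ptr,
                         const IntegerVector& cvert,
                         const NumericVector& p0,
                         const double kp) {
  const int nv = pos.nrow();
  std::vector<double> x(nv), y(nv), gx(nv, 0.0), gy(nv, 0.0);
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
  }
  grad2d_raw(x.data(), y.data(), cell_ptr.begin(), cvert.begin(),
             cell_ptr.size() - 1, p0.begin(), kp, gx.data(), gy.data());
  NumericMatrix g(nv, 2);
  for (int i = 0; i < nv; ++i) {
    g(i, 0) = gx[i];
    g(i, 1) = gy[i];
  }
  return g;
}

// Explicit Euler overdamped dynamics r <- r + dt * (-grad e) on free
// vertices. Energy is monitored every check_every steps; a rise larger than
// tol_rise * check_every flags instability (reported, not thrown).
// [[Rcpp::export]]
List euler2d_cpp(const NumericMatrix& pos,
                 const IntegerVector& cell_ptr,
                 const IntegerVector& cvert,
                 const NumericVector& p0,
                 const double kp,
                 const LogicalVector& freev,
                 const double dt,
                 const int nsteps,
                 const int check_every,
                 const double tol_rise) {
  const int nv = pos.nrow();
  const int nc = cell_ptr.size() - 1;
  const int* cptr = cell_ptr.begin();
  const int* cv = cvert.begin();
  const double* p0p = p0.begin();
  std::vector<double> x(nv), y(nv), gx(nv), gy(nv);
  std::vector<int> freeidx;
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    if (freev[i]) freeidx.push_back(i);
  }
  const int nrec = nsteps / check_every + 1;
  NumericVector e_trace(nrec), f_trace(nrec), t_trace(nrec);
  int rec = 0;
  bool unstable = false;
  double e_prev = energy2d_raw(x.data(), y.data(), cptr, cv, nc, p0p, kp);
  std::fill(gx.begin(), gx.end(), 0.0);
  std::fill(gy.begin(), gy.end(), 0.0);
  grad2d_raw(x.data(), y.data(), cptr, cv, nc, p0p, kp, gx.data(), gy.data());
  double mf = 0.0;
  for (int i : freeidx) {
    double f = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i]);
    if (f > mf) mf = f;
  }
  e_trace[rec] = e_prev;
  f_trace[rec] = mf;
  t_trace[rec] = 0.0;
  ++rec;
  for (int step = 1; step <= nsteps; ++step) {
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    grad2d_raw(x.data(), y.data(), cptr, cv, nc, p0p, kp, gx.data(),
               gy.data());
    for (int i : freeidx) {
      x[i] -= dt * gx[i];
      y[i] -= dt * gy[i];
    }
    if (step % check_every == 0 && rec < nrec) {
      const double e_now = energy2d_raw(x.data(), y.data(), cptr, cv, nc,
                                        p0p, kp);
      if (e_now > e_prev + tol_rise * check_every) unstable = true;
      e_prev = e_now;
      mf = 0.0;
      for (int i : freeidx) {
        double f = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i]);
        if (f > mf) mf = f;
      }
      e_trace[rec] = e_now;
      f_trace[rec] = mf;
      t_trace[rec] = step * dt;
      ++rec;
    }
  }
  NumericMatrix cur(nv, 2);
  for (int i = 0; i < nv; ++i) {
    cur(i, 0) = x[i];
    cur(i, 1) = y[i];
  }
  return List::create(_["pos"] = cur,
                      _["energy"] = e_trace[Range(0, rec - 1)],
                      _["max_force"] = f_trace[Range(0, rec - 1)],
                      _["time"] = t_trace[Range(0, rec - 1)],
                      _["unstable"] = unstable);
}
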