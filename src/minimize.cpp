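#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
#include "nfvm_kernels.h"
using namespace Rcpp;

// Limited-memory BFGS (two-loop recursion, Armijo backtracking) over the
// free coordinates of a tissue. Convergence: per-vertex max force below
// force_tol, or energy stationarity at a non-smooth point (collapsed
// zero-length edges of constricting cells), reported as at_kink.

struct LbfgsResult {
  double energy;
  double max_force;
  int iterations;
  bool converged;
  bool at_kink;
};

// FIRE (fast inertial relaxation engine) burst: damped dynamics with
// adaptive time step, used to carry slow collective modes past the kink
// facets where line searches along -g stall. Returns the final energy.
static double fire_burst(std::vector<double>& x, std::vector<double>& g,
                         std::function<double(const double*, double*)>
                             eval_fg,
                         int nsteps, double dt0, double dtmax) {
  const int n = x.size();
  std::vector<double> v(n, 0.0);
  double dt = dt0, alpha = 0.1;
  const double alpha0 = 0.1, finc = 1.1, fdec = 0.5, falpha = 0.99;
  int npos = 0;
  double f = eval_fg(x.data(), g.data());
  for (int s = 0; s < nsteps; ++s) {
    double P = 0.0, vn2 = 0.0, fn2 = 0.0;
    for (int i = 0; i < n; ++i) {
      P += -g[i] * v[i];
      vn2 += v[i] * v[i];
      fn2 += g[i] * g[i];
    }
    if (P > 0) {
      const double mix = alpha * std::sqrt(vn2 / std::max(fn2, 1e-300));
      for (int i = 0; i < n; ++i) {
        v[i] = (1 - alpha) * v[i] - mix * g[i];
      }
      if (++npos > 5) {
        dt = std::min(dt * finc, dtmax);
        alpha *= falpha;
      }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= fdec;
      alpha = alpha0;
      npos = 0;
    }
    for (int i = 0; i < n; ++i) {
      v[i] -= dt * g[i];
      x[i] += dt * v[i];
    }
    f = eval_fg(x.data(), g.data());
  }
  return f;
}

// eval_f(x) -> energy; eval_fg(x, g) -> energy with full gradient in g.
// freec: indices of free coordinates; dim: coords per vertex for the
// max-force norm.
static LbfgsResult lbfgs_core(std::vector<double>& x,
                              const std::vector<int>& freec, int dim, int nv,
                              const std::vector<char>& vfree,
                              std::function<double(const double*)> eval_f,
                              std::function<double(const double*, double*)>
                                  eval_fg,
                              double force_tol, int maxit,
                              double fire_dt0, double fire_dtmax) {
  const int n = x.size();
  const int m = 8;  // history size
  std::vector<std::vector<double> > S(m, std::vector<double>(n, 0.0)),
      Y(m, std::vector<double>(n, 0.0));
  std::vector<double> rho(m, 0.0), alpha_buf(m, 0.0);
  std::vector<double> g(n, 0.0), gprev(n), xprev(n), d(n), xtrial(n);
  int hist = 0, head = 0;
  double f = eval_fg(x.data(), g.data());
  LbfgsResult res = {f, 0.0, 0, false, false};
  int stall = 0;
  int fire_left = 80;
  // on a kink stall, try a FIRE burst; returns true if it made progress
  auto try_fire = [&]() {
    if (fire_left <= 0) return false;
    --fire_left;
    const double fbefore = f;
    f = fire_burst(x, g, eval_fg, 1500, fire_dt0, fire_dtmax);
    hist = 0;
    stall = 0;
    return fbefore - f > 1e-12 * std::max(1.0, std::fabs(f));
  };
  for (int it = 0; it < maxit; ++it) {
    // max per-vertex force over free vertices
    double mf = 0.0;
    for (int v = 0; v < nv; ++v) {
      if (!vfree[v]) continue;
      double s2 = 0.0;
      for (int dd = 0; dd < dim; ++dd) {
        const double gi = g[dd * nv + v];
        s2 += gi * gi;
      }
      if (s2 > mf) mf = s2;
    }
    mf = std::sqrt(mf);
    res.max_force = mf;
    res.iterations = it;
    res.energy = f;
    if (mf < force_tol) {
      res.converged = true;
      return res;
    }
    // two-loop recursion on the free subspace (frozen coords have zero
    // gradient and zero history, so they never move)
    for (int i = 0; i < n; ++i) d[i] = -g[i];
    int idx = head;
    for (int h = 0; h < hist; ++h) {
      idx = (idx - 1 + m) % m;
      double sd = 0.0;
      for (int i = 0; i < n; ++i) sd += S[idx][i] * d[i];
      alpha_buf[idx] = rho[idx] * sd;
      for (int i = 0; i < n; ++i) d[i] -= alpha_buf[idx] * Y[idx][i];
    }
    if (hist > 0) {
      int last = (head - 1 + m) % m;
      double yy = 0.0, sy = 0.0;
      for (int i = 0; i < n; ++i) {
        yy += Y[last][i] * Y[last][i];
        sy += S[last][i] * Y[last][i];
      }
      const double gamma = (yy > 0) ? sy / yy : 1.0;
      for (int i = 0; i < n; ++i) d[i] *= gamma;
    }
    idx = (head - hist % m + m) % m;  // oldest entry
    for (int h = 0; h < hist; ++h) {
      double yd = 0.0;
      for (int i = 0; i < n; ++i) yd += Y[idx][i] * d[i];
      const double bcoef = rho[idx] * yd;
      for (int i = 0; i < n; ++i) {
        d[i] += (alpha_buf[idx] - bcoef) * S[idx][i];
      }
      idx = (idx + 1) % m;
    }
    // ensure descent
    double gd = 0.0;
    for (int i = 0; i < n; ++i) gd += g[i] * d[i];
    if (!(gd < 0)) {
      for (int i = 0; i < n; ++i) d[i] = -g[i];
      gd = 0.0;
      for (int i = 0; i < n; ++i) gd += g[i] * d[i];
      hist = 0;
    }
    // Armijo backtracking
    double t = 1.0;
    const double c1 = 1e-4;
    double fnew = f;
    bool ok = false;
    for (int ls = 0; ls < 50; ++ls) {
      for (int i = 0; i < n; ++i) xtrial[i] = x[i] + t * d[i];
      fnew = eval_f(xtrial.data());
      if (std::isfinite(fnew) && fnew <= f + c1 * t * gd) {
        ok = true;
        break;
      }
      t *= 0.5;
    }
    if (!ok) {
      if (hist > 0) {  // retry from steepest descent before giving up
        hist = 0;
        continue;
      }
      // overdamped nudges along -g to hop off a kink facet (zero-length
      // edges make the energy piecewise smooth; small explicit steps can
      // still descend where the line search on -g cannot)
      double gn = 0.0;
      for (int i = 0; i < n; ++i) gn += g[i] * g[i];
      gn = std::sqrt(gn);
      bool moved = false;
      for (double tau : {1e-2, 1e-3, 1e-4, 1e-5}) {
        const double step = tau / std::max(1.0, gn);
        for (int i = 0; i < n; ++i) xtrial[i] = x[i] - step * g[i];
        fnew = eval_f(xtrial.data());
        if (std::isfinite(fnew) && fnew < f) {
          std::copy(xtrial.begin(), xtrial.end(), x.begin());
          f = eval_fg(x.data(), g.data());
          moved = true;
          break;
        }
      }
      if (moved) continue;
      if (try_fire()) continue;
      res.energy = f;
      res.converged = true;  // no descent direction left: kink minimum
      res.at_kink = true;
      return res;
    }
    std::copy(x.begin(), x.end(), xprev.begin());
    std::copy(g.begin(), g.end(), gprev.begin());
    std::copy(xtrial.begin(), xtrial.end(), x.begin());
    const double fold = f;
    f = eval_fg(x.data(), g.data());
    // update history
    double sy = 0.0;
    for (int i = 0; i < n; ++i) {
      S[head][i] = x[i] - xprev[i];
      Y[head][i] = g[i] - gprev[i];
      sy += S[head][i] * Y[head][i];
    }
    if (sy > 1e-12) {
      rho[head] = 1.0 / sy;
      head = (head + 1) % m;
      if (hist < m) ++hist;
    }
    // energy stationarity at a non-smooth minimum
    if (fold - f < 1e-13 * std::max(1.0, std::fabs(f))) {
      if (++stall >= 50) {
        if (try_fire()) continue;
        res.energy = f;
        res.converged = true;
        res.at_kink = true;
        return res;
      }
    } else {
      stall = 0;
    }
  }
  res.energy = f;
  return res;  // not converged
}

// [[Rcpp::export]]
List lbfgs2d_cpp(const NumericMatrix& pos,
                 const IntegerVector& cell_ptr,
                 const IntegerVector& cvert,
                 const NumericVector& p0,
                 const double kp,
                 const LogicalVector& freev,
                 const double force_tol,
                 const int maxit) {
  const int nv = pos.nrow();
  const int nc = cell_ptr.size() - 1;
  const int* cptr = cell_ptr.begin();
  const int* cv = cvert.begin();
  const double* p0p = p0.begin();
  std::vector<double> x(2 * nv);
  std::vector<char> vfree(nv);
  std::vector<int> freec;
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    x[nv + i] = pos(i, 1);
    vfree[i] = freev[i] ? 1 : 0;
    if (freev[i]) {
      freec.push_back(i);
      freec.push_back(nv + i);
    }
  }
  auto eval_f = [&](const double* p) {
    return energy2d_raw(p, p + nv, cptr, cv, nc, p0p, kp);
  };
  auto eval_fg = [&](const double* p, double* g) {
    std::fill(g, g + 2 * nv, 0.0);
    double e = grad2d_raw(p, p + nv, cptr, cv, nc, p0p, kp, g, g + nv);
    for (int i = 0; i < nv; ++i) {
      if (!vfree[i]) {
        g[i] = 0.0;
        g[nv + i] = 0.0;
      }
    }
    return e;
  };
  LbfgsResult r = lbfgs_core(x, freec, 2, nv, vfree, eval_f, eval_fg,
                             force_tol, maxit, 1e-3, 5e-2);
  NumericMatrix out(nv, 2);
  for (int i = 0; i < nv; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = x[nv + i];
  }
  return List::create(_["pos"] = out, _["energy"] = r.energy,
                      _["max_force"] = r.max_force,
                      _["iterations"] = r.iterations,
                      _["converged"] = r.converged,
                      _["at_kink"] = r.at_kink);
}

// [[Rcpp::export]]
List lbfgs3d_cpp(const NumericMatrix& pos,
                 const IntegerVector& cell_ptr,
                 const IntegerVector& avert,
                 const IntegerVector& bvert,
                 const NumericVector& xoff,
                 const NumericVector& p0,
                 const double alpha, const double beta,
                 const double kp, const double kV,
                 const LogicalVector& freev,
                 const double force_tol,
                 const int maxit) {
  const int nv = pos.nrow();
  const int nc = cell_ptr.size() - 1;
  const int* cptr = cell_ptr.begin();
  const int* av = avert.begin();
  const int* bv = bvert.begin();
  const double* xo = xoff.begin();
  const double* p0p = p0.begin();
  std::vector<double> x(3 * nv), s5(5 * nc);
  std::vector<char> vfree(nv);
  std::vector<int> freec;
  for (int i = 0; i < nv; ++i) {
    x[i] = pos(i, 0);
    x[nv + i] = pos(i, 1);
    x[2 * nv + i] = pos(i, 2);
    vfree[i] = freev[i] ? 1 : 0;
    if (freev[i]) {
      freec.push_back(i);
      freec.push_back(nv + i);
      freec.push_back(2 * nv + i);
    }
  }
  auto eval_f = [&](const double* p) {
    return energy3d_raw(p, p + nv, p + 2 * nv, cptr, av, bv, xo, nc, p0p,
                        alpha, beta, kp, kV, s5.data());
  };
  auto eval_fg = [&](const double* p, double* g) {
    std::fill(g, g + 3 * nv, 0.0);
    double e = grad3d_raw(p, p + nv, p + 2 * nv, cptr, av, bv, xo, nc, p0p,
                          alpha, beta, kp, kV, s5.data(), g, g + nv,
                          g + 2 * nv);
    for (int i = 0; i < nv; ++i) {
      if (!vfree[i]) {
        g[i] = 0.0;
        g[nv + i] = 0.0;
        g[2 * nv + i] = 0.0;
      }
    }
    return e;
  };
  LbfgsResult r = lbfgs_core(x, freec, 3, nv, vfree, eval_f, eval_fg,
                             force_tol, maxit, 1e-4, 2e-3);
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = x[nv + i];
    out(i, 2) = x[2 * nv + i];
  }
  return List::create(_["pos"] = out, _["energy"] = r.energy,
                      _["max_force"] = r.max_force,
                      _["iterations"] = r.iterations,
                      _["converged"] = r.converged,
                      _["at_kink"] = r.at_kink);
}
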