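// Fast engine for the static equilibrium sweep: the residual of the planar
// ligament/contact model, a small Levenberg-Marquardt least-squares solver
// with finite-difference Jacobian, and the warm-started continuation sweep
// over a moment schedule. Mirrors the reference R implementation built on
// minpack.lm; the two engines are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct ModelCache {
  double mx[6], my[6], fx[6], fy[6], a[6], b[6], L0[6];
  double cmx, cmy, cfx, cfy, clearance, K;
  int internal_mode;  // 1 = conforming internal pair
};

static const double MOMENT_SCALE = 10.0;  // mm, divides the moment residual

// residual r = (Fx [N], Fy [N], Mz [N mm] / MOMENT_SCALE); returns false on
// singular ligament geometry.
static bool eval_residual(const ModelCache& mc, const double* par,
                          double m_ext_nmm, double* r) {
  const double ct = std::cos(par[2]), st = std::sin(par[2]);
  double sfx = 0.0, sfy = 0.0, smz = 0.0;
  for (int i = 0; i < 6; ++i) {
    const double gx = ct * mc.mx[i] - st * mc.my[i] + par[0];
    const double gy = st * mc.mx[i] + ct * mc.my[i] + par[1];
    const double dx = mc.fx[i] - gx, dy = mc.fy[i] - gy;
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-9) return false;
    const double strain = (len - mc.L0[i]) / mc.L0[i];
    if (strain > 0.0) {
      const double f = mc.a[i] * (std::exp(mc.b[i] * strain) - 1.0);
      const double ffx = f * dx / len, ffy = f * dy / len;
      sfx += ffx;
      sfy += ffy;
      smz += (gx - par[0]) * ffy - (gy - par[1]) * ffx;
    }
  }
  const double cx = ct * mc.cmx - st * mc.cmy + par[0];
  const double cy = st * mc.cmx + ct * mc.cmy + par[1];
  const double ddx = cx - mc.cfx, ddy = cy - mc.cfy;
  const double d = std::sqrt(ddx * ddx + ddy * ddy);
  const double depth = mc.internal_mode ? d - mc.clearance : -d;
  if (depth > 0.0 && d > 1e-12) {
    const double fc = mc.K * depth * std::sqrt(depth);
    const double fcx = -fc * ddx / d, fcy = -fc * ddy / d;
    sfx += fcx;
    sfy += fcy;
    smz += (cx - par[0]) * fcy - (cy - par[1]) * fcx;
  }
  r[0] = sfx;
  r[1] = sfy;
  r[2] = (smz + m_ext_nmm) / MOMENT_SCALE;
  return true;
}

static double abs_sum(const double* r) {
  return std::fabs(r[0]) + std::fabs(r[1]) + std::fabs(r[2]);
}

// Solve the symmetric 3x3 system M x = rhs by Gaussian elimination with
// partial pivoting; returns false if numerically singular.
static bool solve3(double M[3][3], const double* rhs, double* x) {
  double A[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) A[i][j] = M[i][j];
    A[i][3] = rhs[i];
  }
  for (int c = 0; c < 3; ++c) {
    int p = c;
    for (int i = c + 1; i < 3; ++i)
      if (std::fabs(A[i][c]) > std::fabs(A[p][c])) p = i;
    if (std::fabs(A[p][c]) < 1e-300) return false;
    if (p != c)
      for (int j = c; j < 4; ++j) std::swap(A[p][j], A[c][j]);
    for (int i = c + 1; i < 3; ++i) {
      const double f = A[i][c] / A[c][c];
      for (int j = c; j < 4; ++j) A[i][j] -= f * A[c][j];
    }
  }
  for (int i = 2; i >= 0; --i) {
    double s = A[i][3];
    for (int j = i + 1; j < 3; ++j) s -= A[i][j] * x[j];
    x[i] = s / A[i][i];
  }
  return true;
}

// Levenberg-Marquardt on the 3-unknown residual; forward-difference
// Jacobian. Stops when the absolute residual sum passes `tol`, the step
// stalls, or the iteration budget is exhausted.
static bool lm_solve(const ModelCache& mc, double m_ext_nmm, double* par,
                     double tol, int maxiter) {
  double r[3];
  if (!eval_residual(mc, par, m_ext_nmm, r)) return false;
  double rs = abs_sum(r);
  if (rs < tol) return true;
  double lambda = 1e-3;
  for (int iter = 0; iter < maxiter; ++iter) {
    // finite-difference Jacobian
    double J[3][3];
    for (int j = 0; j < 3; ++j) {
      const double h = 1.5e-8 * std::max(1.0, std::fabs(par[j]));
      double pj[3] = {par[0], par[1], par[2]};
      pj[j] += h;
      double rj[3];
      if (!eval_residual(mc, pj, m_ext_nmm, rj)) return false;
      for (int i = 0; i < 3; ++i) J[i][j] = (rj[i] - r[i]) / h;
    }
    double A[3][3], g[3];
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) {
        A[i][j] = 0.0;
        for (int k = 0; k < 3; ++k) A[i][j] += J[k][i] * J[k][j];
      }
      g[i] = 0.0;
      for (int k = 0; k < 3; ++k) g[i] += J[k][i] * r[k];
      g[i] = -g[i];
    }
    const double dmax = std::max({A[0][0], A[1][1], A[2][2], 1e-30});
    bool accepted = false;
    for (int inner = 0; inner < 40; ++inner) {
      double Ad[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) Ad[i][j] = A[i][j];
      for (int i = 0; i < 3; ++i)
        Ad[i][i] += lambda * std::max(A[i][i], 1e-12 * dmax);
      double step[3];
      if (!solve3(Ad, g, step)) {
        lambda *= 10.0;
        continue;
      }
      // Trust region on the pose increment: the joint is 2*pi-periodic in
      // theta and the residual is flat wherever every cable is slack, so an
      // undamped Gauss-Newton step can tunnel to an equilibrium several
      // revolutions away. Clamping keeps the solve on the local
      // quasi-static branch reached by warm-started continuation.
      double scale = 1.0;
      if (std::fabs(step[2]) > 0.35) scale = 0.35 / std::fabs(step[2]);
      if (std::fabs(step[0]) * scale > 2.0)
        scale = 2.0 / std::fabs(step[0]);
      if (std::fabs(step[1]) * scale > 2.0)
        scale = 2.0 / std::fabs(step[1]);
      for (int i = 0; i < 3; ++i) step[i] *= scale;
      double trial[3] = {par[0] + step[0], par[1] + step[1], par[2] + step[2]};
      double rt[3];
      if (!eval_residual(mc, trial, m_ext_nmm, rt)) {
        lambda *= 10.0;
        continue;
      }
      const double ss_old = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
      const double ss_new = rt[0] * rt[0] + rt[1] * rt[1] + rt[2] * rt[2];
      if (ss_new < ss_old) {
        for (int i = 0; i < 3; ++i) {
          par[i] = trial[i];
          r[i] = rt[i];
        }
        rs = abs_sum(r);
        lambda = std::max(lambda / 3.0, 1e-12);
        accepted = true;
        const double stepn = std::sqrt(step[0] * step[0] + step[1] * step[1] +
                                       step[2] * step[2]);
        const double parn = std::sqrt(par[0] * par[0] + par[1] * par[1] +
                                      par[2] * par[2]);
        if (rs < tol || stepn < 1e-14 * (1.0 + parn)) return rs < tol;
        break;
      }
      lambda *= 3.0;
      if (lambda > 1e15) return rs < tol;
    }
    if (!accepted) return rs < tol;
  }
  return rs < tol;
}

// Attempt schedule matching the reference engine: warm start, restart from
// the final iterate, then rotational nudges along the unbalanced torque to
// cross slack free-play arcs. `par` holds the best pose found on exit.
static bool solve_attempts(const ModelCache& mc, double m_ext_nmm, double* par,
                           double tol, int maxiter) {
  double best[3] = {par[0], par[1], par[2]};
  double r[3];
  if (!eval_residual(mc, best, m_ext_nmm, r)) return false;
  double best_rs = abs_sum(r);
  if (best_rs < tol) return true;

  double cur[3] = {best[0], best[1], best[2]};
  for (int phase = 0; phase < 5; ++phase) {
    if (phase >= 2) {
      // nudge the best iterate across a possible flat arc
      static const double dth[3] = {0.035, 0.09, 0.18};
      double rb[3];
      if (!eval_residual(mc, best, m_ext_nmm, rb)) return false;
      const double s = (rb[2] > 0.0) ? 1.0 : (rb[2] < 0.0 ? -1.0 : 0.0);
      cur[0] = best[0];
      cur[1] = best[1];
      cur[2] = best[2] + s * dth[phase - 2];
    }
    if (lm_solve(mc, m_ext_nmm, cur, tol, maxiter)) {
      for (int i = 0; i < 3; ++i) par[i] = cur[i];
      return true;
    }
    double rc[3];
    if (eval_residual(mc, cur, m_ext_nmm, rc)) {
      const double rs = abs_sum(rc);
      if (rs < best_rs) {
        best_rs = rs;
        for (int i = 0; i < 3; ++i) best[i] = cur[i];
      }
    }
    // phase 1 restarts from the phase-0 iterate; later phases nudge
    if (phase == 0)
      for (int i = 0; i < 3; ++i) cur[i] = best[i];
  }
  for (int i = 0; i < 3; ++i) par[i] = best[i];
  return false;
}

// Load-increment bisection continuation, depth-limited.
static bool continuation(const ModelCache& mc, double m_from, double m_to,
                         double* par, double tol, int maxiter, int depth) {
  double trial[3] = {par[0], par[1], par[2]};
  if (solve_attempts(mc, m_to * 1000.0, trial, tol, maxiter)) {
    for (int i = 0; i < 3; ++i) par[i] = trial[i];
    return true;
  }
  if (depth <= 0) {
    for (int i = 0; i < 3; ++i) par[i] = trial[i];
    return false;
  }
  const double mid = 0.5 * (m_from + m_to);
  double sub[3] = {par[0], par[1], par[2]};
  continuation(mc, m_from, mid, sub, tol, maxiter, depth - 1);
  const bool ok = continuation(mc, mid, m_to, sub, tol, maxiter, depth - 1);
  for (int i = 0; i < 3; ++i) par[i] = sub[i];
  return ok;
}

static ModelCache build_cache(const List& cache) {
  ModelCache mc;
  NumericVector mx = cache["mx"], my = cache["my"], fx = cache["fx"],
                fy = cache["fy"], a = cache["a"], b = cache["b"],
                L0 = cache["L0"];
  for (int i = 0; i < 6; ++i) {
    mc.mx[i] = mx[i]; mc.my[i] = my[i];
    mc.fx[i] = fx[i]; mc.fy[i] = fy[i];
    mc.a[i] = a[i]; mc.b[i] = b[i]; mc.L0[i] = L0[i];
  }
  NumericVector cm = cache["center_moving"], cf = cache["center_fixed"];
  mc.cmx = cm[0]; mc.cmy = cm[1];
  mc.cfx = cf[0]; mc.cfy = cf[1];
  mc.clearance = as<double>(cache["clearance"]);
  mc.K = as<double>(cache["K"]);
  mc.internal_mode = as<int>(cache["internal_mode"]);
  return mc;
}

// [[Rcpp::export(name = ".cpp_residual")]]
NumericVector cpp_residual(List cache, NumericVector par, double m_ext_nmm) {
  ModelCache mc = build_cache(cache);
  double p[3] = {par[0], par[1], par[2]};
  double r[3];
  if (!eval_residual(mc, p, m_ext_nmm, r))
    stop("singular geometry: coincident ligament attachment points");
  return NumericVector::create(r[0], r[1], r[2]);
}

// [[Rcpp::export(name = ".cpp_solve")]]
List cpp_solve(List cache, double m_ext, NumericVector par0, double tol,
               int maxiter) {
  ModelCache mc = build_cache(cache);
  double par[3] = {par0[0], par0[1], par0[2]};
  const bool ok = solve_attempts(mc, m_ext * 1000.0, par, tol, maxiter);
  double r[3];
  const bool valid = eval_residual(mc, par, m_ext * 1000.0, r);
  return List::create(
      _["par"] = NumericVector::create(par[0], par[1], par[2]),
      _["residual"] = valid ? NumericVector::create(r[0], r[1], r[2])
                            : NumericVector::create(NA_REAL, NA_REAL, NA_REAL),
      _["converged"] = ok && valid);
}

// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(List cache, NumericVector moments_sorted, int zero_index,
               double tol, int maxiter, NumericVector ref_pose) {
  ModelCache mc = build_cache(cache);
  const int n = moments_sorted.size();
  const int i0 = zero_index - 1;  // 1-based from R
  NumericVector tx(n), ty(n), th(n);
  LogicalVector conv(n);
  NumericMatrix forces(n, 7);

  double par[3] = {ref_pose[0], ref_pose[1], ref_pose[2]};
  conv[i0] = solve_attempts(mc, 0.0, par, tol, maxiter);
  tx[i0] = par[0]; ty[i0] = par[1]; th[i0] = par[2];

  double up[3] = {par[0], par[1], par[2]};
  double m_prev = 0.0;
  for (int i = i0 + 1; i < n; ++i) {
    conv[i] = continuation(mc, m_prev, moments_sorted[i], up, tol, maxiter, 5);
    tx[i] = up[0]; ty[i] = up[1]; th[i] = up[2];
    m_prev = moments_sorted[i];
  }
  double dn[3] = {par[0], par[1], par[2]};
  m_prev = 0.0;
  for (int i = i0 - 1; i >= 0; --i) {
    conv[i] = continuation(mc, m_prev, moments_sorted[i], dn, tol, maxiter, 5);
    tx[i] = dn[0]; ty[i] = dn[1]; th[i] = dn[2];
    m_prev = moments_sorted[i];
  }

  for (int i = 0; i < n; ++i) {
    const double ct = std::cos(th[i]), st = std::sin(th[i]);
    for (int j = 0; j < 6; ++j) {
      const double gx = ct * mc.mx[j] - st * mc.my[j] + tx[i];
      const double gy = st * mc.mx[j] + ct * mc.my[j] + ty[i];
      const double dx = mc.fx[j] - gx, dy = mc.fy[j] - gy;
      const double len = std::sqrt(dx * dx + dy * dy);
      const double strain = (len - mc.L0[j]) / mc.L0[j];
      forces(i, j) =
          strain > 0.0 ? mc.a[j] * (std::exp(mc.b[j] * strain) - 1.0) : 0.0;
    }
    const double cx = ct * mc.cmx - st * mc.cmy + tx[i];
    const double cy = st * mc.cmx + ct * mc.cmy + ty[i];
    const double d = std::sqrt((cx - mc.cfx) * (cx - mc.cfx) +
                               (cy - mc.cfy) * (cy - mc.cfy));
    const double depth = mc.internal_mode ? d - mc.clearance : -d;
    forces(i, 6) = depth > 0.0 ? mc.K * depth * std::sqrt(depth) : 0.0;
  }
  return List::create(_["tx"] = tx, _["ty"] = ty, _["theta"] = th,
                      _["converged"] = conv, _["forces"] = forces);
}
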