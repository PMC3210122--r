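// Method-of-steps RK4 integrator for the delayed neural-mass network.
//
// State per node: u_i (mean firing-rate deviation) and v_i = du_i/dt.
// The single constant delay acts on u only.  The step size must divide the
// delay exactly so that derivative discontinuities emitted by the initial
// history always land on grid points; delayed values needed at half-steps are
// taken from a cubic Hermite interpolant of an already completed step, which
// keeps the observed order at 4 between breaking points.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  double gamma, tau;
  std::vector<double> a, b, p2, p3;
  // coupling matrices (row-major n*n); may be empty when uncoupled
  std::vector<double> eu, ev;
  bool coupled;
};

// RHS: du = v
//      dv = -2 g v - g^2 (1-a) u + g^2 [ b ulag + p2 u^2 + p3 u^3 ]
//           + g^2 sum_j eu_ij (u_j - u_i) + g sum_j ev_ij (v_j - v_i)
// (the delay sits in the linear feedback path only; the firing-rate
// nonlinearity is local and instantaneous)
inline void rhs(const Model& m, const double* u, const double* v,
                const double* ulag, double* du, double* dv) {
  const double g = m.gamma, g2 = g * g;
  for (int i = 0; i < m.n; ++i) {
    const double ul = ulag[i], ui = u[i];
    du[i] = v[i];
    dv[i] = -2.0 * g * v[i] - g2 * (1.0 - m.a[i]) * ui
            + g2 * (m.b[i] * ul + m.p2[i] * ui * ui + m.p3[i] * ui * ui * ui);
  }
  if (m.coupled) {
    for (int i = 0; i < m.n; ++i) {
      double cu = 0.0, cv = 0.0;
      const double* eui = &m.eu[(size_t)i * m.n];
      const double* evi = &m.ev[(size_t)i * m.n];
      for (int j = 0; j < m.n; ++j) {
        cu += eui[j] * (u[j] - u[i]);
        cv += evi[j] * (v[j] - v[i]);
      }
      dv[i] += g2 * cu + g * cv;
    }
  }
}

// cubic Hermite value at fraction s in [0,1] of an interval of width h
inline double hermite(double y0, double y1, double d0, double d1,
                      double h, double s) {
  const double s2 = s * s, s3 = s2 * s;
  return (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * h * d0 +
         (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * h * d1;
}

} // namespace

// [[Rcpp::export(name = ".dde_steps")]]
List dde_steps(NumericMatrix hist_u, NumericMatrix hist_v,
               double gamma, double tau,
               NumericVector a, NumericVector b,
               NumericVector p2, NumericVector p3,
               Nullable<NumericMatrix> eps_u, Nullable<NumericMatrix> eps_v,
               int m, int nsteps, double guard) {
  const int n = hist_u.ncol();
  if (hist_u.nrow() != m + 1 || hist_v.nrow() != m + 1)
    stop("history must have m + 1 rows");

  Model mod;
  mod.n = n; mod.gamma = gamma; mod.tau = tau;
  mod.a.assign(a.begin(), a.end());
  mod.b.assign(b.begin(), b.end());
  mod.p2.assign(p2.begin(), p2.end());
  mod.p3.assign(p3.begin(), p3.end());
  mod.coupled = eps_u.isNotNull() || eps_v.isNotNull();
  if (mod.coupled) {
    mod.eu.assign((size_t)n * n, 0.0);
    mod.ev.assign((size_t)n * n, 0.0);
    if (eps_u.isNotNull()) {
      NumericMatrix E(eps_u);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) mod.eu[(size_t)i * n + j] = E(i, j);
    }
    if (eps_v.isNotNull()) {
      NumericMatrix E(eps_v);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) mod.ev[(size_t)i * n + j] = E(i, j);
    }
  }

  const double dt = tau / m;
  const int nrow = m + 1 + nsteps; // history rows + new rows
  NumericMatrix U(nrow, n), V(nrow, n);
  for (int r = 0; r <= m; ++r)
    for (int j = 0; j < n; ++j) { U(r, j) = hist_u(r, j); V(r, j) = hist_v(r, j); }

  std::vector<double> u0(n), v0(n), ut(n), vt(n), ul(n),
      k1u(n), k1v(n), k2u(n), k2v(n), k3u(n), k3v(n), k4u(n), k4v(n);

  int blow_step = -1;
  for (int s = 0; s < nsteps; ++s) {
    const int r = m + s;       // current row (time t)
    const int rl = r - m;      // row holding u(t - tau)
    for (int j = 0; j < n; ++j) { u0[j] = U(r, j); v0[j] = V(r, j); }

    // stage 1: lag at t - tau (grid point)
    for (int j = 0; j < n; ++j) ul[j] = U(rl, j);
    rhs(mod, u0.data(), v0.data(), ul.data(), k1u.data(), k1v.data());

    // stages 2, 3: lag at t + dt/2 - tau (midpoint of past step rl..rl+1)
    for (int j = 0; j < n; ++j)
      ul[j] = hermite(U(rl, j), U(rl + 1, j), V(rl, j), V(rl + 1, j), dt, 0.5);
    for (int j = 0; j < n; ++j) { ut[j] = u0[j] + 0.5 * dt * k1u[j]; vt[j] = v0[j] + 0.5 * dt * k1v[j]; }
    rhs(mod, ut.data(), vt.data(), ul.data(), k2u.data(), k2v.data());
    for (int j = 0; j < n; ++j) { ut[j] = u0[j] + 0.5 * dt * k2u[j]; vt[j] = v0[j] + 0.5 * dt * k2v[j]; }
    rhs(mod, ut.data(), vt.data(), ul.data(), k3u.data(), k3v.data());

    // stage 4: lag at t + dt - tau (grid point rl + 1)
    for (int j = 0; j < n; ++j) ul[j] = U(rl + 1, j);
    for (int j = 0; j < n; ++j) { ut[j] = u0[j] + dt * k3u[j]; vt[j] = v0[j] + dt * k3v[j]; }
    rhs(mod, ut.data(), vt.data(), ul.data(), k4u.data(), k4v.data());

    bool blown = false;
    for (int j = 0; j < n; ++j) {
      const double un = u0[j] + dt / 6.0 * (k1u[j] + 2 * k2u[j] + 2 * k3u[j] + k4u[j]);
      const double vn = v0[j] + dt / 6.0 * (k1v[j] + 2 * k2v[j] + 2 * k3v[j] + k4v[j]);
      if (!std::isfinite(un) || std::fabs(un) > guard) blown = true;
      U(r + 1, j) = un; V(r + 1, j) = vn;
    }
    if (blown) { blow_step = s + 1; break; }
  }

  return List::create(_["u"] = U, _["v"] = V, _["blow_step"] = blow_step);
}

// Same scheme for a scalar first-order linear DDE u'(t) = c0 u(t) + c1 u(t-tau).
// Used by the test fixtures: its exact solution is piecewise polynomial in
// each delay interval and can be built symbolically, which makes it the
// reference problem for convergence-order checks of the stepping scheme.
// [[Rcpp::export(name = ".dde_scalar_steps")]]
List dde_scalar_steps(NumericVector hist_u, NumericVector hist_du,
                      double c0, double c1, double tau,
                      int m, int nsteps) {
  if (hist_u.size() != m + 1 || hist_du.size() != m + 1)
    stop("history must have m + 1 values");
  const double dt = tau / m;
  const int nrow = m + 1 + nsteps;
  NumericVector U(nrow), dU(nrow);
  for (int r = 0; r <= m; ++r) { U[r] = hist_u[r]; dU[r] = hist_du[r]; }
  // the derivative is one-sided at the history/solution junction: the
  // initial function's slope holds to the left of t = 0, the equation's
  // right-derivative to the right; lag interpolation picks the side
  // matching its interval
  const double d_right0 = c0 * U[m] + c1 * U[0];
  for (int s = 0; s < nsteps; ++s) {
    const int r = m + s, rl = r - m;
    const double u0 = U[r];
    const double d0 = (rl == m) ? d_right0 : dU[rl];
    const double lag_mid = hermite(U[rl], U[rl + 1], d0, dU[rl + 1], dt, 0.5);
    const double k1 = c0 * u0 + c1 * U[rl];
    const double k2 = c0 * (u0 + 0.5 * dt * k1) + c1 * lag_mid;
    const double k3 = c0 * (u0 + 0.5 * dt * k2) + c1 * lag_mid;
    const double k4 = c0 * (u0 + dt * k3) + c1 * U[rl + 1];
    U[r + 1] = u0 + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    dU[r + 1] = c0 * U[r + 1] + c1 * U[rl + 1];
  }
  return List::create(_["u"] = U, _["du"] = dU);
}
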