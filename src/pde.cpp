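#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double cell_force_p(double k, double a, double n, double l) {
  double d = a - l;
  if (n == 1.0) return k * d;
  if (n == 3.0) return k * (d * (d * d));
  double s = (d > 0.0) ? 1.0 : ((d < 0.0) ? -1.0 : 0.0);
  return k * s * std::pow(std::fabs(d), n);
}

// D(q) = -F'(1/q) / (eta q^2) with F'(l) = -n k |a-l|^(n-1)
static inline double diffusivity_c(double k, double a, double n, double eta, double q) {
  if (n == 1.0) return k / (eta * (q * q));
  double d = a - 1.0 / q;
  if (n == 3.0) return 3.0 * k * (d * d) / (eta * (q * q));
  return n * k * std::pow(std::fabs(d), n - 1.0) / (eta * q * q);
}

static inline double division_rate_p(int family, double beta, double a_ref,
                                     double shape, double l) {
  switch (family) {
  case 0: return 0.0;
  case 1: return beta;
  case 2: return beta * l / a_ref;
  case 3: {
    double lh = std::pow(l, shape);
    return beta * lh / (std::pow(a_ref, shape) + lh);
  }
  }
  return 0.0;
}

// d/dX on the uniform grid: central in the interior, second-order one-sided
// at both ends.
static void grid_deriv(const std::vector<double>& f, double h, std::vector<double>& out) {
  int M = (int)f.size();
  out.resize(M);
  out[0] = (-3.0 * f[0] + 4.0 * f[1] - f[2]) / (2.0 * h);
  for (int j = 1; j < M - 1; ++j) out[j] = (f[j + 1] - f[j - 1]) / (2.0 * h);
  out[M - 1] = (3.0 * f[M - 1] - 4.0 * f[M - 2] + f[M - 3]) / (2.0 * h);
}

// Thomas algorithm for a tridiagonal system (sub a, diag b, super c).
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& r,
                   std::vector<double>& x) {
  int M = (int)b.size();
  for (int j = 1; j < M; ++j) {
    double w = a[j] / b[j - 1];
    b[j] -= w * c[j - 1];
    r[j] -= w * r[j - 1];
  }
  x.resize(M);
  x[M - 1] = r[M - 1] / b[M - 1];
  for (int j = M - 2; j >= 0; --j) x[j] = (r[j] - c[j] * x[j + 1]) / b[j];
}

// Backward-Euler step(s) of the coupled (Gamma, q) Lagrangian free-boundary
// system with Picard iteration on the lagged nonlinear coefficients
// D(q), E(q), G(1/q) and Gamma_X.
//
// The density is eliminated through the material mass identity
// q Gamma_X = m (m are the per-node mass densities, carried across steps and
// grown pointwise by the proliferation source), which turns the map equation
// into a nonlinear diffusion problem
//   Gamma_T = (C / Gamma_X^2) Gamma_XX - C m_X / (m Gamma_X),  C = D + E,
// solved implicitly: each Picard sweep assembles a linear tridiagonal system
// for Gamma with the stiff Gamma_XX term implicit and the coefficients
// lagged, and recovers q = m / Gamma_X pointwise, iterating until the
// density iterate moves less than picard_tol in max norm. The nonlinear
// free-boundary condition closes the system at X = L(0): it is solved
// (Newton-linearised through d/dq [F(1/q)/eta] = D(q), other coefficients
// lagged) for the boundary density, which is imposed as a one-sided Neumann
// closure Gamma_X = m / q_bc; in legacy mode the prior-work Dirichlet value
// q_bc = 1/a is used instead. Mass is conserved (or grown by the source)
// exactly by construction.
// [[Rcpp::export]]
List pde_run_cpp(NumericVector q_init, NumericVector gamma_init,
                 NumericVector mass_init, double t_init, double h,
                 double k, double a, double n, double eta,
                 int family, double beta, double a_ref, double shape,
                 Nullable<Function> custom_rate,
                 double dt, int n_steps, int record_every,
                 double picard_tol, int picard_max, bool legacy_bc,
                 bool store_snapshots, bool trace = false) {
  const int M = q_init.size();
  if (M < 5) stop("the spatial grid needs at least 5 points");
  const double h2 = h * h;
  const bool proliferating = (family != 0);
  Function rate_fn = proliferating && family == 4 && custom_rate.isNotNull()
    ? Function(custom_rate) : Function("identity");

  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> G(gamma_init.begin(), gamma_init.end());
  std::vector<double> m(mass_init.begin(), mass_init.end());

  std::vector<double> qs, Gs, Gn, GXs, GXn, D(M), grate(M), Ecoef(M), C(M),
      mr(M), mrX(M), ta(M), tb(M), tc(M), tr(M), qn(M);

  std::vector<double> rec_t, rec_L, rec_N, rec_res;
  std::vector<int> rec_it;
  List snapshots;

  auto rates_at = [&](const std::vector<double>& qq) {
    if (!proliferating) { std::fill(grate.begin(), grate.end(), 0.0); return; }
    if (family == 4) {
      NumericVector len(M);
      for (int j = 0; j < M; ++j) len[j] = 1.0 / qq[j];
      NumericVector r = rate_fn(len);
      if ((int)r.size() != M) stop("custom proliferation rate must return one rate per grid point");
      for (int j = 0; j < M; ++j) {
        if (r[j] < 0 || !std::isfinite(r[j])) stop("custom proliferation rate must be finite and non-negative");
        grate[j] = r[j];
      }
    } else {
      for (int j = 0; j < M; ++j)
        grate[j] = division_rate_p(family, beta, a_ref, shape, 1.0 / qq[j]);
    }
  };

  // E(q) = I / (2 q^2) with I the cumulative trapezoidal integral of
  // q G(1/q) Gamma_X = m G(1/q) along the grid (growth integral, Lagrangian
  // form); `mm` are the mass densities of the current step.
  auto growth_E = [&](const std::vector<double>& qq, const std::vector<double>& mm) {
    double I = 0.0, fprev = mm[0] * grate[0];
    Ecoef[0] = 0.0;
    for (int j = 1; j < M; ++j) {
      double fj = mm[j] * grate[j];
      I += 0.5 * h * (fprev + fj);
      Ecoef[j] = I / (2.0 * qq[j] * qq[j]);
      fprev = fj;
    }
  };

  // residual of the free-boundary condition in map variables, with the same
  // one-sided stencils the solver enforces (q = m/Gamma_X throughout)
  auto boundary_residual = [&](const std::vector<double>& qq) {
    int e = M - 1;
    if (legacy_bc) return qq[e] - 1.0 / a;
    double GXe = (3.0 * G[e] - 4.0 * G[e - 1] + G[e - 2]) / (2.0 * h);
    double GXXe = (2.0 * G[e] - 5.0 * G[e - 1] + 4.0 * G[e - 2] - G[e - 3]) / h2;
    double mXe = (3.0 * m[e] - 4.0 * m[e - 1] + m[e - 2]) / (2.0 * h);
    return cell_force_p(k, a, n, GXe / m[e]) / eta +
      (D[e] / 2.0 + Ecoef[e]) * (mXe / (m[e] * GXe) - GXXe / (GXe * GXe));
  };

  auto record = [&](double t, int iters) {
    grid_deriv(G, h, GXn);
    rates_at(q);
    for (int j = 0; j < M; ++j) D[j] = diffusivity_c(k, a, n, eta, q[j]);
    growth_E(q, m);
    double tot = 0.0;
    for (int j = 0; j < M - 1; ++j)
      tot += 0.5 * h * (q[j] * GXn[j] + q[j + 1] * GXn[j + 1]);
    rec_t.push_back(t);
    rec_L.push_back(G[M - 1]);
    rec_N.push_back(tot);
    rec_res.push_back(boundary_residual(q));
    rec_it.push_back(iters);
    if (store_snapshots)
      snapshots.push_back(List::create(_["Gamma"] = NumericVector(G.begin(), G.end()),
                                       _["q"] = NumericVector(q.begin(), q.end())));
  };
  record(t_init, 0);

  for (int step = 1; step <= n_steps; ++step) {
    qs = q; Gs = G;
    bool converged = false;
    int it = 0;
    double delta = NA_REAL, delta_prev = R_PosInf, omega = 1.0;
    for (it = 1; it <= picard_max; ++it) {
      grid_deriv(Gs, h, GXs);
      for (int j = 0; j < M; ++j)
        if (GXs[j] <= 0.0)
          stop("mesh collapse: Gamma_X <= 0 at grid index %d, t = %g", j + 1,
               t_init + step * dt);
      rates_at(qs);
      for (int j = 0; j < M; ++j) {
        D[j] = diffusivity_c(k, a, n, eta, qs[j]);
        double f = 1.0 - dt * grate[j];
        if (f <= 0.0)
          stop("dt * G(1/q) >= 1 at t = %g: time step too large for this proliferation rate",
               t_init + step * dt);
        mr[j] = m[j] / f;
      }
      growth_E(qs, mr);
      for (int j = 0; j < M; ++j) C[j] = D[j] + Ecoef[j];
      grid_deriv(mr, h, mrX);

      // implicit map equation: Gamma/dt - (C/Gamma_X^2) Gamma_XX =
      //   Gamma_old/dt - C m_X / (m Gamma_X)   (first-derivative term lagged)
      ta[0] = 0.0; tb[0] = 1.0; tc[0] = 0.0; tr[0] = 0.0;  // pinned boundary
      for (int j = 1; j < M - 1; ++j) {
        double cj = C[j] / (GXs[j] * GXs[j]);
        ta[j] = -cj / h2;
        tb[j] = 1.0 / dt + 2.0 * cj / h2;
        tc[j] = -cj / h2;
        tr[j] = G[j] / dt - C[j] * mrX[j] / (mr[j] * GXs[j]);
      }

      // Free-boundary closure at X = L(0), written entirely in map
      // variables through q = m/Gamma_X (so every derivative estimate is a
      // uniformly second-order one-sided Gamma stencil):
      //   F(Gamma_X/m)/eta + (D/2 + E) [m_X/(m Gamma_X) - Gamma_XX/Gamma_X^2] = 0
      // linearised in Gamma via d/dGamma_X [F(Gamma_X/m)/eta] = -D q^2 / m
      // with D, E and the 1/Gamma_X factors lagged. In legacy mode the
      // Dirichlet value q = 1/a gives the Neumann closure Gamma_X = a m.
      {
        int e = M - 1;
        double GXse = (3.0 * Gs[e] - 4.0 * Gs[e - 1] + Gs[e - 2]) / (2.0 * h);
        double De = D[e], Ee = Ecoef[e];
        double A = -De * qs[e] * qs[e] / mr[e];
        double B = -(De / 2.0 + Ee) / (GXse * GXse);
        double cM3, cM2, cM1, cM0, rhs;
        bool ok = false;
        if (legacy_bc) {
          cM3 = 0.0;
          cM2 = 1.0 / (2.0 * h);
          cM1 = -4.0 / (2.0 * h);
          cM0 = 3.0 / (2.0 * h);
          rhs = a * mr[e];
          ok = true;
        } else if (std::fabs(A) + std::fabs(B) >= 1e-13) {
          double GXXse = (2.0 * Gs[e] - 5.0 * Gs[e - 1] + 4.0 * Gs[e - 2] - Gs[e - 3]) / h2;
          double mrXe = (3.0 * mr[e] - 4.0 * mr[e - 1] + mr[e - 2]) / (2.0 * h);
          double T1 = (De / 2.0 + Ee) * mrXe / (mr[e] * GXse);
          double F0 = cell_force_p(k, a, n, GXse / mr[e]) / eta;
          cM3 = -B / h2;
          cM2 = A / (2.0 * h) + 4.0 * B / h2;
          cM1 = -4.0 * A / (2.0 * h) - 5.0 * B / h2;
          cM0 = 3.0 * A / (2.0 * h) + 2.0 * B / h2;
          rhs = A * GXse - F0 - T1;
          ok = true;
        }
        if (!ok) {
          // fully degenerate law at its rest state (D = E = 0): the
          // boundary is static; freeze the one-sided Jacobian at the
          // current density
          cM3 = 0.0;
          cM2 = 1.0 / (2.0 * h);
          cM1 = -4.0 / (2.0 * h);
          cM0 = 3.0 / (2.0 * h);
          rhs = mr[e] / qs[e];
        }
        // reduce the 4-point row against rows M-2 and M-1 so the system
        // stays tridiagonal; when those rows are (nearly) diagonal their
        // sub-entries vanish and the reduction uses the diagonal directly
        if (cM3 != 0.0) {
          if (std::fabs(ta[e - 2]) * h2 * dt >= 1e-12) {
            double f3 = cM3 / ta[e - 2];
            cM2 -= f3 * tb[e - 2];
            cM1 -= f3 * tc[e - 2];
            rhs -= f3 * tr[e - 2];
          } else {
            // row M-3 is (nearly) diagonal: Gamma_{M-3} = tr[e-3]/tb[e-3]
            rhs -= cM3 * tr[e - 3] / tb[e - 3];
          }
        }
        if (cM2 != 0.0) {
          if (std::fabs(ta[e - 1]) * h2 * dt >= 1e-12) {
            double f2 = cM2 / ta[e - 1];
            cM1 -= f2 * tb[e - 1];
            cM0 -= f2 * tc[e - 1];
            rhs -= f2 * tr[e - 1];
          } else {
            // row M-2 is diagonal: Gamma_{M-2} = tr[e-2]/tb[e-2]
            rhs -= cM2 * tr[e - 2] / tb[e - 2];
          }
        }
        ta[e] = cM1; tb[e] = cM0; tc[e] = 0.0; tr[e] = rhs;
      }
      thomas(ta, tb, tc, tr, Gn);
      for (int j = 0; j < M - 1; ++j)
        if (!(Gn[j] < Gn[j + 1]))
          stop("mesh collapse: Gamma not increasing at grid index %d, t = %g",
               j + 1, t_init + step * dt);
      grid_deriv(Gn, h, GXn);
      for (int j = 0; j < M; ++j)
        if (GXn[j] <= 0.0)
          stop("mesh collapse: Gamma_X <= 0 at grid index %d, t = %g", j + 1,
               t_init + step * dt);

      // recover the density from the mass identity
      delta = 0.0;
      for (int j = 0; j < M; ++j) {
        qn[j] = mr[j] / GXn[j];
        if (!(qn[j] > 0.0) || !std::isfinite(qn[j]))
          stop("density became non-positive at grid index %d, t = %g", j + 1,
               t_init + step * dt);
        double d = std::fabs(qn[j] - qs[j]);
        if (d > delta) delta = d;
      }
      Gs = Gn;
      if (delta <= picard_tol) { qs = qn; converged = true; break; }
      double ratio = delta / delta_prev;
      if (trace && step <= 2)
        Rprintf("step %d sweep %d delta %.3e ratio %.3f omega %.3f qM %.6f L %.6f\n",
                step, it, delta, ratio, omega, qs[M - 1], Gn[M - 1]);
      // damp the rare weakly oscillatory sweep
      if (ratio > 1.0) omega = std::max(0.2, omega * 0.5);
      else if (ratio < 0.5) omega = std::min(1.0, omega * 1.25);
      delta_prev = delta;
      if (omega == 1.0) {
        qs = qn;
      } else {
        for (int j = 0; j < M; ++j) qs[j] += omega * (qn[j] - qs[j]);
      }
    }
    if (!converged)
      stop("Picard iteration failed to converge at t = %g (last residual %g after %d sweeps)",
           t_init + step * dt, delta, picard_max);
    q = qs; G = Gs; m = mr;  // mr from the final sweep keeps q * Gamma_X = m
    if (step % record_every == 0 || step == n_steps)
      record(t_init + step * dt, it > picard_max ? picard_max : it);
  }

  return List::create(_["times"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["L"] = NumericVector(rec_L.begin(), rec_L.end()),
                      _["N"] = NumericVector(rec_N.begin(), rec_N.end()),
                      _["boundary_residual"] = NumericVector(rec_res.begin(), rec_res.end()),
                      _["picard_iters"] = IntegerVector(rec_it.begin(), rec_it.end()),
                      _["q_final"] = NumericVector(q.begin(), q.end()),
                      _["Gamma_final"] = NumericVector(G.begin(), G.end()),
                      _["mass_final"] = NumericVector(m.begin(), m.end()),
                      _["snapshots"] = snapshots);
}
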