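#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour interaction force at cell length l: k*sign(a-l)*|a-l|^n.
// Positive when the cell is compressed (l < a), zero at rest length.
static inline double cell_force(double k, double a, double n, double l) {
  double d = a - l;
  if (n == 1.0) return k * d;
  if (n == 3.0) return k * (d * (d * d));
  double s = (d > 0.0) ? 1.0 : ((d < 0.0) ? -1.0 : 0.0);
  return k * s * std::pow(std::fabs(d), n);
}

// Per-cell division rate G(l) for the built-in families.
// 0 = none, 1 = constant, 2 = length_proportional, 3 = target_length
static inline double division_rate_c(int family, double beta, double a_ref,
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

// Forward-Euler integration of the overdamped node chain, with an optional
// constant-time-step stochastic proliferation check after each mechanics
// update (at most one division per step). Node 0 stays pinned at the origin.
//
// family == 4 uses `custom_rate`, an R function mapping cell lengths to rates.
// linear_path selects the specialised linear-law velocity stencil
// alpha*(x[i-1] - 2x[i] + x[i+1]) instead of force differences.
// [[Rcpp::export]]
List chain_run_cpp(NumericVector x_init, double t_init,
                   double k, double a, double n, double eta,
                   bool linear_path,
                   int family, double beta, double a_ref, double shape,
                   Nullable<Function> custom_rate,
                   double dt, int n_steps, int record_every,
                   bool store_snapshots) {
  std::vector<double> x(x_init.begin(), x_init.end());
  const double alpha = k / eta;
  const bool proliferating = (family != 0);
  Function rate_fn = proliferating && family == 4 && custom_rate.isNotNull()
    ? Function(custom_rate) : Function("identity");

  std::vector<double> rec_t, rec_L;
  std::vector<int> rec_N;
  List snapshots;
  std::vector<double> v, g;

  auto record = [&](double t) {
    rec_t.push_back(t);
    rec_L.push_back(x.back());
    rec_N.push_back((int)x.size() - 1);
    if (store_snapshots) snapshots.push_back(NumericVector(x.begin(), x.end()));
  };
  record(t_init);

  for (int step = 1; step <= n_steps; ++step) {
    int N = (int)x.size() - 1;
    v.assign(N + 1, 0.0);
    if (linear_path) {
      for (int i = 1; i < N; ++i)
        v[i] = alpha * (x[i - 1] - 2.0 * x[i] + x[i + 1]);
      v[N] = alpha * (x[N - 1] - x[N] + a);
    } else {
      // f[i] = F(x_i - x_{i-1}), force exerted through cell i
      std::vector<double> f(N + 1, 0.0);
      for (int i = 1; i <= N; ++i) f[i] = cell_force(k, a, n, x[i] - x[i - 1]);
      for (int i = 1; i < N; ++i) v[i] = (f[i] - f[i + 1]) / eta;
      v[N] = f[N] / eta;
    }
    for (int i = 1; i <= N; ++i) x[i] += dt * v[i];
    for (int i = 0; i < N; ++i) {
      if (!(x[i] < x[i + 1]))
        stop("node ordering violated at index %d, t = %g (time step too large for this stiffness)",
             i + 1, t_init + step * dt);
    }

    if (proliferating) {
      g.assign(N, 0.0);
      double total = 0.0;
      if (family == 4) {
        NumericVector len(N);
        for (int i = 0; i < N; ++i) len[i] = x[i + 1] - x[i];
        NumericVector r = rate_fn(len);
        if ((int)r.size() != N) stop("custom proliferation rate must return one rate per cell");
        for (int i = 0; i < N; ++i) {
          if (r[i] < 0 || !std::isfinite(r[i])) stop("custom proliferation rate must be finite and non-negative");
          g[i] = r[i];
          total += r[i];
        }
      } else {
        for (int i = 0; i < N; ++i) {
          g[i] = division_rate_c(family, beta, a_ref, shape, x[i + 1] - x[i]);
          total += g[i];
        }
      }
      if (total * dt >= 1.0)
        stop("sum of division rates times dt is %g >= 1 at t = %g: time step too large",
             total * dt, t_init + step * dt);
      if (total > 0.0) {
        double u1 = unif_rand();
        if (u1 < total * dt) {
          double u2 = unif_rand() * total, acc = 0.0;
          int cell = N - 1;
          for (int i = 0; i < N; ++i) {
            acc += g[i];
            if (u2 < acc) { cell = i; break; }
          }
          double mid = 0.5 * (x[cell] + x[cell + 1]);
          x.insert(x.begin() + cell + 1, mid);
        }
      }
    }

    if (step % record_every == 0 || step == n_steps) record(t_init + step * dt);
  }

  return List::create(_["times"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["L"] = NumericVector(rec_L.begin(), rec_L.end()),
                      _["N"] = IntegerVector(rec_N.begin(), rec_N.end()),
                      _["x_final"] = NumericVector(x.begin(), x.end()),
                      _["snapshots"] = snapshots);
}
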