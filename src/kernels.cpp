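// Trajectory engines for the stochastic simulators.  The R-level
// single-step functions are the reference kernels; these compiled
// engines reproduce their per-step algebra (same accumulation order,
// same RNG consumption) for whole trajectories.  RNG state is handled
// by the Rcpp wrapper (RNGScope), so the caller controls per-replicate
// substreams by setting .Random.seed before each call.
#include <Rcpp.h>
using namespace Rcpp;

// propensity kinds
static const int KIND_LINEAR = 0;
static const int KIND_MASSACTION = 1;

// a_j(x) for one channel; mass-action uses the combinatorial count
// x(x-1)...(x-rho+1)/rho! per reactant species, evaluated as written
// (no clamping at non-integer or negative stage values).
static inline double propensity_one(int j, const double* x, int N,
                                    const IntegerVector& kind,
                                    const NumericMatrix& coef,
                                    const NumericVector& rate,
                                    const IntegerMatrix& mult) {
  if (kind[j] == KIND_LINEAR) {
    double a = 0.0;
    for (int i = 0; i < N; ++i) a += coef(i, j) * x[i];
    return a;
  }
  double a = rate[j];
  for (int i = 0; i < N; ++i) {
    int rho = mult(i, j);
    if (rho > 0) {
      double fac = 1.0;
      for (int q = 0; q < rho; ++q) { a *= (x[i] - q); fac *= (q + 1); }
      a /= fac;
    }
  }
  return a;
}

static inline void propensities_all(const double* x, int N, int m,
                                    const IntegerVector& kind,
                                    const NumericMatrix& coef,
                                    const NumericVector& rate,
                                    const IntegerMatrix& mult,
                                    double* a) {
  for (int j = 0; j < m; ++j)
    a[j] = propensity_one(j, x, N, kind, coef, rate, mult);
}

static inline bool bad_state(const double* x, int N, double bound) {
  for (int i = 0; i < N; ++i)
    if (!R_finite(x[i]) || std::fabs(x[i]) > bound) return true;
  return false;
}

// [[Rcpp::export]]
List cpp_ssa(NumericMatrix nu, IntegerVector kind, NumericMatrix coef,
             NumericVector rate, IntegerMatrix mult, NumericVector x0,
             double t_final, double max_events) {
  int N = nu.nrow(), m = nu.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(m);
  double t = 0.0, events = 0.0;
  bool absorbed = false;
  while (true) {
    propensities_all(x.data(), N, m, kind, coef, rate, mult, a.data());
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) a0 += a[j];
    if (a0 <= 0.0) { absorbed = true; break; }
    double dt = exp_rand() / a0;
    if (t + dt > t_final) { t = t_final; break; }
    t += dt;
    double u = unif_rand() * a0;
    int k = 0;
    double acc = a[0];
    while (acc < u && k < m - 1) { ++k; acc += a[k]; }
    for (int i = 0; i < N; ++i) x[i] += nu(i, k);
    if (++events >= max_events) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["t"] = t, _["events"] = events,
                      _["absorbed"] = absorbed);
}

// [[Rcpp::export]]
List cpp_poisson_traj(NumericMatrix nu, IntegerVector kind,
                      NumericMatrix coef, NumericVector rate,
                      IntegerMatrix mult, NumericVector x0, double tau,
                      int n_steps, double div_bound) {
  int N = nu.nrow(), m = nu.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(m);
  bool failed = false;
  for (int step = 0; step < n_steps; ++step) {
    propensities_all(x.data(), N, m, kind, coef, rate, mult, a.data());
    for (int j = 0; j < m && !failed; ++j)
      if (!(tau * a[j] >= 0)) failed = true;   // negative or NaN mean
    if (failed) break;
    for (int j = 0; j < m; ++j) {
      double K = R::rpois(tau * a[j]);
      for (int i = 0; i < N; ++i) x[i] += nu(i, j) * K;
    }
    if (bad_state(x.data(), N, div_bound)) { failed = true; break; }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["failed"] = failed);
}

// One RK tau-leap step, general explicit tableau.  d_n = sum nu_j K_j -
// tau f(X_n); stages Y_i = X_n + w_i d_n + sum_{j<i} alpha_ij g_j with
// g_j = tau f(Y_j); update X + sum(nu K) + (sum beta_j g_j - g_0).  The
// grouping makes the s = 1 tableau agree bitwise with the Poisson
// kernel, and the subdiagonal path in cpp_rk_eff_traj agree bitwise
// with this one.
// [[Rcpp::export]]
List cpp_rk_traj(NumericMatrix nu, IntegerVector kind, NumericMatrix coef,
                 NumericVector rate, IntegerMatrix mult,
                 NumericMatrix A, NumericVector b, NumericVector w,
                 NumericVector x0, double tau, int n_steps,
                 double div_bound) {
  int N = nu.nrow(), m = nu.ncol(), s = b.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(m), SnuK(N), g0(N), d(N), Y(N), corr(N);
  std::vector<std::vector<double> > g(s, std::vector<double>(N));
  bool failed = false;
  for (int step = 0; step < n_steps && !failed; ++step) {
    propensities_all(x.data(), N, m, kind, coef, rate, mult, a.data());
    for (int j = 0; j < m && !failed; ++j)
      if (!(tau * a[j] >= 0)) failed = true;
    if (failed) break;
    std::fill(SnuK.begin(), SnuK.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      double K = R::rpois(tau * a[j]);
      for (int i = 0; i < N; ++i) SnuK[i] += nu(i, j) * K;
    }
    std::fill(g0.begin(), g0.end(), 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < N; ++i) g0[i] += nu(i, j) * a[j];
    for (int i = 0; i < N; ++i) g0[i] *= tau;
    for (int i = 0; i < N; ++i) d[i] = SnuK[i] - g0[i];
    for (int si = 0; si < s; ++si) {
      for (int i = 0; i < N; ++i) Y[i] = x[i] + w[si] * d[i];
      for (int sj = 0; sj < si; ++sj)
        if (A(si, sj) != 0)
          for (int i = 0; i < N; ++i) Y[i] += A(si, sj) * g[sj][i];
      if (si == 0) {
        g[0] = g0;
      } else {
        propensities_all(Y.data(), N, m, kind, coef, rate, mult, a.data());
        std::fill(g[si].begin(), g[si].end(), 0.0);
        for (int j = 0; j < m; ++j)
          for (int i = 0; i < N; ++i) g[si][i] += nu(i, j) * a[j];
        for (int i = 0; i < N; ++i) g[si][i] *= tau;
      }
    }
    std::fill(corr.begin(), corr.end(), 0.0);
    for (int sj = 0; sj < s; ++sj)
      if (b[sj] != 0)
        for (int i = 0; i < N; ++i) corr[i] += b[sj] * g[sj][i];
    for (int i = 0; i < N; ++i) x[i] = x[i] + SnuK[i] + (corr[i] - g0[i]);
    if (bad_state(x.data(), N, div_bound)) failed = true;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["failed"] = failed);
}

// Efficient subdiagonal form: Y_1 = X_n; Y_i = X_n + alpha_i d_n +
// alpha_i g_{i-1}; update as in the general kernel with b = e_s.
// alpha[i] (0-based stage i >= 1) is A(i, i-1).
// [[Rcpp::export]]
List cpp_rk_eff_traj(NumericMatrix nu, IntegerVector kind,
                     NumericMatrix coef, NumericVector rate,
                     IntegerMatrix mult, NumericVector alpha,
                     NumericVector x0, double tau, int n_steps,
                     double div_bound) {
  int N = nu.nrow(), m = nu.ncol(), s = alpha.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(m), SnuK(N), g0(N), d(N), Y(N), gprev(N), corr(N);
  bool failed = false;
  for (int step = 0; step < n_steps && !failed; ++step) {
    propensities_all(x.data(), N, m, kind, coef, rate, mult, a.data());
    for (int j = 0; j < m && !failed; ++j)
      if (!(tau * a[j] >= 0)) failed = true;
    if (failed) break;
    std::fill(SnuK.begin(), SnuK.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      double K = R::rpois(tau * a[j]);
      for (int i = 0; i < N; ++i) SnuK[i] += nu(i, j) * K;
    }
    std::fill(g0.begin(), g0.end(), 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < N; ++i) g0[i] += nu(i, j) * a[j];
    for (int i = 0; i < N; ++i) g0[i] *= tau;
    for (int i = 0; i < N; ++i) d[i] = SnuK[i] - g0[i];
    gprev = g0;                       // tau f(Y_1), Y_1 = X_n
    for (int si = 1; si < s; ++si) {
      for (int i = 0; i < N; ++i) Y[i] = x[i] + alpha[si] * d[i];
      for (int i = 0; i < N; ++i) Y[i] += alpha[si] * gprev[i];
      propensities_all(Y.data(), N, m, kind, coef, rate, mult, a.data());
      std::fill(gprev.begin(), gprev.end(), 0.0);
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < N; ++i) gprev[i] += nu(i, j) * a[j];
      for (int i = 0; i < N; ++i) gprev[i] *= tau;
    }
    std::fill(corr.begin(), corr.end(), 0.0);
    for (int i = 0; i < N; ++i) corr[i] += 1.0 * gprev[i];
    for (int i = 0; i < N; ++i) x[i] = x[i] + SnuK[i] + (corr[i] - g0[i]);
    if (bad_state(x.data(), N, div_bound)) failed = true;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["failed"] = failed);
}
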