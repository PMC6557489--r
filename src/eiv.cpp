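#include <Rcpp.h>
using namespace Rcpp;

// Robust errors-in-variables regression through the origin, y = beta * x.
// Loss: sum_i rho(d_i / S) with rho Tukey's biweight (c = c_rho) and
// d_i = (1 + beta^2)^(-1/2) (y_i - beta x_i) the orthogonal distance of
// (x_i, y_i) from the line.  S is the M-estimate of scale solving
// mean(chi(d_i / S)) = kappa with chi Tukey's biweight at c = c_chi,
// re-solved at every candidate beta (nested formulation).

static double tukey1(double t, double c) {
  double a = std::fabs(t);
  if (a >= c) return c * c / 6.0;
  double u = (t * t) / (c * c);
  return t * t / 6.0 * (3.0 - 3.0 * u + u * u);
}

// [[Rcpp::export(name = ".tukey_rho_cpp")]]
NumericVector tukey_rho_cpp(NumericVector t, double c) {
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i) out[i] = tukey1(t[i], c);
  return out;
}

// M-scale by bracketed bisection; returns 0 when the scale equation has no
// positive solution (degenerate: too many exactly-zero residuals).
static double mscale(const std::vector<double>& r, double c_chi, double kappa) {
  const int n = (int)r.size();
  double rmax = 0.0;
  int nz = 0;
  for (int i = 0; i < n; ++i) {
    double a = std::fabs(r[i]);
    if (a > rmax) rmax = a;
    if (a > 0) ++nz;
  }
  if (rmax == 0.0) return 0.0;
  double cap = c_chi * c_chi / 6.0;
  // sup_{S -> 0+} mean chi = cap * nz / n; below kappa the equation is
  // unsolvable and S = 0 is returned with the degenerate convention.
  if (cap * nz / n <= kappa * (1.0 + 1e-12)) return 0.0;
  double lo = rmax * 1e-14, hi = rmax * 10.0;
  for (int it = 0; it < 100 && (hi - lo) > 1e-12 * hi; ++it) {
    double mid = 0.5 * (lo + hi), m = 0.0;
    for (int i = 0; i < n; ++i) m += tukey1(r[i] / mid, c_chi);
    m /= n;
    if (m > kappa) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export(name = ".m_scale_cpp")]]
double m_scale_cpp(NumericVector r, double c_chi, double kappa) {
  std::vector<double> rr(r.begin(), r.end());
  return mscale(rr, c_chi, kappa);
}


struct SlopeResult { double beta, S, obj; bool converged; int n_eval; };

// generic 1-d minimizer: log-spaced grid around beta0 (sign preserved),
// then golden-section refinement of the bracketing interval; the best point
// ever evaluated wins (the landscape can have a needle minimum at an
// exact-fit beta).
template <typename F>
static void grid_golden(F f, double beta0, double span, int n_grid,
                        double xtol, int max_eval, double* best_beta,
                        double* best_obj, bool* converged, int* n_eval) {
  double sgn = beta0 < 0 ? -1.0 : 1.0;
  double m0 = std::fabs(beta0);
  if (m0 == 0.0 || !std::isfinite(m0)) { m0 = 1.0; sgn = 1.0; }
  std::vector<double> grid(n_grid);
  for (int i = 0; i < n_grid; ++i) {
    double e = -span + 2.0 * span * i / (n_grid - 1);
    grid[i] = sgn * m0 * std::pow(10.0, e);
  }
  int best_i = 0;
  for (int i = 0; i < n_grid; ++i) {
    double o = f(grid[i]);
    ++*n_eval;
    if (o < *best_obj) { *best_obj = o; *best_beta = grid[i]; best_i = i; }
  }
  double a = grid[std::max(0, best_i - 1)];
  double b = grid[std::min(n_grid - 1, best_i + 1)];
  if (a > b) std::swap(a, b);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = f(c1), f2 = f(c2);
  *n_eval += 2;
  if (f1 < *best_obj) { *best_obj = f1; *best_beta = c1; }
  if (f2 < *best_obj) { *best_obj = f2; *best_beta = c2; }
  while (*n_eval < max_eval &&
         (b - a) > xtol * std::max(1.0, std::fabs(*best_beta))) {
    if (f1 < f2) {
      b = c2; c2 = c1; f2 = f1;
      c1 = b - gr * (b - a);
      f1 = f(c1);
      if (f1 < *best_obj) { *best_obj = f1; *best_beta = c1; }
    } else {
      a = c1; c1 = c2; f1 = f2;
      c2 = a + gr * (b - a);
      f2 = f(c2);
      if (f2 < *best_obj) { *best_obj = f2; *best_beta = c2; }
    }
    ++*n_eval;
  }
  if ((b - a) <= xtol * std::max(1.0, std::fabs(*best_beta)))
    *converged = true;
}

static double scale_at(double beta, const std::vector<double>& x,
                       const std::vector<double>& y, double c_chi,
                       double kappa) {
  const int n = (int)x.size();
  std::vector<double> d(n);
  double inv = 1.0 / std::sqrt(1.0 + beta * beta);
  for (int i = 0; i < n; ++i) d[i] = inv * (y[i] - beta * x[i]);
  return mscale(d, c_chi, kappa);
}

static double mstep_at(double beta, double S, const std::vector<double>& x,
                       const std::vector<double>& y, double c_rho) {
  const int n = (int)x.size();
  double inv = 1.0 / std::sqrt(1.0 + beta * beta), loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = inv * (y[i] - beta * x[i]);
    if (S == 0.0) { if (d != 0.0) loss += c_rho * c_rho / 6.0; }
    else loss += tukey1(d / S, c_rho);
  }
  return loss;
}

// Objective of the M-step at a fixed scale: sum_i rho(d_i(beta)/S).
// Exposed for grid oracles in tests.
// [[Rcpp::export(name = ".eiv_objective_cpp")]]
double eiv_objective_cpp(double beta, NumericVector x, NumericVector y,
                         double S, double c_rho) {
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end());
  return mstep_at(beta, S, xx, yy, c_rho);
}

// Two-step S/M estimate.  Step 1 (S-estimator): minimize the M-scale
// S(beta) of the orthogonal distances over beta (chi at c_chi, target
// kappa).  Step 2 (M-step): with the scale fixed at S* = S(beta_S),
// minimize sum_i rho(d_i(beta)/S*) with rho at c_rho.  The fully nested
// objective sum rho(d_i/S(beta)) is a function of d_i/S only and is
// therefore nearly invariant to beta; the scale itself carries the fit
// information, which is what step 1 minimizes.
static SlopeResult slope_search(const std::vector<double>& x,
                                const std::vector<double>& y, double beta0,
                                double c_rho, double c_chi, double kappa,
                                double xtol, int max_eval, int n_grid,
                                double span) {
  SlopeResult res{beta0, 0.0, 0.0, false, 0};
  double beta_s = beta0, s_obj = R_PosInf;
  bool conv_s = false;
  grid_golden([&](double b) { return scale_at(b, x, y, c_chi, kappa); },
              beta0, span, n_grid, xtol, max_eval, &beta_s, &s_obj,
              &conv_s, &res.n_eval);
  double S = s_obj;
  res.S = S;
  if (S == 0.0) {  // exact fit (or degenerate zero-residual majority)
    res.beta = beta_s;
    res.obj = mstep_at(beta_s, 0.0, x, y, c_rho);
    res.converged = true;
    return res;
  }
  double beta_m = beta_s;
  double m_obj = mstep_at(beta_s, S, x, y, c_rho);
  ++res.n_eval;
  bool conv_m = false;
  // the fixed-scale loss is cheap (no nested scale solve) but can be
  // multimodal; a dense grid guards the golden refinement
  int m_grid = 5 * n_grid + 1;
  grid_golden([&](double b) { return mstep_at(b, S, x, y, c_rho); },
              beta_s, 1.5, m_grid, xtol, res.n_eval + m_grid + max_eval,
              &beta_m, &m_obj, &conv_m, &res.n_eval);
  res.beta = beta_m;
  res.obj = m_obj;
  res.converged = conv_s && conv_m;
  return res;
}

// [[Rcpp::export(name = ".eiv_slope_cpp")]]
List eiv_slope_cpp(NumericVector x, NumericVector y, double beta0,
                   double c_rho, double c_chi, double kappa, double xtol,
                   int max_eval, int n_grid, double span) {
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end());
  SlopeResult r = slope_search(xx, yy, beta0, c_rho, c_chi, kappa, xtol,
                               max_eval, n_grid, span);
  return List::create(_["beta"] = r.beta, _["scale"] = r.S,
                      _["objective"] = r.obj, _["converged"] = r.converged,
                      _["n_eval"] = r.n_eval);
}

static double med(std::vector<double> v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// Bootstrap replicate slopes (resampling pairs with replacement).  Uses R's
// RNG so set.seed() governs reproducibility.  The search is centred on the
// full-data estimate with a narrower grid: replicates of a well-posed fit
// stay close to it.
// [[Rcpp::export(name = ".eiv_boot_cpp")]]
NumericVector eiv_boot_cpp(NumericVector x, NumericVector y, int B,
                           double beta_center, double c_rho, double c_chi,
                           double kappa, double xtol, int max_eval,
                           int n_grid, double span) {
  const int n = x.size();
  NumericVector out(B);
  std::vector<double> xb(n), yb(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = (int)std::floor(unif_rand() * n);
      if (k >= n) k = n - 1;
      xb[i] = x[k];
      yb[i] = y[k];
    }
    // robust start from the replicate itself, falling back to the centre
    std::vector<double> ratio;
    ratio.reserve(n);
    for (int i = 0; i < n; ++i)
      if (xb[i] > 0) ratio.push_back(yb[i] / xb[i]);
    double b0 = ratio.empty() ? beta_center : med(ratio);
    if (!std::isfinite(b0) || b0 == 0.0) b0 = beta_center;
    SlopeResult r = slope_search(xb, yb, b0, c_rho, c_chi, kappa, xtol,
                                 max_eval, n_grid, span);
    out[b] = r.converged || r.S == 0.0 ? r.beta : NA_REAL;
  }
  return out;
}
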