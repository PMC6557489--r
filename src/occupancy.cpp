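#include <Rcpp.h>
using namespace Rcpp;

// Partition-function dynamic programme over binding sites sorted by start.
//
// Sites are 0-based half-open intervals; two sites may be co-bound iff they
// do not overlap.  A configuration's statistical weight is the product of the
// bound sites' weights w_i = K * q * nu times, for every pair of consecutive
// bound sites (in coordinate order), the cooperativity factor omega(k, j)
// (1 unless the pair was declared cooperative within its gap limit).
//
// A[j] = total weight of all configurations whose rightmost bound site is j,
//        using sites 0..j only.
// B[j] = total weight of all right-extensions of a configuration whose
//        leftmost bound site to the right of j chains to j via omega(j, m);
//        B[j] excludes w_j itself.
// Z    = 1 (empty configuration) + sum_j A[j].
// Occupancy of j = A[j] * B[j] / Z.
//
// [[Rcpp::export(name = ".occ_dp_cpp")]]
List occ_dp_cpp(IntegerVector start, IntegerVector end, NumericVector w,
                NumericMatrix omega) {
  const int n = w.size();
  NumericVector A(n), B(n), occ(n);
  for (int j = 0; j < n; ++j) {
    double s = 1.0;
    for (int k = 0; k < j; ++k) {
      if (end[k] <= start[j]) s += A[k] * omega(k, j);
    }
    A[j] = w[j] * s;
  }
  for (int j = n - 1; j >= 0; --j) {
    double s = 1.0;
    for (int m = j + 1; m < n; ++m) {
      if (end[j] <= start[m]) s += omega(j, m) * w[m] * B[m];
    }
    B[j] = s;
  }
  double Z = 1.0;
  for (int j = 0; j < n; ++j) Z += A[j];
  for (int j = 0; j < n; ++j) occ[j] = A[j] * B[j] / Z;
  return List::create(_["occupancy"] = occ, _["partition"] = Z);
}

// Fast whole-model fold predictions used by the ensemble fitter.  No
// cooperativity on this path (the default model has none); the R-level
// predict_construct() is the reference implementation.
//
// Each site table is a numeric matrix with columns (start, end, tf, q),
// tf being a 1-based index into the parameter vectors.  role: 0 activator,
// 1 repressor.  conc is TF x condition.  Returns constructs x conditions
// fold matrix, each fold normalized to the promoter-only rate in that
// condition.
static double rate_one(const NumericMatrix& sites, const NumericMatrix& conc,
                       const IntegerVector& role, const NumericVector& K,
                       const NumericVector& alpha, const NumericVector& gamma_,
                       const NumericVector& betaR, double dq, double theta,
                       double rmax, int cond) {
  const int n = sites.nrow();
  std::vector<double> occ(n, 0.0);
  if (n > 0) {
    std::vector<double> A(n), B(n), w(n);
    for (int i = 0; i < n; ++i) {
      int tf = (int)sites(i, 2) - 1;
      w[i] = K[tf] * sites(i, 3) * conc(tf, cond);
    }
    for (int j = 0; j < n; ++j) {
      double s = 1.0;
      for (int k = 0; k < j; ++k)
        if (sites(k, 1) <= sites(j, 0)) s += A[k];
      A[j] = w[j] * s;
    }
    for (int j = n - 1; j >= 0; --j) {
      double s = 1.0;
      for (int m = j + 1; m < n; ++m)
        if (sites(j, 1) <= sites(m, 0)) s += w[m] * B[m];
      B[j] = s;
    }
    double Z = 1.0;
    for (int j = 0; j < n; ++j) Z += A[j];
    for (int j = 0; j < n; ++j) occ[j] = A[j] * B[j] / Z;
  }
  // quenching + weighted sum + long-range repression
  double E = 0.0, longrange = 1.0;
  for (int i = 0; i < n; ++i) {
    int tfi = (int)sites(i, 2) - 1;
    if (role[tfi] == 1) {
      longrange *= (1.0 - betaR[tfi] * occ[i]);
      continue;
    }
    double oeff = occ[i];
    for (int j = 0; j < n; ++j) {
      int tfj = (int)sites(j, 2) - 1;
      if (role[tfj] != 1) continue;
      double d = 0.0;
      if (sites(i, 1) <= sites(j, 0)) d = sites(j, 0) - sites(i, 1);
      else if (sites(j, 1) <= sites(i, 0)) d = sites(i, 0) - sites(j, 1);
      if (d <= dq) oeff *= (1.0 - gamma_[tfj] * occ[j]);
    }
    if (oeff < 0) oeff = 0;
    E += alpha[tfi] * oeff;
  }
  double Ep = E * longrange;
  double barrier = theta - Ep;
  if (barrier < 0) barrier = 0;
  return rmax * std::exp(-barrier);
}

// [[Rcpp::export(name = ".predict_folds_cpp")]]
NumericMatrix predict_folds_cpp(List site_tables, NumericMatrix prom_sites,
                                NumericMatrix conc, IntegerVector role,
                                NumericVector K, NumericVector alpha,
                                NumericVector gamma_, NumericVector betaR,
                                double dq, double theta, double rmax) {
  const int nc = site_tables.size(), ncond = conc.ncol();
  NumericMatrix folds(nc, ncond);
  for (int cond = 0; cond < ncond; ++cond) {
    double r0 = rate_one(prom_sites, conc, role, K, alpha, gamma_, betaR,
                         dq, theta, rmax, cond);
    for (int i = 0; i < nc; ++i) {
      NumericMatrix st = site_tables[i];
      folds(i, cond) = rate_one(st, conc, role, K, alpha, gamma_, betaR,
                                dq, theta, rmax, cond) / r0;
    }
  }
  return folds;
}
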