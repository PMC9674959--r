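#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for L1-penalized linear and logistic models.
//
// Objective (glmnet-style scaling, intercept unpenalized):
//   gaussian: (1/(2n)) * sum((y - b0 - X b)^2)      + lambda * sum(|b_j|)
//   binomial: (1/n) * sum(log(1+exp(eta)) - y*eta)  + lambda * sum(|b_j|)
// The binomial case is solved by IRLS over a weighted least-squares
// inner problem, itself solved by coordinate descent with an active-set
// strategy (full sweep, then iterate the nonzero set to convergence,
// repeat until a full sweep changes nothing). Columns are visited in
// their given (deterministic) order; no internal standardization is
// applied, since inputs are already scaled to [0, 1]. A path that
// saturates (>99.9% of the null deviance explained) is terminated early
// and the saturated solution carried forward to the remaining smaller
// penalties.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate sweep over the given index set. Returns the convergence
// criterion: the largest weighted squared update max_j (wxsq_j * d_j^2),
// which tolerates the non-unique solutions exact collinearity induces.
static double cd_sweep(const NumericMatrix& X, const std::vector<double>& w,
                       double wsum, const std::vector<double>& wxsq,
                       std::vector<double>& r, double& b0,
                       std::vector<double>& b, double lambda,
                       const std::vector<int>& idx) {
  const int n = X.nrow();
  double maxdelta = 0.0;
  double rs = 0.0;
  for (int i = 0; i < n; ++i) rs += w[i] * r[i];
  double d0 = rs / wsum;
  b0 += d0;
  for (int i = 0; i < n; ++i) r[i] -= d0;
  maxdelta = (wsum / n) * d0 * d0;
  for (int k = 0; k < (int)idx.size(); ++k) {
    int j = idx[k];
    if (wxsq[j] <= 0.0) { b[j] = 0.0; continue; }
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * X(i, j) * r[i];
    num = num / n + wxsq[j] * b[j];
    double bj = soft_threshold(num, lambda) / wxsq[j];
    double d = bj - b[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
      b[j] = bj;
      double crit = wxsq[j] * d * d;
      if (crit > maxdelta) maxdelta = crit;
    }
  }
  return maxdelta;
}

// weighted least-squares lasso with active-set iteration
static void cd_wls(const NumericMatrix& X, const std::vector<double>& w,
                   std::vector<double>& r, double& b0,
                   std::vector<double>& b, double lambda, double tol,
                   int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];
  if (wsum <= 0.0) return;
  std::vector<double> wxsq(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
    wxsq[j] = s / n;
  }
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    double d_full = cd_sweep(X, w, wsum, wxsq, r, b0, b, lambda, all);
    ++sweeps;
    if (d_full < tol) break;
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) active.push_back(j);
    while (sweeps < max_sweeps) {
      double d = cd_sweep(X, w, wsum, wxsq, r, b0, b, lambda, active);
      ++sweeps;
      if (d < tol) break;
    }
  }
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                   std::string family, double tol = 1e-7,
                   int max_sweeps = 2000) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  const bool binomial = (family == "binomial");
  NumericMatrix beta(p, nl);
  NumericVector intercept(nl);

  std::vector<double> b(p, 0.0);
  double b0 = 0.0;
  double null_dev = 0.0;
  double ybar = mean(y);
  if (binomial) {
    double pb = std::min(std::max(ybar, 1e-8), 1.0 - 1e-8);
    b0 = std::log(pb / (1.0 - pb));
    for (int i = 0; i < n; ++i)
      null_dev += -2.0 * (y[i] * std::log(pb) +
                          (1.0 - y[i]) * std::log(1.0 - pb));
  } else {
    b0 = ybar;
    for (int i = 0; i < n; ++i)
      null_dev += (y[i] - ybar) * (y[i] - ybar);
  }
  if (null_dev <= 0.0) null_dev = 1e-10;

  std::vector<double> w(n, 1.0), r(n), eta(n);
  int saturated_at = -1;
  for (int l = 0; l < nl; ++l) {  // warm starts along a decreasing path
    if (saturated_at >= 0) {
      intercept[l] = intercept[saturated_at];
      for (int j = 0; j < p; ++j) beta(j, l) = beta(j, saturated_at);
      continue;
    }
    double lam = lambda[l];
    double dev = 0.0;
    if (!binomial) {
      for (int i = 0; i < n; ++i) {
        double fit = b0;
        for (int j = 0; j < p; ++j) if (b[j] != 0.0) fit += X(i, j) * b[j];
        r[i] = y[i] - fit;
      }
      cd_wls(X, w, r, b0, b, lam, tol, max_sweeps);
      for (int i = 0; i < n; ++i) dev += r[i] * r[i];
    } else {
      for (int outer = 0; outer < 50; ++outer) {
        for (int i = 0; i < n; ++i) {
          double fit = b0;
          for (int j = 0; j < p; ++j) if (b[j] != 0.0) fit += X(i, j) * b[j];
          double pr = 1.0 / (1.0 + std::exp(-fit));
          pr = std::min(std::max(pr, 1e-5), 1.0 - 1e-5);
          w[i] = pr * (1.0 - pr);
          r[i] = (y[i] - pr) / w[i];  // working residual about current fit
        }
        double b0_old = b0;
        std::vector<double> b_old(b);
        cd_wls(X, w, r, b0, b, lam, tol, max_sweeps);
        double crit = b0 - b0_old; crit = crit * crit;
        for (int j = 0; j < p; ++j) {
          double d = b[j] - b_old[j];
          if (d * d > crit) crit = d * d;
        }
        if (crit < tol) break;
      }
      dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double fit = b0;
        for (int j = 0; j < p; ++j) if (b[j] != 0.0) fit += X(i, j) * b[j];
        double pr = 1.0 / (1.0 + std::exp(-fit));
        pr = std::min(std::max(pr, 1e-10), 1.0 - 1e-10);
        dev += -2.0 * (y[i] * std::log(pr) +
                       (1.0 - y[i]) * std::log(1.0 - pr));
      }
    }
    intercept[l] = b0;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    if (1.0 - dev / null_dev > 0.999) saturated_at = l;
  }
  return List::create(_["intercept"] = intercept, _["beta"] = beta);
}
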