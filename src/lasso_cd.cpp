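#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// L1-penalized logistic regression by IRLS with cyclic coordinate descent.
//
// Objective, with W = sum_i w_i (observation weights, default 1):
//   (1/W) * sum_i w_i * [ -y_i*eta_i + log(1 + exp(eta_i)) ]
//     + lambda * sum_j pf_j * |beta_j|
// Each outer (IRLS) iteration forms the weighted quadratic approximation at
// the current eta and solves it by cyclic coordinate-wise soft-thresholding.
// The inner solver alternates full residual-based sweeps (which certify the
// KKT conditions over all coordinates) with covariance-updating sweeps over
// the active set: inner products among active columns are cached, so an
// active sweep costs O(|A|^2) instead of O(|A| n) — near-collinear index
// columns need many sweeps to converge and this keeps them cheap. The
// intercept and penalty-factor-0 columns are unpenalized. IRLS variance
// weights are floored at 1e-9 to keep the working response finite near
// separation; for lambda > 0 the penalty keeps the solution finite anyway.

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".lasso_logistic_cd")]]
List lasso_logistic_cd(const NumericMatrix& X,
                       const NumericVector& y,
                       const NumericVector& obs_weight,
                       const NumericVector& penalty_factor,
                       double lambda,
                       double intercept_init,
                       const NumericVector& beta_init,
                       double tol,
                       int max_outer,
                       int max_inner) {
  const int n = X.nrow(), p = X.ncol();
  double b0 = intercept_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(n), w(n), r(n), denom(p), gpen(p);
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += obs_weight[i];

  for (int j = 0; j < p; ++j) {
    // lambda may be +Inf (used to fit the unpenalized-controls-only model);
    // 0 * Inf must mean "no penalty", not NaN
    gpen[j] = (penalty_factor[j] == 0.0) ? 0.0 : lambda * penalty_factor[j];
  }
  for (int i = 0; i < n; ++i) {
    double e = b0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  // residual-based update of one coordinate (exact); returns |delta|
  auto update_coord = [&](int j) -> double {
    if (denom[j] <= 0.0) return 0.0;
    if (!R_finite(gpen[j])) { beta[j] = 0.0; return 0.0; }
    const double* xj = &X(0, j);
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
    num = num / wsum + denom[j] * beta[j];
    double bj = soft_threshold(num, gpen[j]) / denom[j];
    double d = bj - beta[j];
    if (d != 0.0) {
      beta[j] = bj;
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
    }
    return std::fabs(d);
  };
  auto update_intercept = [&]() -> double {
    double num0 = 0.0;
    for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
    double d0 = num0 / wsum;
    if (d0 != 0.0) {
      b0 += d0;
      for (int i = 0; i < n; ++i) r[i] -= d0;
    }
    return std::fabs(d0);
  };

  bool converged = false;
  int outer = 0;
  double max_delta_outer = NA_REAL;

  for (outer = 0; outer < max_outer; ++outer) {
    for (int i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta[i]));
      double v = mu * (1.0 - mu);
      if (v < 1e-9) v = 1e-9;
      w[i] = obs_weight[i] * v;
      r[i] = obs_weight[i] * (y[i] - mu) / w[i];  // z - eta
    }
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      denom[j] = s / wsum;
    }
    const double b0_old = b0;
    std::vector<double> beta_old(beta);

    // covariance cache for the active set (index -1 = intercept); C depends
    // only on the IRLS weights, which are fixed within this outer iteration,
    // so it is rebuilt only when the active membership changes
    std::vector<int> act_cached;
    std::vector<double> C, da, ga;
    auto build_cache = [&](const std::vector<int>& act) {
      const int m = (int) act.size();
      C.assign((size_t) m * m, 0.0);
      da.assign(m, 0.0); ga.assign(m, 0.0);
      for (int a = 0; a < m; ++a) {
        da[a] = (act[a] < 0) ? 1.0 : denom[act[a]];
        ga[a] = (act[a] < 0) ? 0.0 : gpen[act[a]];
        for (int b = 0; b <= a; ++b) {
          double cab = 0.0;
          if (act[a] < 0 && act[b] < 0) {
            cab = wsum;
          } else if (act[b] < 0) {
            const double* xa = &X(0, act[a]);
            for (int i = 0; i < n; ++i) cab += w[i] * xa[i];
          } else {
            const double* xa = &X(0, act[a]);
            const double* xb = &X(0, act[b]);
            for (int i = 0; i < n; ++i) cab += w[i] * xa[i] * xb[i];
          }
          cab /= wsum;
          C[(size_t) a * m + b] = cab;
          C[(size_t) b * m + a] = cab;
        }
      }
      act_cached = act;
    };

    int sweeps = 0;
    while (sweeps < max_inner) {
      // full certified sweep over all coordinates (exact residual updates)
      double max_delta = update_intercept();
      for (int j = 0; j < p; ++j) {
        double d = update_coord(j);
        if (d > max_delta) max_delta = d;
      }
      ++sweeps;
      if (max_delta < tol) break;

      // covariance-mode sweeps over the active set
      std::vector<int> act;
      act.push_back(-1);
      for (int j = 0; j < p; ++j) {
        if ((beta[j] != 0.0 || penalty_factor[j] == 0.0) &&
            denom[j] > 0.0 && R_finite(gpen[j])) act.push_back(j);
      }
      if (act != act_cached) build_cache(act);
      const int m = (int) act.size();
      std::vector<double> q(m), dacc(m, 0.0);
      for (int a = 0; a < m; ++a) {
        double s = 0.0;
        if (act[a] < 0) {
          for (int i = 0; i < n; ++i) s += w[i] * r[i];
        } else {
          const double* xa = &X(0, act[a]);
          for (int i = 0; i < n; ++i) s += w[i] * xa[i] * r[i];
        }
        q[a] = s / wsum;
      }
      while (sweeps < max_inner) {
        double md = 0.0;
        for (int a = 0; a < m; ++a) {
          double cur = (act[a] < 0) ? b0 : beta[act[a]];
          double num = q[a] + da[a] * cur;
          double nb = (ga[a] == 0.0) ? num / da[a]
                                     : soft_threshold(num, ga[a]) / da[a];
          double d = nb - cur;
          if (d != 0.0) {
            if (act[a] < 0) b0 = nb; else beta[act[a]] = nb;
            dacc[a] += d;
            const double* Ca = &C[(size_t) a * m];
            for (int b = 0; b < m; ++b) q[b] -= d * Ca[b];
            double ad = std::fabs(d);
            if (ad > md) md = ad;
          }
        }
        ++sweeps;
        if (md < tol * 0.5) break;  // slack for drift against exact residuals
      }
      // sync the residual with the accumulated active-set moves
      for (int a = 0; a < m; ++a) {
        if (dacc[a] == 0.0) continue;
        if (act[a] < 0) {
          for (int i = 0; i < n; ++i) r[i] -= dacc[a];
        } else {
          const double* xa = &X(0, act[a]);
          for (int i = 0; i < n; ++i) r[i] -= dacc[a] * xa[i];
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
      eta[i] = e;
    }
    double md = std::fabs(b0 - b0_old);
    for (int j = 0; j < p; ++j) {
      double d = std::fabs(beta[j] - beta_old[j]);
      if (d > md) md = d;
    }
    max_delta_outer = md;
    if (md < tol) { converged = true; ++outer; break; }
  }

  return List::create(_["intercept"] = b0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = converged,
                      _["outer_iterations"] = outer,
                      _["max_delta"] = max_delta_outer);
}

// [[Rcpp::export(name = ".lasso_objective_cpp")]]
double lasso_objective_cpp(const NumericMatrix& X,
                           const NumericVector& y,
                           const NumericVector& obs_weight,
                           const NumericVector& penalty_factor,
                           double lambda,
                           double intercept,
                           const NumericVector& beta) {
  const int n = X.nrow(), p = X.ncol();
  double wsum = 0.0, nll = 0.0;
  for (int i = 0; i < n; ++i) wsum += obs_weight[i];
  for (int i = 0; i < n; ++i) {
    double e = intercept;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
    // log(1 + exp(e)) computed stably
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    nll += obs_weight[i] * (lse - y[i] * e);
  }
  double pen = 0.0;
  for (int j = 0; j < p; ++j) {
    if (penalty_factor[j] != 0.0 && beta[j] != 0.0)
      pen += penalty_factor[j] * std::fabs(beta[j]);
  }
  return nll / wsum + lambda * pen;
}
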