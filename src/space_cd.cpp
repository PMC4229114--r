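#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Joint sparse regression for symmetric partial correlations.
//
// Data model: each standardized gene i is regressed on all the others with
// the coefficients tied through the partial-correlation parameterization
//   beta_ij = rho_ij * sqrt(d_j / d_i),
// where d_i is gene i's diagonal concentration. The loss is
//   (1/2) * sum_i ||x_i - sum_{j != i} beta_ij x_j||^2
//     + lambda * sum_{i < j} |rho_ij|,
// minimized by cyclic coordinate descent over the unordered pairs. Each
// pair update is an exact univariate lasso step (soft threshold); residual
// columns for both genes are updated in place. Alternates full sweeps with
// sweeps over the current active (nonzero) set; after each inner
// convergence the diagonal concentrations are refit from the residual
// variances and the residuals are rebuilt (outer loop).
//
// X must arrive column-standardized with sum of squares n per column.
// [[Rcpp::export(name = ".space_cd")]]
List space_cd(NumericMatrix X, double lambda, int max_iter, double tol,
              int outer_iter) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix rho(p, p);
  std::vector<double> d(p, 1.0);        // diagonal concentration estimates
  std::vector<double> xnorm(p);         // column sums of squares
  NumericMatrix R(n, p);                // residual columns

  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int k = 0; k < n; ++k) s += X(k, j) * X(k, j);
    xnorm[j] = s;
  }

  int sweeps = 0;
  bool converged = false;

  for (int outer = 0; outer < outer_iter; ++outer) {
    // rebuild residuals from the current rho and d
    for (int i = 0; i < p; ++i) {
      for (int k = 0; k < n; ++k) R(k, i) = X(k, i);
      for (int j = 0; j < p; ++j) {
        double r = rho(i, j);
        if (j == i || r == 0.0) continue;
        double b = r * std::sqrt(d[j] / d[i]);
        for (int k = 0; k < n; ++k) R(k, i) -= b * X(k, j);
      }
    }

    // one exact coordinate update for pair (i, j); returns |change|
    double* Rp = REAL(R);
    double* Xp = REAL(X);
    double* rhop = REAL(rho);
    auto update_pair = [&](int i, int j) -> double {
      double r_old = rhop[i + (size_t)p * j];
      double aij = std::sqrt(d[j] / d[i]);
      double aji = std::sqrt(d[i] / d[j]);
      double* xi = Xp + (size_t)n * i;
      double* xj = Xp + (size_t)n * j;
      double* ri = Rp + (size_t)n * i;
      double* rj = Rp + (size_t)n * j;
      double dot_i = 0.0, dot_j = 0.0;
      for (int k = 0; k < n; ++k) {
        dot_i += xj[k] * ri[k];
        dot_j += xi[k] * rj[k];
      }
      double denom = aij * aij * xnorm[j] + aji * aji * xnorm[i];
      double u = aij * dot_i + aji * dot_j + r_old * denom;
      double r_new = 0.0;
      if (u > lambda) r_new = (u - lambda) / denom;
      else if (u < -lambda) r_new = (u + lambda) / denom;
      double delta = r_new - r_old;
      if (delta != 0.0) {
        double bi = delta * aij, bj = delta * aji;
        for (int k = 0; k < n; ++k) {
          ri[k] -= bi * xj[k];
          rj[k] -= bj * xi[k];
        }
        rhop[i + (size_t)p * j] = r_new;
        rhop[j + (size_t)p * i] = r_new;
      }
      return std::fabs(delta);
    };

    // active-set descent: cycle the nonzero pairs to convergence, then scan
    // all pairs once; re-enter descent only if the scan moved something
    // (a zero pair violating its optimality condition, or an active pair
    // still improving). Terminates when a full scan changes nothing by
    // more than tol.
    converged = false;
    int it = 0;
    std::vector<std::pair<int, int> > active;
    while (it < max_iter) {
      // full scan
      ++it;
      ++sweeps;
      double scan_delta = 0.0;
      for (int i = 0; i < p - 1; ++i)
        for (int j = i + 1; j < p; ++j) {
          double ad = update_pair(i, j);
          if (ad > scan_delta) scan_delta = ad;
        }
      if (scan_delta < tol) { converged = true; break; }
      // collect active set
      active.clear();
      for (int i = 0; i < p - 1; ++i)
        for (int j = i + 1; j < p; ++j)
          if (rhop[i + (size_t)p * j] != 0.0) active.push_back({i, j});
      // descend on the active set
      while (it < max_iter) {
        ++it;
        ++sweeps;
        double maxdelta = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          double ad = update_pair(active[a].first, active[a].second);
          if (ad > maxdelta) maxdelta = ad;
        }
        if (maxdelta < tol) break;
      }
    }

    if (outer < outer_iter - 1) {
      for (int i = 0; i < p; ++i) {
        double rss = 0.0;
        for (int k = 0; k < n; ++k) rss += R(k, i) * R(k, i);
        d[i] = n / std::max(rss, 1e-12);
      }
    }
  }

  return List::create(_["rho"] = rho,
                      _["d"] = NumericVector(d.begin(), d.end()),
                      _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
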