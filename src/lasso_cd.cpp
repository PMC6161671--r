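#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for L1-penalised logistic regression on the
// IRLS quadratic approximation (glmnet-style).  X is expected to be
// standardised (mean 0, population SD 1); the intercept is unpenalised.
// Objective: (1/n) * sum -loglik_i + lambda * sum_j |beta_j|.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List lasso_path_cd(const NumericMatrix& X, const NumericVector& y,
                   const NumericVector& lambda, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix beta_out(p, nl);
  NumericVector b0_out(nl);
  IntegerVector iters(nl);

  std::vector<double> beta(p, 0.0);
  const double ybar = mean(y);
  double b0 = std::log(std::max(ybar, 1e-12) /
                       std::max(1.0 - ybar, 1e-12));
  std::vector<double> eta(n), w(n), z(n), r(n);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    int it = 0;
    for (; it < maxit; ++it) {
      // IRLS weights and working response at current (b0, beta)
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
        double pr = 1.0 / (1.0 + std::exp(-e));
        if (pr < 1e-8) pr = 1e-8;
        if (pr > 1.0 - 1e-8) pr = 1.0 - 1e-8;
        w[i] = pr * (1.0 - pr);
        z[i] = e + (y[i] - pr) / w[i];
        r[i] = z[i] - e;  // working residual
      }
      double sw = 0.0;
      for (int i = 0; i < n; ++i) sw += w[i];

      // inner coordinate descent on the weighted least squares problem
      double dmax_outer = 0.0;
      for (int inner = 0; inner < 1000; ++inner) {
        double dmax = 0.0;
        // intercept
        double num0 = 0.0;
        for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
        double db0 = num0 / sw;
        if (db0 != 0.0) {
          b0 += db0;
          for (int i = 0; i < n; ++i) r[i] -= db0;
          dmax = std::max(dmax, std::fabs(db0));
        }
        for (int j = 0; j < p; ++j) {
          double num = 0.0, den = 0.0;
          for (int i = 0; i < n; ++i) {
            num += w[i] * X(i, j) * r[i];
            den += w[i] * X(i, j) * X(i, j);
          }
          num = num / n + (den / n) * beta[j];
          double bj = soft(num, lam) / (den / n);
          double d = bj - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
            beta[j] = bj;
            dmax = std::max(dmax, std::fabs(d));
          }
        }
        dmax_outer = std::max(dmax_outer, dmax);
        if (dmax < tol) break;
      }
      if (dmax_outer < tol) break;  // IRLS converged
    }
    iters[l] = it + 1;
    if (it >= maxit)
      stop("coordinate descent did not converge at lambda = %g "
           "(maxit = %d, tol = %g)", lam, maxit, tol);
    b0_out[l] = b0;
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
  }
  return List::create(_["b0"] = b0_out, _["beta"] = beta_out,
                      _["iterations"] = iters);
}
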