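#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// L1-penalized logistic regression, solved by IRLS with cyclic coordinate
// descent on the penalized weighted least-squares subproblem (the glmnet
// algorithm, written here for the unscaled objective used throughout the
// package):
//
//   f(b0, b) = -sum_i [ y_i eta_i - log(1 + exp(eta_i)) ] + lambda * sum_j |b_j|
//
// with eta = b0 + X b and the intercept unpenalized. X is expected to be
// standardized by the caller. A step-halving safeguard keeps the objective
// monotone non-increasing across outer iterations.

static inline double log1pe(double z) {
  if (z > 30.0) return z;
  if (z < -30.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

// soft threshold with a tiny relative fuzz: the first IRLS weight pass
// reconstructs the prevalence through logit/plogis, so at lambda = lambda_max
// the stationarity bound can be exceeded by a few ulp; the fuzz keeps the
// all-zero solution exact there without measurably moving any other solution
static inline double soft(double z, double g) {
  const double fuzz = 1e-10 * (g + 1.0);
  if (z > g + fuzz) return z - g;
  if (z < -g - fuzz) return z + g;
  return 0.0;
}

static double objective(const NumericMatrix& X, const NumericVector& y,
                        double b0, const NumericVector& beta, double lambda) {
  const int n = X.nrow(), p = X.ncol();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = b0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    nll -= y[i] * eta - log1pe(eta);
  }
  double pen = 0.0;
  for (int j = 0; j < p; ++j) pen += std::fabs(beta[j]);
  return nll + lambda * pen;
}

// one fit at a single lambda, warm-started in place; returns iterations used
static int fit_one(const NumericMatrix& X, const NumericVector& y,
                   double lambda, double& b0, NumericVector& beta,
                   double tol, int max_outer, int max_inner,
                   bool use_intercept, std::vector<double>* trace) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n), w(n), z(n);
  double f_prev = objective(X, y, b0, beta, lambda);
  if (trace) trace->push_back(f_prev);
  {
    // warm start already at a perfect (separable) fit: nothing left to gain
    double pen0 = 0.0;
    for (int j = 0; j < p; ++j) pen0 += std::fabs(beta[j]);
    if (f_prev - lambda * pen0 < 1e-8) return 1;
  }
  int outer;
  for (outer = 0; outer < max_outer; ++outer) {
    // IRLS weights and working response at current estimate
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
      double pr = 1.0 / (1.0 + std::exp(-e));
      double wi = pr * (1.0 - pr);
      if (wi < 1e-5) wi = 1e-5;
      w[i] = wi;
      z[i] = e + (y[i] - pr) / wi;
    }
    double b0_old = b0;
    NumericVector beta_old = clone(beta);
    // coordinate descent on 0.5*sum w (z - b0 - Xb)^2 + lambda*sum|b|
    NumericVector r(n);  // residual z - b0 - X beta
    for (int i = 0; i < n; ++i) r[i] = z[i] - eta[i];
    // weighted column norms are constant within this subproblem
    std::vector<double> wx2(p);
    double sw = 0.0;
    for (int i = 0; i < n; ++i) sw += w[i];
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      wx2[j] = s;
    }
    std::vector<int> active;
    active.reserve(p);
    auto update_coord = [&](int j) -> double {
      if (wx2[j] <= 0.0) return 0.0;
      double swxr = 0.0;
      for (int i = 0; i < n; ++i) swxr += w[i] * X(i, j) * r[i];
      double bj_new = soft(beta[j] * wx2[j] + swxr, lambda) / wx2[j];
      double d = bj_new - beta[j];
      if (d != 0.0) {
        beta[j] = bj_new;
        for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
      }
      return std::fabs(d);
    };
    auto update_intercept = [&]() -> double {
      if (!use_intercept) return 0.0;
      double swr = 0.0;
      for (int i = 0; i < n; ++i) swr += w[i] * r[i];
      double d0 = swr / sw;
      if (d0 != 0.0) {
        b0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
      }
      return std::fabs(d0);
    };
    // one full sweep to establish the active set, then iterate on it,
    // finishing with full sweeps until no coordinate moves
    int sweeps = 0;
    while (sweeps < max_inner) {
      double delta_max = update_intercept();
      for (int j = 0; j < p; ++j) delta_max = std::max(delta_max, update_coord(j));
      ++sweeps;
      if (delta_max < 1e-10) break;
      active.clear();
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
      while (sweeps < max_inner) {
        double dm = update_intercept();
        for (int j : active) dm = std::max(dm, update_coord(j));
        ++sweeps;
        if (dm < 1e-10) break;
      }
    }
    // safeguard: step-halve back toward the previous iterate if the Newton
    // step overshot (objective must be monotone non-increasing)
    double f_new = objective(X, y, b0, beta, lambda);
    int halvings = 0;
    while (f_new > f_prev + 1e-12 && halvings < 30) {
      b0 = 0.5 * (b0 + b0_old);
      for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + beta_old[j]);
      f_new = objective(X, y, b0, beta, lambda);
      ++halvings;
    }
    if (trace) trace->push_back(f_new);
    bool converged = std::fabs(f_prev - f_new) < tol * (std::fabs(f_new) + 1.0);
    f_prev = f_new;
    if (converged) break;
    // separable / perfect-fit region: the penalized NLL cannot go below the
    // penalty term; stop once the data part is numerically exhausted
    double pen = 0.0;
    for (int j = 0; j < p; ++j) pen += std::fabs(beta[j]);
    if (f_new - lambda * pen < 1e-8) break;
  }
  return outer + 1;
}

// [[Rcpp::export(name = ".lasso_logistic_path_cpp")]]
List lasso_logistic_path_cpp(NumericMatrix X, NumericVector y,
                             NumericVector lambdas, double tol,
                             int max_outer, int max_inner, bool keep_trace,
                             bool use_intercept) {
  const int p = X.ncol(), L = lambdas.size();
  NumericMatrix beta_path(p, L);
  NumericVector b0_path(L), obj(L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  double ybar = mean(y);
  if (ybar <= 0.0 || ybar >= 1.0) stop("y must contain both classes");
  double b0 = use_intercept ? std::log(ybar / (1.0 - ybar)) : 0.0;
  NumericVector beta(p);
  std::vector<double> trace;
  for (int l = 0; l < L; ++l) {
    int used = fit_one(X, y, lambdas[l], b0, beta, tol, max_outer, max_inner,
                       use_intercept,
                       keep_trace ? &trace : (std::vector<double>*)nullptr);
    for (int j = 0; j < p; ++j) beta_path(j, l) = beta[j];
    b0_path[l] = b0;
    obj[l] = objective(X, y, b0, beta, lambdas[l]);
    iters[l] = used;
    conv[l] = used < max_outer;
  }
  List out = List::create(_["beta"] = beta_path, _["b0"] = b0_path,
                          _["objective"] = obj, _["iterations"] = iters,
                          _["converged"] = conv);
  if (keep_trace) out["trace"] = wrap(trace);
  return out;
}

// [[Rcpp::export(name = ".lasso_objective_cpp")]]
double lasso_objective_cpp(NumericMatrix X, NumericVector y, double b0,
                           NumericVector beta, double lambda) {
  return objective(X, y, b0, beta, lambda);
}
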