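# standardize columns to mean 0 / sd 1 (sd on n-1 denominator); constant
# columns are centered and left at zero scale 1 so they can never be selected
standardize_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

apply_standardization <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

#' Smallest penalty that zeroes every coefficient
#'
#' With an unpenalized intercept, the all-zero coefficient vector (intercept
#' at the prevalence logit) is optimal exactly when
#' `lambda >= max_j |x_j' (y - mean(y))|`; in the intercept-free model (the
#' form the study's likelihood is written in) the fitted null probability is
#' 1/2 and the bound is `max_j |x_j' (y - 1/2)|`.
#'
#' @param X Design matrix; standardized internally by default with exactly the
#'   arithmetic the fit uses, so the zero-solution guarantee holds to the last
#'   bit.
#' @param y 0/1 response.
#' @param standardize Standardize `X` first (default `TRUE`).
#' @param intercept Whether the model the bound is for has an unpenalized
#'   intercept.
#' @return The critical penalty value.
#' @export
lambda_max <- function(X, y, standardize = TRUE, intercept = TRUE) {
  if (standardize) X <- standardize_train(X)$X
  max(abs(crossprod(X, y - if (intercept) mean(y) else 0.5)))
}

#' Fit an L1-penalized logistic regression
#'
#' Minimizes `-sum_i [y_i eta_i - log(1+exp(eta_i))] + lambda * sum_j |beta_j|`
#' (`eta = b0 + X beta`) by iteratively reweighted least squares with cyclic
#' coordinate descent and a monotone step-halving safeguard. Features are
#' standardized on the supplied rows before fitting unless
#' `standardize = FALSE`; coefficients are reported on the standardized
#' scale. With `intercept = TRUE` an unpenalized intercept is fitted; with
#' `intercept = FALSE` the model is the pure `beta' rho` form the study's
#' likelihood is written in (the ensemble default, see
#' [repeated_holdout()]).
#'
#' @param X Numeric matrix (samples x features), finite.
#' @param y 0/1 response containing both classes.
#' @param lambda Non-negative penalty (on the summed, unscaled
#'   log-likelihood).
#' @param standardize Standardize columns internally (default `TRUE`).
#' @param intercept Fit an unpenalized intercept (default `TRUE`).
#' @param tol Relative objective convergence tolerance.
#' @param max_outer,max_inner Iteration caps (outer IRLS / inner coordinate
#'   sweeps). With `lambda = 0` on separable data coefficients diverge; the
#'   cap stops the fit and `converged` is `FALSE`.
#' @param keep_trace Keep the per-outer-iteration objective trace.
#' @return A `penalized_logistic_fit`: `beta`, `intercept`, `lambda`,
#'   `objective`, `converged`, `iterations`, standardization parameters, and
#'   optionally `trace`.
#' @export
fit_penalized_logistic <- function(X, y, lambda, standardize = TRUE,
                                   intercept = TRUE, tol = 1e-9,
                                   max_outer = 200L, max_inner = 200L,
                                   keep_trace = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (any(!is.finite(X)))
    id_stop("X contains non-finite values (impute before fitting)", "immunodyn_domain_error")
  if (length(unique(y)) < 2L)
    id_stop("y must contain both classes", "immunodyn_domain_error")
  if (!all(y %in% c(0, 1)))
    id_stop("y must be coded 0/1", "immunodyn_domain_error")
  if (lambda < 0) id_stop("lambda must be non-negative", "immunodyn_config_error")
  std <- if (standardize) standardize_train(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  res <- .lasso_logistic_path_cpp(std$X, y, lambda, tol, max_outer, max_inner,
                                  keep_trace, intercept)
  if (!res$converged[1L])
    id_log("fit at lambda=%g hit the iteration cap (separable or lambda=0 data)",
           lambda)
  structure(list(beta = setNames(res$beta[, 1L], colnames(X)),
                 intercept = res$b0[1L], lambda = lambda,
                 objective = res$objective[1L],
                 converged = res$converged[1L],
                 iterations = res$iterations[1L],
                 center = std$center, scale = std$scale,
                 trace = if (keep_trace) res$trace else NULL),
            class = "penalized_logistic_fit")
}

#' @export
print.penalized_logistic_fit <- function(x, ...) {
  cat(sprintf("penalized_logistic_fit: lambda=%.4g, %d/%d nonzero, objective %.6g%s\n",
              x$lambda, sum(x$beta != 0), length(x$beta), x$objective,
              if (x$converged) "" else " (iteration cap)"))
  invisible(x)
}

predict_fit <- function(fit, X_std) {
  plogis(fit$intercept + drop(X_std %*% fit$beta))
}

# log-spaced penalty path from lambda_max down to ratio*lambda_max
lambda_path <- function(lmax, n_lambda = 100L, min_ratio = 0.01) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# stratified fold assignment: shuffles within each class so every fold holds
# both classes whenever counts permit
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Select the penalty by internal cross-validation
#'
#' Builds a log-spaced path of `n_lambda` penalties from the training
#' `lambda_max` down to `min_ratio * lambda_max` and scores each by mean
#' held-out binomial deviance over stratified `n_folds`-fold
#' cross-validation. The default `rule = "1se"` returns the sparsest penalty
#' whose mean deviance is within one standard error of the minimum (the
#' conventional guard against overselection at this sample size);
#' `rule = "min"` returns the deviance minimizer itself. Ties resolve to the
#' largest (sparsest) penalty. Deterministic given `seed`.
#'
#' @param X_train,y_train Training data (unstandardized; each fold fit
#'   standardizes on its own rows).
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param n_lambda,min_ratio Path settings.
#' @param rule `"1se"` (default) or `"min"`.
#' @return List: `lambda` (selected), `lambda_min`, `path`, `cv_deviance`,
#'   `cv_se`.
#' @export
select_lambda <- function(X_train, y_train, n_folds = 5L, seed = 1L,
                          n_lambda = 100L, min_ratio = 0.01,
                          rule = c("1se", "min"), intercept = TRUE) {
  rule <- match.arg(rule)
  if (n_folds < 2L) id_stop("n_folds must be at least 2", "immunodyn_config_error")
  if (length(unique(y_train)) < 2L)
    id_stop("training set must contain both classes", "immunodyn_domain_error")
  path <- lambda_path(lambda_max(X_train, y_train, intercept = intercept),
                      n_lambda, min_ratio)
  set.seed(seed)
  fold <- stratified_folds(y_train, n_folds)
  dev <- matrix(NA_real_, n_folds, length(path))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y_train[tr])) < 2L || sum(!tr) == 0L) next
    std <- standardize_train(X_train[tr, , drop = FALSE])
    # lighter caps than a final fit: warm starts keep the path accurate, and
    # the deep-overfit end of the path only needs to score badly, not converge
    res <- .lasso_logistic_path_cpp(std$X, y_train[tr], path, 1e-8, 50L, 100L,
                                    FALSE, intercept)
    X_ho <- apply_standardization(X_train[!tr, , drop = FALSE], std)
    eta <- sweep(X_ho %*% res$beta, 2L, res$b0, "+")
    pr <- plogis(eta)
    dev[f, ] <- vapply(seq_along(path), function(l)
      binomial_deviance(y_train[!tr], pr[, l]), numeric(1))
  }
  mdev <- colMeans(dev, na.rm = TRUE)
  sedev <- apply(dev, 2L, function(v) sd(v, na.rm = TRUE)) /
    sqrt(colSums(!is.na(dev)))
  i_min <- which(mdev <= min(mdev) + 1e-12)[1L]  # decreasing path: first = sparsest
  best <- if (rule == "1se")
    which(mdev <= mdev[i_min] + sedev[i_min])[1L] else i_min
  list(lambda = path[best], lambda_min = path[i_min], path = path,
       cv_deviance = mdev, cv_se = sedev)
}

#' Shared AUC implementation (Mann-Whitney)
#'
#' `AUC = U / (n_case * n_control)` with ties counted 0.5, computed from
#' midranks. This single implementation backs both the ensemble-model
#' evaluation and the per-feature univariate annotations.
#'
#' @param values Numeric scores.
#' @param labels 0/1 (or logical) class labels; `1` = case.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    id_stop("both classes required for AUC", "immunodyn_domain_error")
  r <- rank(values)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Evaluate final blinded predictions
#'
#' AUC via the Mann-Whitney U identity (ties 0.5) and a two-sided Wilcoxon
#' rank-sum p-value comparing predictions between groups. Constant
#' predictions give AUC 0.5 and p 1 with a warning.
#'
#' @param predictions Numeric vector of per-patient final predictions.
#' @param labels 0/1 labels (1 = case).
#' @return List with `auc` and `p_value`.
#' @export
evaluate_predictions <- function(predictions, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    id_stop("both classes required", "immunodyn_domain_error")
  if (length(unique(predictions)) == 1L) {
    warning("constant predictions: AUC 0.5, p = 1")
    return(list(auc = 0.5, p_value = 1))
  }
  auc <- auc_mann_whitney(predictions, labels)
  pv <- suppressWarnings(
    wilcox.test(predictions[labels == 1L], predictions[labels == 0L],
                alternative = "two.sided")$p.value)
  list(auc = auc, p_value = pv)
}

# mean imputation at modeling time: training rows imputed within their own
# group, test rows with the overall training mean (labels stay blinded)
impute_rates <- function(X_train, y_train, X_test = NULL) {
  for (j in seq_len(ncol(X_train))) {
    miss <- is.na(X_train[, j])
    if (any(miss)) {
      for (g in c(0, 1)) {
        rows <- miss & y_train == g
        if (any(rows)) {
          mu <- mean(X_train[y_train == g, j], na.rm = TRUE)
          if (!is.finite(mu)) mu <- mean(X_train[, j], na.rm = TRUE)
          if (!is.finite(mu)) mu <- 0
          X_train[rows, j] <- mu
        }
      }
    }
    if (!is.null(X_test)) {
      missT <- is.na(X_test[, j])
      if (any(missT)) {
        mu <- mean(X_train[, j], na.rm = TRUE)
        if (!is.finite(mu)) mu <- 0
        X_test[missT, j] <- mu
      }
    }
  }
  list(train = X_train, test = X_test)
}

#' Repeated random-holdout ensemble model
#'
#' The estimation scheme of the predictive analysis: at each iteration a
#' uniform random test set of `n_test` patients is held out, the model is
#' standardized and tuned (penalty by internal cross-validation) on the
#' remaining patients only, and test-set probabilities are recorded. After
#' `n_iterations` draws (default 100, the published scheme for a 23-patient
#' cohort: train on 20, test on 3), extra iterations are appended until every
#' patient has been held out at least once. Each patient's final blinded
#' prediction is the mean of their out-of-sample probabilities; AUC and a
#' two-sided Wilcoxon group-difference p-value are computed from those final
#' predictions only.
#'
#' The model is fitted without an intercept, exactly the `beta' rho` logistic
#' form the study's likelihood is written in. This is not cosmetic: with an
#' unpenalized intercept, a null (all-zero) fit predicts the training-set
#' prevalence, which is systematically lower whenever a case patient is held
#' out, so averaging such predictions anti-ranks cases perfectly and drives
#' the permutation-null AUC to 0 instead of 0.5. Intercept-free null fits
#' predict 1/2 for everyone and are information-free, as they should be.
#'
#' Inside the ensemble the penalty is chosen by the plain deviance minimizer
#' (`rule = "min"`): averaging 100 held-out fits already damps per-fit
#' overfitting, and the conservative one-SE rule (the [select_lambda()]
#' standalone default) collapses too many null-cohort iterations to the empty
#' model, starving both the predictions and the selection-frequency ranking.
#'
#' @param rates A `dynamics_matrix` (or plain patients x features matrix).
#' @param sheet A [sample_sheet()] (ignored if `rates` carries one).
#' @param n_test Held-out patients per iteration.
#' @param n_iterations Planned iterations.
#' @param seed Integer seed; fold seeds and split draws derive from it.
#' @param n_folds,n_lambda,min_ratio,rule Passed to [select_lambda()].
#' @param intercept Fit an unpenalized intercept inside each iteration
#'   (default `FALSE`; see Details).
#' @return A `model_result`.
#' @export
repeated_holdout <- function(rates, sheet = attr(rates, "sheet"), n_test = 3L,
                             n_iterations = 100L, seed = 1L, n_folds = 5L,
                             n_lambda = 100L, min_ratio = 0.01,
                             rule = c("min", "1se"), intercept = FALSE) {
  rule <- match.arg(rule)
  X <- unclass(rates)
  attr(X, "feature_meta") <- NULL
  attr(X, "sheet") <- NULL
  if (is.null(sheet)) id_stop("a sample sheet is required", "immunodyn_config_error")
  stopifnot(nrow(X) == nrow(sheet))
  n <- nrow(X)
  if (n < n_test + 4L)
    id_stop("cohort too small for the requested holdout size", "immunodyn_config_error")
  y <- as.integer(sheet$group == "case")
  p <- ncol(X)
  supports <- list(); lambdas <- numeric(0); test_sets <- list()
  preds <- vector("list", n)
  coef_abs_sum <- numeric(p)  # running sum of |beta| for ranking tie-breaks
  set.seed(seed)
  it <- 0L
  redraws <- 0L
  repeat {
    it <- it + 1L
    covered <- vapply(preds, function(z) length(z) > 0L, logical(1))
    if (it > n_iterations && all(covered)) break
    if (it > n_iterations + 50L * n) break  # safety stop; coverage contract
    test <- sort(sample.int(n, n_test))
    if (length(unique(y[-test])) < 2L) { redraws <- redraws + 1L; it <- it - 1L; next }
    imp <- impute_rates(X[-test, , drop = FALSE], y[-test], X[test, , drop = FALSE])
    sel <- select_lambda(imp$train, y[-test], n_folds = n_folds,
                         seed = derive_seed(seed, it),
                         n_lambda = n_lambda, min_ratio = min_ratio,
                         rule = rule, intercept = intercept)
    fit <- fit_penalized_logistic(imp$train, y[-test], sel$lambda,
                                  intercept = intercept)
    Xt <- apply_standardization(imp$test, fit)
    pr <- predict_fit(fit, Xt)
    for (k in seq_along(test)) preds[[test[k]]] <- c(preds[[test[k]]], pr[k])
    supports[[length(supports) + 1L]] <- fit$beta != 0
    coef_abs_sum <- coef_abs_sum + abs(fit$beta)
    lambdas <- c(lambdas, sel$lambda)
    test_sets[[length(test_sets) + 1L]] <- sheet$patient[test]
  }
  n_done <- length(supports)
  if (n_done > n_iterations)
    id_log("%d coverage top-up iteration(s) appended", n_done - n_iterations)
  final <- vapply(preds, mean, numeric(1))
  ev <- evaluate_predictions(final, y)
  structure(list(
    selection = do.call(rbind, supports),
    lambdas = lambdas,
    test_sets = test_sets,
    predictions = setNames(preds, sheet$patient),
    final_predictions = setNames(final, sheet$patient),
    mean_abs_coef = setNames(coef_abs_sum / n_done, colnames(X)),
    auc = ev$auc, p_value = ev$p_value,
    n_iterations = n_done, n_planned = n_iterations, n_redraws = redraws,
    seed = seed, labels = setNames(y, sheet$patient),
    rates = X, sheet = sheet,
    feature_meta = attr(rates, "feature_meta")),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result: %d iterations (%d planned), AUC %.3f, Wilcoxon p %.3g\n",
              x$n_iterations, x$n_planned, x$auc, x$p_value))
  cat(sprintf("  %d features, median support size %d\n",
              ncol(x$selection), as.integer(median(rowSums(x$selection)))))
  invisible(x)
}
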