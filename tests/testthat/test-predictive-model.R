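test_that("the solver matches the brute-force objective oracle", {
  # 10 random instances here; acceptance runs the full 50
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(100), 20, 5)
    y <- rbinom(20, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 3]))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    lambda <- runif(1, 0.2, 2)
    fit <- fit_penalized_logistic(X, y, lambda)
    Xs <- immunodyn:::standardize_train(X)$X
    oracle <- oracle_lasso_optimum(Xs, y, lambda,
                                   start = c(fit$intercept, fit$beta), seed = s)
    expect_lt(abs(fit$objective - oracle), 1e-5)
  }
})

test_that("lambda at or above lambda_max gives the exact null model", {
  set.seed(11)
  X <- matrix(rnorm(120), 24, 5)
  y <- rep(c(0, 1), c(13, 11))
  lmax <- lambda_max(X, y)
  for (lam in c(lmax, lmax * 1.5, lmax * 10)) {
    fit <- fit_penalized_logistic(X, y, lam)
    expect_identical(unname(fit$beta), rep(0, 5))
    expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-12)
  }
  # just below lambda_max at least one coefficient activates
  fit2 <- fit_penalized_logistic(X, y, lmax * 0.95)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("objective is monotone across solver iterations and warm starts match", {
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10)
  y <- rbinom(20, 1, plogis(X[, 1]))
  fit <- fit_penalized_logistic(X, y, 0.3, keep_trace = TRUE)
  expect_true(all(diff(fit$trace) <= 1e-12))
  # warm-started path equals cold-started single fits
  Xs <- immunodyn:::standardize_train(X)$X
  path <- immunodyn:::lambda_path(lambda_max(X, y), 20, 0.05)
  warm <- immunodyn:::.lasso_logistic_path_cpp(Xs, y, path, 1e-9, 200L, 200L,
                                               FALSE, TRUE)
  for (l in c(1, 7, 14, 20)) {
    cold <- fit_penalized_logistic(X, y, path[l])
    expect_lt(abs(warm$objective[l] - cold$objective), 1e-6)
  }
})

test_that("separable data at lambda = 0 hits the cap but ranks correctly", {
  x <- matrix(seq(-2, 2, length.out = 12), ncol = 1)
  y <- as.integer(x[, 1] > 0)
  fit <- fit_penalized_logistic(x, y, 0, max_outer = 50L, keep_trace = TRUE)
  expect_false(fit$converged)
  expect_true(all(diff(fit$trace) <= 1e-12))  # still monotone
  Xs <- immunodyn:::apply_standardization(x, fit)
  pr <- immunodyn:::predict_fit(fit, Xs)
  expect_true(all(pr[y == 1] > max(pr[y == 0])))
  expect_error(fit_penalized_logistic(x, rep(1, 12), 0.1),
               class = "immunodyn_domain_error")
  xna <- x; xna[1] <- NA
  expect_error(fit_penalized_logistic(xna, y, 0.1),
               class = "immunodyn_domain_error")
})

test_that("cross-validated lambda behaves at the path endpoints and under noise", {
  # deviance at lambda_max equals the held-out null deviance of each fold
  set.seed(5)
  X <- matrix(rnorm(24 * 8), 24, 8)
  y <- rep(c(0, 1), each = 12)
  sel <- select_lambda(X, y, n_folds = 4L, seed = 9L, n_lambda = 30)
  set.seed(9L)
  fold <- immunodyn:::stratified_folds(y, 4L)
  null_dev <- mean(vapply(1:4, function(f) {
    pbar <- mean(y[fold != f])
    immunodyn:::binomial_deviance(y[fold == f], rep(pbar, sum(fold == f)))
  }, numeric(1)))
  expect_equal(sel$cv_deviance[1], null_dev, tolerance = 1e-9)

  # pure noise: selected lambda near lambda_max, support size 0-1 mostly
  small <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(20 * 15), 20, 15)
    yn <- rep(c(0, 1), each = 10)
    sl <- select_lambda(Xn, yn, seed = s, n_lambda = 40)
    fitn <- fit_penalized_logistic(Xn, yn, sl$lambda)
    if (sum(fitn$beta != 0) <= 1) small <- small + 1L
  }
  expect_gte(small / 50, 0.8)

  # one huge effect: that feature selected nearly always
  found <- 0L
  for (s in 1:50) {
    set.seed(2000 + s)
    Xh <- matrix(rnorm(20 * 10), 20, 10)
    yh <- rep(c(0, 1), each = 10)
    Xh[, 4] <- Xh[, 4] * 0.2 + (yh - 0.5) * 3
    sl <- select_lambda(Xh, yh, seed = s, n_lambda = 40)
    fith <- fit_penalized_logistic(Xh, yh, sl$lambda)
    if (fith$beta[4] != 0) found <- found + 1L
  }
  expect_gte(found / 50, 0.95)
})

test_that("prediction evaluation matches exhaustive pair counting", {
  expect_equal(evaluate_predictions(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(evaluate_predictions(c(0.9, 0.4, 0.7, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    v <- c(rnorm(n1), rnorm(n0))
    if (i %% 3 == 0) v <- round(v)  # force ties
    lab <- rep(c(1, 0), c(n1, n0))
    expect_equal(auc_mann_whitney(v, lab), oracle_auc(v, lab))
    # U / (n1 n0) identity against stats::wilcox.test
    u <- suppressWarnings(wilcox.test(v[lab == 1], v[lab == 0]))$statistic
    expect_equal(auc_mann_whitney(v, lab), unname(u) / (n1 * n0))
    # sign reversal maps AUC -> 1 - AUC
    expect_equal(auc_mann_whitney(-v, lab), 1 - auc_mann_whitney(v, lab))
  }
  expect_warning(ev <- evaluate_predictions(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)))
  expect_equal(ev$auc, 0.5)
  expect_equal(ev$p_value, 1)
})

test_that("repeated holdout covers every patient and honours its contracts", {
  design <- cohort_design(n_control = 5, n_case = 5, seed = 17,
                          cell_types = paste0("ct", 1:4),
                          functional_markers = paste0("m", 1:3),
                          conditions = "unstim",
                          planted_effects = list(basal_effect("ct1", "m1", 0.08)),
                          noise_sd = 0.3, n_latent_factors = 0)
  sim <- simulate_feature_matrix(design)
  rates <- compute_rates(sim$t1, sim$t2, sim$sheet)
  # n_iterations = 1: top-up guarantees full coverage anyway
  res1 <- repeated_holdout(rates, n_iterations = 1L, seed = 4L, n_lambda = 30)
  expect_true(all(vapply(res1$predictions, length, integer(1)) >= 1L))
  expect_gt(res1$n_iterations, 1L)
  # all predictions are probabilities; AUC from final predictions only
  res <- repeated_holdout(rates, n_iterations = 15L, seed = 4L, n_lambda = 30)
  expect_true(all(unlist(res$predictions) >= 0 & unlist(res$predictions) <= 1))
  expect_equal(res$auc,
               auc_mann_whitney(res$final_predictions, res$labels))
  # deterministic given the seed
  res_b <- repeated_holdout(rates, n_iterations = 15L, seed = 4L, n_lambda = 30)
  expect_identical(res$final_predictions, res_b$final_predictions)
  expect_identical(res$selection, res_b$selection)
  # cohort too small
  expect_error(repeated_holdout(rates[1:5, ], sim$sheet[1:5, ], n_test = 3L),
               class = "immunodyn_config_error")
})

test_that("zero-noise single planted feature is always in the selected support", {
  for (s in 1:5) {
    design <- cohort_design(n_control = 5, n_case = 5, seed = s,
                            cell_types = paste0("ct", 1:3),
                            functional_markers = paste0("m", 1:3),
                            conditions = "unstim",
                            planted_effects = list(basal_effect("ct1", "m1", 0.05)),
                            noise_sd = 0, n_latent_factors = 0)
    sim <- simulate_feature_matrix(design)
    rates <- compute_rates(sim$t1, sim$t2, sim$sheet)
    X <- unclass(rates); attr(X, "sheet") <- NULL; attr(X, "feature_meta") <- NULL
    y <- as.integer(sim$sheet$group == "case")
    sl <- select_lambda(X, y, seed = s, n_lambda = 40)
    fit <- fit_penalized_logistic(X, y, sl$lambda)
    expect_true(fit$beta["basal|ct1|m1"] != 0)
  }
})
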