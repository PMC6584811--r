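#' Normality-gated two-group comparison of one feature
#'
#' Applies the Shapiro-Wilk test within each group; if both groups look
#' Gaussian (`p >= alpha_normality`) the groups are compared with a two-sample
#' Student t-test, otherwise with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test. The feature's discriminative AUC is always computed (same
#' implementation as the model evaluation). Degenerate input (constant within
#' both groups) returns p = 1 flagged.
#'
#' @param values Numeric feature values.
#' @param labels 0/1 or logical labels (1 = case).
#' @param alpha_normality Gate level for the Shapiro-Wilk test.
#' @return A `feature_test_result` list: `test` ("t-test" or "mann-whitney"),
#'   `statistic`, `p_value`, `auc`, `group_means`, `group_medians`,
#'   `degenerate`.
#' @export
compare_feature <- function(values, labels, alpha_normality = 0.05) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(values)
  values <- values[ok]; labels <- labels[ok]
  g0 <- values[labels == 0L]; g1 <- values[labels == 1L]
  if (length(g0) < 3L || length(g1) < 3L)
    id_stop("need at least 3 observations per group", "immunodyn_domain_error")
  if (length(unique(g0)) == 1L && length(unique(g1)) == 1L &&
      g0[1L] == g1[1L]) {
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p_value = 1, auc = 0.5,
                          group_means = c(control = mean(g0), case = mean(g1)),
                          group_medians = c(control = median(g0), case = median(g1)),
                          degenerate = TRUE),
                     class = "feature_test_result"))
  }
  sw_ok <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)  # constant: not Gaussian
    shapiro.test(v)$p.value >= alpha_normality
  }
  normal <- sw_ok(g0) && sw_ok(g1)
  if (normal) {
    ht <- t.test(g1, g0, var.equal = TRUE)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(g1, g0, alternative = "two.sided"))
    test <- "mann-whitney"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 auc = auc_mann_whitney(values, labels),
                 group_means = c(control = mean(g0), case = mean(g1)),
                 group_medians = c(control = median(g0), case = median(g1)),
                 degenerate = FALSE),
            class = "feature_test_result")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Classical two-sided definition: the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. An empty margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    id_stop("fisher_exact expects a 2x2 table", "immunodyn_config_error")
  if (any(table < 0) || any(table != round(table)))
    id_stop("counts must be non-negative integers", "immunodyn_domain_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Confounder-adjusted association of a feature with case status
#'
#' Ordinary least squares of the feature on case status plus the four
#' comorbidity covariates (BMI, autoimmune disease, chronic hypertension,
#' type 2 diabetes), reporting the Wald p-value for the status coefficient.
#' A rank-deficient design (e.g. a comorbidity present only in cases) is
#' flagged, and any aliased coefficient reported as `NA` with a warning
#' rather than silently dropped.
#'
#' @param values Numeric feature values (one per patient, sheet order).
#' @param sheet A [sample_sheet()] with covariate columns `bmi`,
#'   `autoimmune`, `chronic_htn`, `t2d`.
#' @return A `confounder_result`: coefficient table, `status_coef`,
#'   `status_p`, `r_squared`, `rank_deficient`.
#' @export
confounder_regression <- function(values, sheet) {
  need <- c("bmi", "autoimmune", "chronic_htn", "t2d")
  missing_cov <- setdiff(need, names(sheet))
  if (length(missing_cov))
    id_stop(sprintf("sample sheet lacks covariate(s): %s",
                    paste(missing_cov, collapse = ", ")), "immunodyn_config_error")
  d <- data.frame(y = as.numeric(values),
                  status = as.integer(sheet$group == "case"),
                  bmi = sheet$bmi, autoimmune = sheet$autoimmune,
                  chronic_htn = sheet$chronic_htn, t2d = sheet$t2d)
  if (!all(complete.cases(d[, -1L])))
    id_stop("covariates must be complete for the confounder analysis",
            "immunodyn_validation_error")
  if (nrow(d) <= 6L)
    id_stop("need more observations than predictors + 1", "immunodyn_domain_error")
  fit <- lm(y ~ status + bmi + autoimmune + chronic_htn + t2d, data = d)
  sm <- summary(fit)
  rank_def <- fit$rank < 6L
  if (rank_def)
    warning("rank-deficient confounder design; aliased coefficients are NA")
  co <- coef(sm)
  full <- matrix(NA_real_, 6L, 4L,
                 dimnames = list(c("(Intercept)", "status", "bmi", "autoimmune",
                                   "chronic_htn", "t2d"), colnames(co)))
  full[rownames(co), ] <- co
  structure(list(coefficients = full,
                 status_coef = full["status", "Estimate"],
                 status_p = full["status", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 rank_deficient = rank_def,
                 fit = fit),
            class = "confounder_result")
}

#' Per-feature univariate and confounder analysis over a rate matrix
#'
#' Convenience wrapper running [compare_feature()] (and optionally
#' [confounder_regression()]) for every feature column, with optional
#' Benjamini-Hochberg adjustment. Raw p-values are the default, matching how
#' individual model components are usually reported in this setting.
#'
#' @param rates A `dynamics_matrix` or plain matrix.
#' @param sheet Sample sheet (taken from `rates` if attached).
#' @param confounders Also run the confounder regressions.
#' @param bh_adjust Add Benjamini-Hochberg adjusted p-values.
#' @return `data.frame` with one row per feature.
#' @export
univariate_table <- function(rates, sheet = attr(rates, "sheet"),
                             confounders = FALSE, bh_adjust = FALSE) {
  X <- unclass(rates)
  labels <- as.integer(sheet$group == "case")
  rows <- lapply(colnames(X), function(fid) {
    r <- compare_feature(X[, fid], labels)
    out <- data.frame(feature = fid, test = r$test, statistic = r$statistic,
                      p_value = r$p_value, auc = r$auc,
                      mean_control = r$group_means[["control"]],
                      mean_case = r$group_means[["case"]],
                      stringsAsFactors = FALSE)
    if (confounders) {
      cr <- confounder_regression(X[, fid], sheet)
      out$status_coef <- cr$status_coef
      out$status_p_adjusted_for_confounders <- cr$status_p
      out$rank_deficient <- cr$rank_deficient
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (bh_adjust) tab$p_bh <- stats::p.adjust(tab$p_value, method = "BH")
  rownames(tab) <- NULL
  tab
}

#' Cohort demographic summary
#'
#' Per-group mean +/- SD of continuous covariates (t-test p) and counts of
#' binary comorbidities (Fisher's exact p), mirroring the usual Table-1
#' layout.
#'
#' @param sheet A [sample_sheet()].
#' @return `data.frame` summary.
#' @export
demographic_summary <- function(sheet) {
  grp <- sheet$group
  cont <- intersect(c("ga_t1", "ga_t2", "bmi"), names(sheet))
  bin <- intersect(c("autoimmune", "chronic_htn", "t2d", "gdm"), names(sheet))
  rows <- list()
  for (v in cont) {
    x0 <- sheet[[v]][grp == "control"]; x1 <- sheet[[v]][grp == "case"]
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      control = sprintf("%.1f ± %.1f", mean(x0), sd(x0)),
      case = sprintf("%.1f ± %.1f", mean(x1), sd(x1)),
      p_value = t.test(x1, x0)$p.value, stringsAsFactors = FALSE)
  }
  for (v in bin) {
    tab <- matrix(c(sum(sheet[[v]][grp == "control"] == 1),
                    sum(sheet[[v]][grp == "control"] == 0),
                    sum(sheet[[v]][grp == "case"] == 1),
                    sum(sheet[[v]][grp == "case"] == 0)), 2L)
    rows[[v]] <- data.frame(
      variable = v, type = "binary",
      control = sprintf("%d/%d", tab[1, 1], sum(tab[, 1])),
      case = sprintf("%d/%d", tab[1, 2], sum(tab[, 2])),
      p_value = fisher_exact(tab), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
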