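test_that("design validation names the offending field", {
  expect_error(cohort_design(n_control = 1), "n_control",
               class = "immunodyn_config_error")
  expect_error(cohort_design(ga_t1_mean_sd = c(25, 1), ga_t2_mean_sd = c(11, 1)),
               "ga_t2_mean_sd", class = "immunodyn_config_error")
  expect_error(cohort_design(events_per_sample = 10), "events_per_sample",
               class = "immunodyn_config_error")
  expect_error(
    cohort_design(planted_effects = list(planted_effect("nope", "basal", "pSTAT5"))),
    "nope", class = "immunodyn_config_error")
  expect_error(
    cohort_design(planted_effects = list(planted_effect("Th1", "basal", "mX"))),
    "mX", class = "immunodyn_config_error")
})

test_that("zero-noise designs give exact planted rates and exact zero elsewhere", {
  planted <- list(basal_effect("ct1", "m1", slope = 0.1))
  design <- clean_design(planted = planted, seed = 5L)
  sim <- simulate_feature_matrix(design)
  rates <- compute_rates(sim$t1, sim$t2, sim$sheet)
  fid <- "basal|ct1|m1"
  ctrl <- sim$sheet$group == "control"
  expect_equal(unname(rates[ctrl, fid]), rep(0.1, sum(ctrl)))
  expect_equal(unname(rates[!ctrl, fid]), rep(-0.1, sum(!ctrl)))
  # every non-planted, non-frequency feature has rho exactly 0
  meta <- attr(sim$t1, "feature_meta")
  others <- setdiff(meta$feature[meta$category != "frequency"], fid)
  expect_true(all(rates[, others] == 0))
  # zero-slope design: frequencies constant too
  sim0 <- simulate_feature_matrix(clean_design(seed = 5L))
  rates0 <- compute_rates(sim0$t1, sim0$t2, sim0$sheet)
  expect_true(all(rates0 == 0))
  # truth table records exactly the planted feature
  expect_identical(sim$truth$informative_features, fid)
})

test_that("simulation is bit-identical for a fixed seed", {
  design <- cohort_design(n_control = 3, n_case = 3, seed = 99L,
                          cell_types = paste0("ct", 1:3),
                          functional_markers = paste0("m", 1:2))
  a <- simulate_feature_matrix(design)
  b <- simulate_feature_matrix(design)
  expect_identical(unclass(a$t1), unclass(b$t1))
  expect_identical(unclass(a$t2), unclass(b$t2))
  expect_identical(a$sheet, b$sheet)
  ea <- simulate_event_tables(design)
  eb <- simulate_event_tables(design)
  expect_identical(lapply(ea$events, as.data.frame),
                   lapply(eb$events, as.data.frame))
  # different seed changes the draw
  c <- simulate_feature_matrix(cohort_design(n_control = 3, n_case = 3,
                                             seed = 100L,
                                             cell_types = paste0("ct", 1:3),
                                             functional_markers = paste0("m", 1:2)))
  expect_false(identical(unclass(a$t1), unclass(c$t1)))
})

test_that("latent factors induce stronger within-community correlation", {
  # Monte-Carlo check of the factor-model construction: with loadings dominating
  # noise, same-factor feature pairs out-correlate cross-factor pairs
  diffs <- vapply(1:20, function(s) {
    design <- cohort_design(n_control = 8, n_case = 8, seed = s,
                            cell_types = paste0("ct", 1:4),
                            functional_markers = paste0("m", 1:3),
                            conditions = "unstim",
                            n_latent_factors = 3, factor_loading_sd = 1.5,
                            noise_sd = 0.2)
    sim <- simulate_feature_matrix(design)
    X <- rbind(unclass(sim$t1), unclass(sim$t2))
    meta <- attr(sim$t1, "feature_meta")
    keep <- meta$category == "basal"   # frequencies carry no loading
    X <- X[, keep]
    comm <- sim$truth$community_assignment[keep]
    C <- abs(cor(X, method = "spearman"))
    same <- outer(comm, comm, "==") & upper.tri(C)
    diff <- outer(comm, comm, "!=") & upper.tri(C)
    mean(C[same]) - mean(C[diff])
  }, numeric(1))
  expect_gt(mean(diffs), 0.2)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("event-level cell counts concentrate at the intended proportions", {
  # binomial-concentration oracle: observed subset frequency within +/-0.02 of
  # its intended proportion (~0.25 here) in >= 95% of >= 100 sample draws
  hits <- 0L; total <- 0L
  for (s in 1:13) {
    design <- cohort_design(n_control = 2, n_case = 2, seed = s,
                            cell_types = paste0("ct", 1:4),
                            functional_markers = "m1", conditions = "unstim",
                            events_per_sample = 10000L,
                            n_latent_factors = 0, noise_sd = 0)
    sim <- simulate_event_tables(design)
    intended <- unclass(sim$intended$t1)  # constant across samples here
    target <- intended[1, "freq|ct2"] / 100
    for (ev in sim$events) {
      obs <- mean(ev$cell_type == "ct2")
      hits <- hits + as.integer(abs(obs - target) <= 0.02)
      total <- total + 1L
    }
  }
  expect_gte(total, 100L)
  expect_gte(hits / total, 0.95)
})

test_that("no stimulation response means near-zero stim features", {
  design <- cohort_design(n_control = 2, n_case = 2, seed = 21L,
                          cell_types = paste0("ct", 1:3),
                          functional_markers = paste0("m", 1:2),
                          stim_response_mean = 0, stim_baseline_sd = 0,
                          noise_sd = 0, n_latent_factors = 0,
                          events_per_sample = 4000L)
  sim <- simulate_event_tables(design)
  panel <- panel_config(cell_types = design$cell_types,
                        functional_markers = design$functional_markers,
                        conditions = design$conditions)
  fms <- extract_features(sim$events, panel, sim$sheet)
  meta <- attr(fms$t1, "feature_meta")
  stim_cols <- meta$feature[meta$category == "stim_response"]
  ses <- feature_se_matrices(sim$events, panel, sim$sheet,
                             design$dirichlet_concentration)
  for (tp in c("t1", "t2")) {
    vals <- unclass(fms[[tp]])[, stim_cols, drop = FALSE]
    se <- ses[[tp]][, stim_cols, drop = FALSE]
    ok <- is.finite(vals) & is.finite(se)
    expect_true(all(abs(vals[ok]) < 3 * se[ok]))
  }
})

test_that("cohort artifacts round-trip losslessly through disk", {
  design <- clean_design(planted = list(basal_effect("ct2", "m2", 0.05)),
                         seed = 31L)
  sim <- simulate_feature_matrix(design)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "t1.csv"); p2 <- file.path(td, "sheet.csv")
  p3 <- file.path(td, "truth.json"); p4 <- file.path(td, "rates.csv")
  write_feature_matrix(sim$t1, p1)
  fm1 <- read_feature_matrix(p1)
  expect_identical(unclass(fm1), unclass(sim$t1))
  expect_equal(attr(fm1, "feature_meta"), attr(sim$t1, "feature_meta"))
  write_sample_sheet(sim$sheet, p2)
  expect_equal(read_sample_sheet(p2), sim$sheet, ignore_attr = TRUE)
  write_truth_table(sim$truth, p3)
  tr <- read_truth_table(p3, sheet = sim$sheet)
  expect_identical(tr$informative_features, sim$truth$informative_features)
  expect_equal(tr$slopes, sim$truth$slopes)
  expect_equal(tr$community_assignment, sim$truth$community_assignment)
  rates <- compute_rates(sim$t1, sim$t2, sim$sheet)
  write_dynamics_matrix(rates, p4)
  r2 <- read_dynamics_matrix(p4)
  expect_identical(unclass(r2)[, colnames(rates)], unclass(rates)[, ])
})
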