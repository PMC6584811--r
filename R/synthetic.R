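#' Planted differential-dynamics effect
#'
#' Declares one immune feature whose trajectory differs by group: the feature
#' identified by (category, cell type, marker, condition) changes at
#' `control_slope` units/week in controls and `case_slope` units/week in cases,
#' with an optional additive offset for cases at the first time point
#' (emulating, e.g., a signal that starts higher in cases and then falls while
#' rising in controls).
#'
#' @param cell_type Subset name.
#' @param category One of `"frequency"`, `"basal"`, `"stim_response"`.
#' @param marker Functional marker (not used for frequency features).
#' @param condition Stimulation condition (stim_response features only).
#' @param control_slope,case_slope Feature units per week.
#' @param baseline_shift_case Feature units added for cases at T1.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(cell_type, category, marker = NA_character_,
                           condition = NA_character_,
                           control_slope = 0, case_slope = 0,
                           baseline_shift_case = 0) {
  if (!category %in% c("frequency", "basal", "stim_response"))
    id_stop("category must be frequency, basal or stim_response", "immunodyn_config_error")
  structure(list(cell_type = cell_type, category = category, marker = marker,
                 condition = condition, control_slope = control_slope,
                 case_slope = case_slope,
                 baseline_shift_case = baseline_shift_case),
            class = "planted_effect")
}

#' Synthetic cohort design
#'
#' The stated world of the generator: a two-group (control / case), two
#' time-point, two-condition cohort. Defaults mirror the motivating study:
#' 12 controls and 11 cases sampled at gestational weeks ~11 +/- 1.9 and
#' ~25 +/- 4.1, 21 cell subsets, 11 functional markers, one unstimulated and
#' one stimulated (LPS+IFNa) condition. Feature values follow a latent-factor
#' model: `value = baseline + group/time trend + loading * factor score +
#' Gaussian noise`, so features sharing a latent factor form correlated
#' communities and the planted trends are the only group-informative signal.
#'
#' @param n_control,n_case Patients per group (each >= 2).
#' @param ga_t1_mean_sd,ga_t2_mean_sd `c(mean, sd)` gestational age (weeks) at
#'   the two samplings; draws truncated to `[8, 16]` and `[18, 34]`.
#' @param cell_types,functional_markers,conditions Panel composition.
#' @param planted_effects List of [planted_effect()] objects.
#' @param n_latent_factors Number of latent factors inducing feature
#'   correlation communities; every feature is assigned to one factor.
#' @param factor_loading_sd SD of per-feature factor loadings (feature units).
#' @param noise_sd SD of independent per-observation Gaussian noise (feature
#'   units).
#' @param basal_mean,stim_response_mean Central baseline levels (arcsinh
#'   units) of basal and stimulation-response features; per-feature baselines
#'   are drawn around these.
#' @param basal_baseline_sd,stim_baseline_sd SD of the fixed per-feature
#'   baseline spread around those central levels (zero makes all features of a
#'   category share one baseline exactly).
#' @param events_per_sample Cells per synthetic acquisition (>= 100).
#' @param dirichlet_concentration Concentration of the Dirichlet-multinomial
#'   cell-count sampling (higher = closer to multinomial).
#' @param event_sdlog Log-scale SD of single-cell raw intensities.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_design`.
#' @export
cohort_design <- function(n_control = 12L, n_case = 11L,
                          ga_t1_mean_sd = c(11, 1.9),
                          ga_t2_mean_sd = c(25, 4.1),
                          cell_types = default_cell_types(),
                          functional_markers = default_functional_markers(),
                          conditions = c("unstim", "LPS+IFNa"),
                          planted_effects = list(),
                          n_latent_factors = 6L,
                          factor_loading_sd = 0.5,
                          noise_sd = 0.35,
                          basal_mean = 2.0,
                          stim_response_mean = 0.5,
                          basal_baseline_sd = 0.3,
                          stim_baseline_sd = 0.15,
                          events_per_sample = 5000L,
                          dirichlet_concentration = 5000,
                          event_sdlog = 0.5,
                          seed = 1L) {
  chk <- function(ok, field, why)
    if (!ok) id_stop(sprintf("invalid design field '%s': %s", field, why),
                     "immunodyn_config_error")
  chk(n_control >= 2, "n_control", "need at least 2 control patients")
  chk(n_case >= 2, "n_case", "need at least 2 case patients")
  chk(ga_t2_mean_sd[1] > ga_t1_mean_sd[1], "ga_t2_mean_sd",
      "mean GA at T2 must exceed mean GA at T1")
  chk(events_per_sample >= 100, "events_per_sample", "need at least 100 events")
  chk(n_latent_factors >= 0, "n_latent_factors", "must be non-negative")
  chk(noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(factor_loading_sd >= 0, "factor_loading_sd", "must be non-negative")
  if (inherits(planted_effects, "planted_effect")) planted_effects <- list(planted_effects)
  for (pe in planted_effects) {
    chk(pe$cell_type %in% cell_types, "planted_effects",
        sprintf("cell type '%s' not declared", pe$cell_type))
    if (pe$category != "frequency")
      chk(pe$marker %in% functional_markers, "planted_effects",
          sprintf("marker '%s' not declared", pe$marker))
    if (pe$category == "stim_response")
      chk(pe$condition %in% conditions[-1L], "planted_effects",
          sprintf("condition '%s' not a declared stimulation condition", pe$condition))
  }
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 ga_t1_mean_sd = ga_t1_mean_sd, ga_t2_mean_sd = ga_t2_mean_sd,
                 cell_types = cell_types, functional_markers = functional_markers,
                 conditions = conditions, planted_effects = planted_effects,
                 n_latent_factors = as.integer(n_latent_factors),
                 factor_loading_sd = factor_loading_sd, noise_sd = noise_sd,
                 basal_mean = basal_mean, stim_response_mean = stim_response_mean,
                 basal_baseline_sd = basal_baseline_sd,
                 stim_baseline_sd = stim_baseline_sd,
                 events_per_sample = as.integer(events_per_sample),
                 dirichlet_concentration = dirichlet_concentration,
                 event_sdlog = event_sdlog, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Expected rate-of-change noise SD for a null feature
#'
#' Analytic SD of the per-patient rate `rho` for a feature with zero planted
#' slope: both time points carry independent noise plus a latent-factor
#' contribution with loading SD `factor_loading_sd`, and the difference is
#' divided by the mean GA gap. Used to express planted effect sizes in noise
#' units.
#'
#' @param design A [cohort_design()].
#' @return SD of `rho` (feature units per week).
#' @export
rate_noise_sd <- function(design) {
  lat <- if (design$n_latent_factors > 0) design$factor_loading_sd^2 else 0
  sqrt(2 * (design$noise_sd^2 + lat)) /
    (design$ga_t2_mean_sd[1] - design$ga_t1_mean_sd[1])
}

#' Default discriminative planted effects
#'
#' Eight cell-specific effects patterned on the known immunology of
#' preeclampsia-discriminating dynamics: basal STAT5 signaling rising in
#' controls but falling in cases in Th1 cells (with a higher case level at
#' T1), STAT5/STAT1/NF-kB basal activity decelerating in myeloid subsets
#' (mDCs, intermediate and classical monocytes), and stimulation-response
#' dynamics in naive CD4 T cells, TCRgd T cells and Tregs.
#' The slope gap between groups is `delta` for every effect.
#'
#' @param design A [cohort_design()] (declares the available names).
#' @param delta Absolute control-vs-case slope difference (feature units per
#'   week); default 3x [rate_noise_sd()] of the design.
#' @return List of eight [planted_effect()]s.
#' @export
default_planted_effects <- function(design, delta = 3 * rate_noise_sd(design)) {
  stim <- design$conditions[2L]
  h <- delta / 2
  list(
    planted_effect("Th1", "basal", "pSTAT5", control_slope = h, case_slope = -h,
                   baseline_shift_case = 0.3),
    planted_effect("Tregs", "basal", "pSTAT5", control_slope = h, case_slope = -h),
    planted_effect("intMC", "basal", "pSTAT1", control_slope = h, case_slope = -h,
                   baseline_shift_case = 0.3),
    planted_effect("mDC", "basal", "pSTAT5", control_slope = h, case_slope = -h,
                   baseline_shift_case = 0.3),
    planted_effect("cMC", "basal", "pNFkB", control_slope = h, case_slope = -h,
                   baseline_shift_case = 0.3),
    planted_effect("cMC", "basal", "pSTAT1", control_slope = h, case_slope = -h),
    planted_effect("CD4+Tnaive", "stim_response", "pMAPKAPK2", stim,
                   control_slope = h, case_slope = -h),
    planted_effect("TCRgd T", "stim_response", "pP38", stim,
                   control_slope = h, case_slope = -h)
  )
}

design_panel <- function(design) {
  panel_config(cell_types = design$cell_types,
               functional_markers = design$functional_markers,
               conditions = design$conditions)
}

# deterministic (per design seed) feature-level generative parameters:
# baselines, latent-factor assignment, loadings, per-group slopes, case shift
feature_model <- function(design) {
  panel <- design_panel(design)
  meta <- panel_feature_meta(panel)
  p <- nrow(meta)
  K <- length(design$cell_types)
  set.seed(derive_seed(design$seed, 101L))
  # frequency baselines: fixed decreasing subset abundances summing to 100%
  w <- exp(-0.12 * seq_len(K))
  w <- 100 * w / sum(w)
  baseline <- numeric(p)
  baseline[meta$category == "frequency"] <- w
  nb <- sum(meta$category == "basal")
  baseline[meta$category == "basal"] <-
    design$basal_mean + rnorm(nb, 0, design$basal_baseline_sd)
  ns <- sum(meta$category == "stim_response")
  baseline[meta$category == "stim_response"] <-
    design$stim_response_mean + rnorm(ns, 0, design$stim_baseline_sd)
  community <- if (design$n_latent_factors > 0)
    (seq_len(p) - 1L) %% design$n_latent_factors + 1L else rep(0L, p)
  loading <- if (design$n_latent_factors > 0)
    rnorm(p, 0, design$factor_loading_sd) else rep(0, p)
  # frequency features get no latent loading: keeps percentages in range and
  # the compositional renormalization honest
  loading[meta$category == "frequency"] <- 0
  ctrl_slope <- numeric(p)
  case_slope <- numeric(p)
  shift_case <- numeric(p)
  for (pe in design$planted_effects) {
    fid <- feature_id(pe$category, pe$cell_type, pe$marker, pe$condition)
    j <- match(fid, meta$feature)
    if (is.na(j)) id_stop(sprintf("planted effect targets excluded feature %s", fid),
                          "immunodyn_config_error")
    ctrl_slope[j] <- pe$control_slope
    case_slope[j] <- pe$case_slope
    shift_case[j] <- pe$baseline_shift_case
  }
  list(panel = panel, meta = meta, baseline = baseline, community = community,
       loading = loading, ctrl_slope = ctrl_slope, case_slope = case_slope,
       shift_case = shift_case)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

simulate_sheet <- function(design) {
  set.seed(derive_seed(design$seed, 202L))
  n <- design$n_control + design$n_case
  patient <- sprintf("P%02d", seq_len(n))
  group <- c(rep("control", design$n_control), rep("case", design$n_case))
  ga1 <- rtrunc_norm(n, design$ga_t1_mean_sd[1], design$ga_t1_mean_sd[2], 8, 16)
  ga2 <- rtrunc_norm(n, design$ga_t2_mean_sd[1], design$ga_t2_mean_sd[2], 18, 34)
  ga2 <- pmax(ga2, ga1 + 2)  # keep T2 strictly after T1
  # covariates for the confounder analysis: BMI higher in cases, comorbidity
  # flags concentrated in the case group (as in the emulated cohort)
  bmi <- rnorm(n, ifelse(group == "case", 29.4, 24.5), 5)
  covs <- data.frame(
    bmi = round(bmi, 1),
    autoimmune = as.integer(group == "case" & runif(n) < 3 / 11),
    chronic_htn = as.integer(group == "case" & runif(n) < 2 / 11),
    t2d = as.integer(group == "case" & runif(n) < 2 / 11),
    gdm = as.integer(runif(n) < 1 / 12))
  sample_sheet(patient, group, ga1, ga2, covs)
}

# intended feature values for every (patient, timepoint): the latent-factor +
# trend model; noise optionally included
intended_values <- function(design, fmod, sheet, with_noise = TRUE) {
  p <- nrow(fmod$meta)
  n <- nrow(sheet)
  anchor <- design$ga_t1_mean_sd[1]
  is_case <- sheet$group == "case"
  vals <- list()
  set.seed(derive_seed(design$seed, 303L))
  for (tp in c("T1", "T2")) {
    ga <- if (tp == "T1") sheet$ga_t1 else sheet$ga_t2
    u <- if (design$n_latent_factors > 0)
      matrix(rnorm(n * design$n_latent_factors), n, design$n_latent_factors)
    else matrix(0, n, 1L)
    slope <- outer(is_case, fmod$case_slope) + outer(!is_case, fmod$ctrl_slope)
    v <- matrix(fmod$baseline, n, p, byrow = TRUE) +
      outer(as.numeric(is_case), fmod$shift_case) +
      slope * (ga - anchor)
    if (design$n_latent_factors > 0)
      v <- v + u[, fmod$community, drop = FALSE] *
        matrix(fmod$loading, n, p, byrow = TRUE)
    if (with_noise && design$noise_sd > 0)
      v <- v + matrix(rnorm(n * p, 0, design$noise_sd), n, p)
    # frequencies are percentages of a disjoint partition: clamp and renormalize
    fq <- fmod$meta$category == "frequency"
    vf <- v[, fq, drop = FALSE]
    vf <- pmax(vf, 0.05)
    vf <- 100 * vf / rowSums(vf)
    v[, fq] <- vf
    dimnames(v) <- list(sheet$patient, fmod$meta$feature)
    vals[[tp]] <- v
  }
  vals
}

truth_table <- function(design, fmod, sheet) {
  informative <- fmod$meta$feature[fmod$ctrl_slope != fmod$case_slope]
  structure(list(
    informative_features = informative,
    slopes = data.frame(feature = fmod$meta$feature,
                        control_slope = fmod$ctrl_slope,
                        case_slope = fmod$case_slope,
                        baseline_shift_case = fmod$shift_case,
                        stringsAsFactors = FALSE),
    community_assignment = setNames(fmod$community, fmod$meta$feature),
    sheet = sheet,
    seed = design$seed), class = "truth_table")
}

#' Simulate a feature-level synthetic cohort
#'
#' Draws the samples x features matrices at both time points directly from the
#' latent-factor feature model (no event-level sampling), together with the
#' sample sheet and a truth table recording exactly which features carry
#' group-differential slopes and which latent factor (correlation community)
#' each feature belongs to. Deterministic for a fixed design seed.
#'
#' @param design A [cohort_design()].
#' @return List with elements `t1`, `t2` (`feature_matrix`), `sheet`
#'   ([sample_sheet()]) and `truth` (`truth_table`).
#' @export
simulate_feature_matrix <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  fmod <- feature_model(design)
  sheet <- simulate_sheet(design)
  vals <- intended_values(design, fmod, sheet, with_noise = TRUE)
  list(t1 = feature_matrix(vals$T1, fmod$meta, "T1"),
       t2 = feature_matrix(vals$T2, fmod$meta, "T2"),
       sheet = sheet,
       truth = truth_table(design, fmod, sheet))
}

#' Simulate event-level synthetic cytometry tables
#'
#' Generates one labeled event table per (patient, timepoint, condition).
#' Cell-type counts follow a Dirichlet-multinomial around the sample's
#' intended subset percentages; single-cell raw intensities are lognormal on
#' the linear scale, with the log-mean calibrated numerically so that the
#' expected arcsinh-transformed intensity equals the intended feature-level
#' mean (basal mean for the reference condition; basal + stimulation response
#' for stimulated conditions). Running [extract_features()] on the output
#' therefore recovers the intended feature matrix up to sampling error.
#'
#' @param design A [cohort_design()].
#' @return List with `events` (list of [event_table()]), `sheet`, `truth`, and
#'   `intended` (list of `t1`/`t2` intended `feature_matrix` objects).
#' @export
simulate_event_tables <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  fmod <- feature_model(design)
  panel <- fmod$panel
  sheet <- simulate_sheet(design)
  vals <- intended_values(design, fmod, sheet, with_noise = TRUE)
  meta <- fmod$meta
  cof <- panel$arcsinh_cofactor
  inv <- meanlog_calibrator(design$event_sdlog, cof)
  K <- length(design$cell_types)
  stim_conditions <- setdiff(design$conditions, panel$reference_condition)
  events <- list()
  warned_rare <- FALSE
  for (i in seq_len(nrow(sheet))) {
    pid <- sheet$patient[i]
    for (tp in c("T1", "T2")) {
      v <- vals[[tp]][i, ]
      props <- v[meta$category == "frequency"] / 100
      # per (cell type, marker) arcsinh-scale target means
      basal_target <- matrix(v[meta$category == "basal"], nrow = K)
      dimnames(basal_target) <- list(design$cell_types, design$functional_markers)
      for (ci in seq_along(design$conditions)) {
        cond <- design$conditions[ci]
        target <- basal_target
        if (cond != panel$reference_condition) {
          sm <- meta$category == "stim_response" & meta$condition == cond
          if (any(sm)) {
            idx <- cbind(match(meta$cell_type[sm], design$cell_types),
                         match(meta$marker[sm], design$functional_markers))
            target[idx] <- target[idx] + v[sm]
          }
        }
        set.seed(derive_seed(design$seed, 404L, i, match(tp, c("T1", "T2")), ci))
        alpha <- design$dirichlet_concentration * props
        g <- rgamma(K, shape = alpha, rate = 1)
        pr <- if (sum(g) > 0) g / sum(g) else props
        counts <- as.integer(rmultinom(1L, design$events_per_sample, pr))
        if (any(counts == 0L) && !warned_rare) {
          warning("events_per_sample too small to represent all subsets: ",
                  "rare subsets absent from some samples")
          warned_rare <- TRUE
        }
        lab <- rep(design$cell_types, counts)
        raw <- matrix(NA_real_, length(lab), length(design$functional_markers),
                      dimnames = list(NULL, design$functional_markers))
        offset <- c(0L, cumsum(counts))
        for (k in seq_len(K)) {
          if (counts[k] == 0L) next
          rows <- (offset[k] + 1L):offset[k + 1L]
          mlog <- inv(pmax(target[k, ], 1e-3))
          raw[rows, ] <- exp(matrix(rnorm(counts[k] * ncol(raw), 0,
                                          design$event_sdlog),
                                    counts[k]) +
                             matrix(mlog, counts[k], ncol(raw), byrow = TRUE))
        }
        events[[length(events) + 1L]] <-
          event_table(data.frame(cell_type = lab, raw, check.names = FALSE),
                      pid, tp, cond, transformed = FALSE)
      }
    }
  }
  list(events = events, sheet = sheet,
       truth = truth_table(design, fmod, sheet),
       intended = list(t1 = feature_matrix(vals$T1, meta, "T1"),
                       t2 = feature_matrix(vals$T2, meta, "T2")))
}

# For X ~ lognormal(mu, sdlog), E[asinh(X/cof)] is strictly increasing in mu.
# Build the inverse map target-mean -> mu once (Gauss-Hermite quadrature on a
# dense mu grid + monotone interpolation); error << sampling SE.
meanlog_calibrator <- function(sdlog, cof) {
  gh <- gauss_hermite(40L)
  mu_grid <- seq(-12, 10, length.out = 1500L)
  fwd <- vapply(mu_grid, function(mu)
    sum(gh$w * asinh(exp(mu + sqrt(2) * sdlog * gh$x) / cof)) / sqrt(pi),
    numeric(1))
  stats::approxfun(fwd, mu_grid, rule = 2)
}

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' convention)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}
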