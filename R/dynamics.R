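#' Cohort sample sheet
#'
#' Patient-level metadata: group label, gestational age (weeks) at the two
#' sampling time points, and optional covariates used by the confounder
#' analysis (BMI and binary flags for autoimmune disease, chronic
#' hypertension, type 2 diabetes, gestational diabetes).
#'
#' @param patient Character vector of patient ids (unique).
#' @param group Factor or character, `"control"` / `"case"`.
#' @param ga_t1,ga_t2 Gestational ages in weeks; `ga_t2 > ga_t1` per patient.
#' @param covariates Optional `data.frame` with columns among `bmi`,
#'   `autoimmune`, `chronic_htn`, `t2d`, `gdm`.
#' @return A `sample_sheet` data.frame.
#' @export
sample_sheet <- function(patient, group, ga_t1, ga_t2, covariates = NULL) {
  patient <- as.character(patient)
  group <- as.character(group)
  if (anyDuplicated(patient))
    id_stop("duplicated patient ids in sample sheet", "immunodyn_config_error")
  if (!all(group %in% c("control", "case")))
    id_stop("group labels must be 'control' or 'case'", "immunodyn_config_error")
  bad <- which(!(ga_t2 > ga_t1))
  if (length(bad))
    id_stop(sprintf("GA_T2 must exceed GA_T1; violated for patient(s): %s",
                    paste(patient[bad], collapse = ", ")), "immunodyn_validation_error")
  sheet <- data.frame(patient = patient, group = group,
                      ga_t1 = as.numeric(ga_t1), ga_t2 = as.numeric(ga_t2),
                      stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    sheet <- cbind(sheet, covariates)
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Rate of change of each immune feature
#'
#' Parametrizes each feature's trajectory between the two sampling time points
#' as a per-week difference quotient:
#' `rho = (value_T2 - value_T1) / (GA_T2 - GA_T1)`.
#' Only patients present in both matrices are used; a feature missing at
#' either time point gives a missing rate.
#'
#' @param fm_t1,fm_t2 `feature_matrix` objects sharing columns.
#' @param sheet A [sample_sheet()] providing the gestational ages.
#' @return A `dynamics_matrix`: patients x features matrix of rates
#'   (feature units per week) with `feature_meta` and `sheet` attributes.
#' @export
compute_rates <- function(fm_t1, fm_t2, sheet) {
  if (!identical(colnames(fm_t1), colnames(fm_t2)))
    id_stop("feature matrices at T1 and T2 have different columns", "immunodyn_config_error")
  bad_ga <- which(!(sheet$ga_t2 > sheet$ga_t1))
  if (length(bad_ga))
    id_stop(sprintf("GA_T2 <= GA_T1 for patient(s): %s",
                    paste(sheet$patient[bad_ga], collapse = ", ")),
            "immunodyn_validation_error")
  present <- sheet$patient %in% rownames(fm_t1) & sheet$patient %in% rownames(fm_t2)
  if (!all(present)) {
    warning(sprintf("dropping patient(s) missing a time point: %s",
                    paste(sheet$patient[!present], collapse = ", ")))
    sheet <- sheet[present, , drop = FALSE]
  }
  v1 <- unclass(fm_t1)[sheet$patient, , drop = FALSE]
  v2 <- unclass(fm_t2)[sheet$patient, , drop = FALSE]
  dt <- sheet$ga_t2 - sheet$ga_t1
  rho <- sweep(v2 - v1, 1L, dt, "/")
  structure(rho,
            feature_meta = attr(fm_t1, "feature_meta"),
            sheet = sheet,
            class = c("dynamics_matrix", class(rho)))
}

#' @export
print.dynamics_matrix <- function(x, ...) {
  sheet <- attr(x, "sheet")
  cat(sprintf("dynamics_matrix: %d patients (%d control / %d case) x %d feature rates\n",
              nrow(x), sum(sheet$group == "control"), sum(sheet$group == "case"),
              ncol(x)))
  invisible(x)
}
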