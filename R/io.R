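# full-precision CSV writing so that re-loading round-trips losslessly and
# repeated runs are byte-identical
fmt17 <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_csv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write / read a feature matrix
#'
#' CSV (patients x features, full precision) plus a JSON metadata sidecar
#' (`<path>.meta.json`) holding the per-feature metadata and timepoint.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `write_feature_matrix`: the path, invisibly.
#'   `read_feature_matrix`: the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv17(df, path)
  jsonlite::write_json(list(timepoint = attr(fm, "timepoint"),
                            feature_meta = attr(fm, "feature_meta")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_js <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  meta <- as.data.frame(meta_js$feature_meta, stringsAsFactors = FALSE)
  for (col in c("marker", "condition"))
    meta[[col]][vapply(meta[[col]], is.null, logical(1))] <- NA_character_
  meta$marker <- as.character(meta$marker)
  meta$condition <- as.character(meta$condition)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$patient
  feature_matrix(m, meta, meta_js$timepoint)
}

#' Write / read a sample sheet
#'
#' @param sheet A [sample_sheet()].
#' @param path CSV path.
#' @return The path / the `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_csv17(as.data.frame(sheet), path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  covs <- df[, setdiff(names(df), c("patient", "group", "ga_t1", "ga_t2")),
             drop = FALSE]
  sample_sheet(df$patient, df$group, df$ga_t1, df$ga_t2,
               if (ncol(covs)) covs else NULL)
}

#' Write / read a synthetic truth table
#'
#' JSON serialization of the generator's ground truth (informative features,
#' per-group true slopes, community assignment, seed). The sample sheet
#' travels separately as CSV.
#'
#' @param truth A `truth_table`.
#' @param path JSON path.
#' @return The path / the reconstructed `truth_table` (sans sheet unless
#'   `sheet` is supplied).
#' @export
write_truth_table <- function(truth, path) {
  jsonlite::write_json(list(informative_features = truth$informative_features,
                            slopes = truth$slopes,
                            community_assignment =
                              as.list(truth$community_assignment),
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_table
#' @param sheet Optional [sample_sheet()] to re-attach.
#' @export
read_truth_table <- function(path, sheet = NULL) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(informative_features = as.character(js$informative_features),
                 slopes = as.data.frame(js$slopes, stringsAsFactors = FALSE),
                 community_assignment = unlist(js$community_assignment),
                 sheet = sheet, seed = js$seed),
            class = "truth_table")
}

#' Write / read a dynamics matrix
#'
#' @param rates A `dynamics_matrix`.
#' @param path CSV path (sheet is stored alongside as `<path>.sheet.csv`).
#' @return The path / the `dynamics_matrix`.
#' @export
write_dynamics_matrix <- function(rates, path) {
  df <- data.frame(patient = rownames(rates), as.data.frame(unclass(rates)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv17(df, path)
  write_sample_sheet(attr(rates, "sheet"), paste0(path, ".sheet.csv"))
  invisible(path)
}

#' @rdname write_dynamics_matrix
#' @export
read_dynamics_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sheet <- read_sample_sheet(paste0(path, ".sheet.csv"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$patient
  structure(m, sheet = sheet, class = c("dynamics_matrix", class(m)))
}

#' Write cohort event tables as one long CSV
#'
#' One row per cell: `patient`, `timepoint`, `condition`, `cell_type`, then
#' one column per marker (raw intensities).
#'
#' @param events List of [event_table()]s.
#' @param path CSV path.
#' @return The path / the list of `event_table`s.
#' @export
write_event_tables <- function(events, path) {
  blocks <- lapply(events, function(ev)
    data.frame(patient = attr(ev, "patient"), timepoint = attr(ev, "timepoint"),
               condition = attr(ev, "condition"), as.data.frame(ev),
               check.names = FALSE, stringsAsFactors = FALSE))
  write_csv17(do.call(rbind, blocks), path)
  invisible(path)
}

#' @rdname write_event_tables
#' @export
read_event_tables <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  keys <- unique(df[, c("patient", "timepoint", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$patient == keys$patient[i] & df$timepoint == keys$timepoint[i] &
                df$condition == keys$condition[i], , drop = FALSE]
    event_table(sub[, setdiff(names(sub), c("patient", "timepoint", "condition")),
                    drop = FALSE],
                keys$patient[i], keys$timepoint[i], keys$condition[i])
  })
}

#' Serialize a model result to JSON + CSV summary
#'
#' @param result A `model_result`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_model_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- file.path(dir, "model_result.json")
  jsonlite::write_json(
    list(auc = result$auc, p_value = result$p_value,
         n_iterations = result$n_iterations, n_planned = result$n_planned,
         seed = result$seed, lambdas = result$lambdas,
         test_sets = result$test_sets,
         final_predictions = as.list(result$final_predictions),
         selection_frequencies = as.list(colMeans(result$selection))),
    js, auto_unbox = TRUE, digits = NA)
  cs <- file.path(dir, "predictions.csv")
  write_csv17(data.frame(patient = names(result$final_predictions),
                         group = ifelse(result$labels == 1L, "case", "control"),
                         final_prediction = as.numeric(result$final_predictions),
                         n_holdouts = vapply(result$predictions, length,
                                             integer(1)),
                         stringsAsFactors = FALSE), cs)
  invisible(c(json = js, csv = cs))
}

#' Serialize a selection profile
#'
#' @param profile A `selection_profile`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_selection_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- file.path(dir, "selection_profile.csv")
  write_csv17(profile$table, cs)
  js <- file.path(dir, "selection_summary.json")
  jsonlite::write_json(list(breakpoint = profile$breakpoint,
                            top_features = profile$top_features,
                            no_shift = profile$no_shift),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = cs, json = js))
}
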