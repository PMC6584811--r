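#' arcsinh transform for cytometry intensities
#'
#' The standard variance-stabilizing transform for mass cytometry,
#' `asinh(x / cofactor)`. Raw ion counts are non-negative; negative input is a
#' domain error rather than silently transformed.
#'
#' @param x Numeric vector of non-negative raw intensities.
#' @param cofactor Positive scale factor (default 5, the mass cytometry
#'   convention).
#' @return Transformed numeric vector.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0)
    id_stop("cofactor must be a single positive number", "immunodyn_config_error")
  if (any(x < 0, na.rm = TRUE))
    id_stop("negative intensities are outside the transform domain", "immunodyn_domain_error")
  asinh(x / cofactor)
}

#' Construct a single-sample event table
#'
#' One row per cell for one (patient, timepoint, condition) acquisition, with a
#' `cell_type` label column and one numeric column per functional marker.
#' Raw vs transformed state is carried explicitly so downstream code never
#' double-transforms.
#'
#' @param cells `data.frame` with a `cell_type` column plus marker columns.
#' @param patient,timepoint,condition Sample key. `timepoint` is `"T1"` or `"T2"`.
#' @param transformed Logical; `TRUE` if marker columns are already on the
#'   arcsinh scale.
#' @return An `event_table` (a `data.frame` with sample-key attributes).
#' @export
event_table <- function(cells, patient, timepoint, condition, transformed = FALSE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!"cell_type" %in% names(cells))
    id_stop("event table needs a cell_type column", "immunodyn_config_error")
  if (!timepoint %in% c("T1", "T2"))
    id_stop("timepoint must be 'T1' or 'T2'", "immunodyn_config_error")
  marker_cols <- setdiff(names(cells), "cell_type")
  if (!transformed) {
    for (m in marker_cols) {
      if (any(cells[[m]] < 0, na.rm = TRUE))
        id_stop(sprintf("negative raw intensities in marker '%s' (%s %s %s)",
                        m, patient, timepoint, condition), "immunodyn_domain_error")
    }
  }
  structure(cells,
            patient = as.character(patient),
            timepoint = as.character(timepoint),
            condition = as.character(condition),
            transformed = isTRUE(transformed),
            class = c("event_table", "data.frame"))
}

event_key <- function(ev) {
  paste(attr(ev, "patient"), attr(ev, "timepoint"), sep = "_")
}

# marker columns on the arcsinh scale, given the panel cofactor
transformed_markers <- function(ev, panel, markers) {
  unknown <- setdiff(markers, names(ev))
  if (length(unknown))
    id_stop(sprintf("marker(s) not present in event table: %s",
                    paste(unknown, collapse = ", ")), "immunodyn_config_error")
  vals <- as.matrix(as.data.frame(ev)[, markers, drop = FALSE])
  if (!isTRUE(attr(ev, "transformed"))) {
    vals <- arcsinh_transform(vals, panel$arcsinh_cofactor)
  }
  vals
}

#' Cell frequency features for one sample
#'
#' Frequency of each declared subset as a percentage of all labeled live
#' mononuclear cells in the table (cells labeled `"unassigned"` are excluded
#' from the denominator). Subsets with no events get 0.
#'
#' @param events An [event_table()].
#' @param panel A [panel_config()].
#' @return Named numeric vector, one percentage in `[0, 100]` per cell type.
#' @export
compute_frequencies <- function(events, panel) {
  labels <- events$cell_type
  labels <- labels[labels != "unassigned"]
  total <- length(labels)
  if (total == 0L)
    id_stop(sprintf("no labeled cells in sample %s/%s/%s",
                    attr(events, "patient"), attr(events, "timepoint"),
                    attr(events, "condition")), "immunodyn_domain_error")
  counts <- table(factor(labels, levels = panel$cell_types))
  setNames(100 * as.numeric(counts) / total, panel$cell_types)
}

#' Basal signaling features for one sample
#'
#' Per (cell type, marker): the mean of arcsinh-transformed single-cell
#' intensities in the unstimulated sample. Subsets with fewer than
#' `panel$min_cells` events yield `NA` (flagged missing, not computed from
#' unstable tiny counts).
#'
#' @param events_unstim [event_table()] from the reference condition.
#' @param panel A [panel_config()].
#' @return Named numeric vector over `cell_type x marker`, names are canonical
#'   feature ids.
#' @export
compute_basal_signaling <- function(events_unstim, panel) {
  if (attr(events_unstim, "condition") != panel$reference_condition)
    id_stop("basal signaling requires events from the reference (unstimulated) condition",
            "immunodyn_pairing_error")
  subset_marker_means(events_unstim, panel, "basal", condition = NA_character_)
}

# shared worker: mean transformed intensity per (cell_type, marker)
subset_marker_means <- function(ev, panel, category, condition) {
  vals <- transformed_markers(ev, panel, panel$functional_markers)
  ct <- factor(ev$cell_type, levels = panel$cell_types)
  out <- numeric(0)
  nms <- character(0)
  for (m in panel$functional_markers) {
    mu <- tapply(vals[, m], ct, mean)
    n <- tabulate(ct, nbins = length(panel$cell_types))
    mu[n < panel$min_cells] <- NA_real_
    out <- c(out, as.numeric(mu))
    nms <- c(nms, if (category == "basal")
      paste("basal", panel$cell_types, m, sep = "|")
    else paste("stim", condition, panel$cell_types, m, sep = "|"))
  }
  setNames(out, nms)
}

#' Stimulation response features for one sample pair
#'
#' Per included (cell type, marker, condition): the arcsinh difference
#' ("arcsinh ratio") — mean transformed intensity in the stimulated sample
#' minus mean transformed intensity in the paired unstimulated sample.
#' Triples in the panel's exclusion mask are omitted.
#'
#' @param events_stim Stimulated [event_table()].
#' @param events_unstim Paired unstimulated [event_table()]; must share
#'   patient and timepoint with `events_stim`.
#' @param panel A [panel_config()].
#' @return Named numeric vector over included stim triples.
#' @export
compute_stim_response <- function(events_stim, events_unstim, panel) {
  if (attr(events_stim, "patient") != attr(events_unstim, "patient") ||
      attr(events_stim, "timepoint") != attr(events_unstim, "timepoint"))
    id_stop("stimulated and unstimulated tables are from different samples",
            "immunodyn_pairing_error")
  cond <- attr(events_stim, "condition")
  if (!cond %in% setdiff(panel$conditions, panel$reference_condition))
    id_stop(sprintf("'%s' is not a declared stimulation condition", cond),
            "immunodyn_config_error")
  stim_mu <- subset_marker_means(events_stim, panel, "stim", cond)
  base_mu <- subset_marker_means(events_unstim, panel, "basal", NA_character_)
  triples <- included_stim_triples(panel)
  triples <- triples[triples$condition == cond, , drop = FALSE]
  ids <- feature_id("stim_response", triples$cell_type, triples$marker,
                    triples$condition)
  stim_key <- paste("stim", cond, triples$cell_type, triples$marker, sep = "|")
  base_key <- paste("basal", triples$cell_type, triples$marker, sep = "|")
  setNames(stim_mu[stim_key] - base_mu[base_key], ids)
}

#' Assemble the immune feature matrix for a cohort
#'
#' Converts a collection of labeled event tables into the samples x features
#' matrix of the three feature categories: cell frequencies (percent of live
#' mononuclear cells), basal signaling (mean arcsinh intensity, unstimulated),
#' and stimulation responses (arcsinh difference stim - unstim). With the
#' default 21-subset / 11-marker panel and one stimulation condition the full
#' column count is 21 + 231 + 231 = 483; the exclusion mask reduces it.
#'
#' @param events List of [event_table()] objects covering the cohort; every
#'   sample in `sample_sheet` must have an unstimulated table at each
#'   timepoint.
#' @param panel A [panel_config()].
#' @param sample_sheet A [sample_sheet()].
#' @return A named list of two `feature_matrix` objects (`t1`, `t2`), each a
#'   numeric matrix (rows = patients, in sheet order) with a `feature_meta`
#'   attribute.
#' @export
extract_features <- function(events, panel, sample_sheet) {
  meta <- panel_feature_meta(panel)
  stopifnot(inherits(sample_sheet, "sample_sheet"))
  index <- vapply(events, function(ev)
    paste(attr(ev, "patient"), attr(ev, "timepoint"), attr(ev, "condition"),
          sep = "\r"), character(1))
  get_table <- function(patient, timepoint, condition) {
    hit <- which(index == paste(patient, timepoint, condition, sep = "\r"))
    if (length(hit) == 0L) return(NULL)
    events[[hit[[1L]]]]
  }
  build_tp <- function(tp) {
    rows <- lapply(sample_sheet$patient, function(pid) {
      unstim <- get_table(pid, tp, panel$reference_condition)
      if (is.null(unstim))
        id_stop(sprintf("missing unstimulated table for patient %s at %s", pid, tp),
                "immunodyn_pairing_error")
      vals <- rep(NA_real_, nrow(meta))
      names(vals) <- meta$feature
      fq <- compute_frequencies(unstim, panel)
      vals[feature_id("frequency", names(fq))] <- fq
      bs <- compute_basal_signaling(unstim, panel)
      vals[names(bs)] <- bs
      for (cond in setdiff(panel$conditions, panel$reference_condition)) {
        stim <- get_table(pid, tp, cond)
        if (is.null(stim)) next
        sr <- compute_stim_response(stim, unstim, panel)
        vals[names(sr)] <- sr
      }
      vals
    })
    m <- do.call(rbind, rows)
    if (is.null(m)) m <- matrix(numeric(0), nrow = 0L, ncol = nrow(meta))
    rownames(m) <- sample_sheet$patient
    colnames(m) <- meta$feature
    feature_matrix(m, meta, timepoint = tp)
  }
  list(t1 = build_tp("T1"), t2 = build_tp("T2"))
}

#' Feature matrix container
#'
#' A plain numeric matrix (rows = patients for one timepoint, columns =
#' features) carrying a `feature_meta` data.frame (`feature`, `category`,
#' `cell_type`, `marker`, `condition`) and the timepoint.
#'
#' @param values Numeric matrix; `colnames` must equal `meta$feature`.
#' @param meta Feature metadata `data.frame`.
#' @param timepoint `"T1"` or `"T2"`.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, meta, timepoint) {
  values <- as.matrix(values)
  if (!identical(colnames(values), meta$feature))
    id_stop("feature matrix columns do not match metadata", "immunodyn_config_error")
  fq <- values[, meta$category == "frequency", drop = FALSE]
  if (length(fq) && any(stats::na.omit(c(fq)) < 0 | stats::na.omit(c(fq)) > 100))
    id_stop("frequency features must lie in [0, 100]", "immunodyn_domain_error")
  structure(values, feature_meta = meta, timepoint = timepoint,
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  meta <- attr(x, "feature_meta")
  cat(sprintf("feature_matrix [%s]: %d samples x %d features (%d frequency, %d basal, %d stim response)\n",
              attr(x, "timepoint"), nrow(x), ncol(x),
              sum(meta$category == "frequency"), sum(meta$category == "basal"),
              sum(meta$category == "stim_response")))
  invisible(x)
}
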