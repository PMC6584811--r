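#' Default immune cell subsets
#'
#' The 21 PBMC subsets profiled by the assay: major lymphoid populations
#' (B, NK and NK subsets, CD4/CD8 T cells and their memory, naive, Th1,
#' Treg and Tbet+ compartments, TCRgd T cells) and myeloid populations
#' (classical, non-classical and intermediate monocytes, M-MDSCs, and
#' myeloid/plasmacytoid dendritic cells).
#'
#' @return Character vector of 21 subset names.
#' @export
default_cell_types <- function() {
  c("B cells", "NK", "CD56hiCD16- NK", "CD56loCD16+ NK",
    "CD4+T", "CD4+Tmem", "CD4+Tnaive", "Th1", "Tregs",
    "CD8+T", "CD8+Tmem", "CD8+Tnaive", "CD8+Tbet+CD45RA-", "CD8+Tbet+CD45RA+",
    "TCRgd T", "cMC", "ncMC", "intMC", "M-MDSC", "mDC", "pDC")
}

#' Default functional markers
#'
#' Ten phospho-epitopes read out per cell plus total IkB (measured to track
#' IkB degradation downstream of NF-kB activation).
#'
#' @return Character vector of 11 marker names.
#' @export
default_functional_markers <- function() {
  c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6", "pNFkB",
    "pMAPKAPK2", "pP38", "prpS6", "pERK1/2", "pCREB", "IkB")
}

#' Panel / gating configuration
#'
#' Describes the analysis panel: which cell subsets and functional markers are
#' quantified, the stimulation conditions (one of which is the unstimulated
#' reference), which (cell type, marker, condition) triples are excluded from
#' stimulation-response features, and the arcsinh cofactor.
#'
#' @param cell_types Character vector of subset names.
#' @param functional_markers Character vector of functional marker names.
#' @param conditions Character vector of condition names; the first entry (or
#'   `reference_condition`) is the unstimulated reference.
#' @param reference_condition Name of the unstimulated condition.
#' @param exclusion_mask `data.frame` with columns `cell_type`, `marker`,
#'   `condition`: stim-response triples dropped from the feature set. Default
#'   empty. The assay's own mask (non-responding combinations) is supplied by
#'   the user; it is a config input, not a constant.
#' @param arcsinh_cofactor Positive scale factor of the arcsinh transform.
#' @param min_cells Minimum number of events in a subset for its signaling
#'   features to be computed; below this the value is flagged missing.
#'
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(cell_types = default_cell_types(),
                         functional_markers = default_functional_markers(),
                         conditions = c("unstim", "LPS+IFNa"),
                         reference_condition = conditions[[1L]],
                         exclusion_mask = NULL,
                         arcsinh_cofactor = 5,
                         min_cells = 3L) {
  if (!is.numeric(arcsinh_cofactor) || length(arcsinh_cofactor) != 1L ||
      !is.finite(arcsinh_cofactor) || arcsinh_cofactor <= 0)
    id_stop("arcsinh_cofactor must be a single positive number", "immunodyn_config_error")
  if (!reference_condition %in% conditions)
    id_stop("reference_condition must be one of `conditions`", "immunodyn_config_error")
  if (anyDuplicated(cell_types)) id_stop("duplicated cell_types", "immunodyn_config_error")
  if (anyDuplicated(functional_markers)) id_stop("duplicated functional_markers", "immunodyn_config_error")
  if (is.null(exclusion_mask)) {
    exclusion_mask <- data.frame(cell_type = character(), marker = character(),
                                 condition = character(), stringsAsFactors = FALSE)
  } else {
    exclusion_mask <- as.data.frame(exclusion_mask, stringsAsFactors = FALSE)
    need <- c("cell_type", "marker", "condition")
    if (!all(need %in% names(exclusion_mask)))
      id_stop("exclusion_mask needs columns cell_type, marker, condition", "immunodyn_config_error")
    exclusion_mask <- exclusion_mask[, need]
    bad <- !(exclusion_mask$cell_type %in% cell_types) |
      !(exclusion_mask$marker %in% functional_markers) |
      !(exclusion_mask$condition %in% setdiff(conditions, reference_condition))
    if (any(bad))
      id_stop(sprintf("exclusion_mask row(s) %s reference undeclared cell type/marker/condition",
                      paste(which(bad), collapse = ", ")), "immunodyn_config_error")
  }
  structure(list(cell_types = cell_types,
                 functional_markers = functional_markers,
                 conditions = conditions,
                 reference_condition = reference_condition,
                 exclusion_mask = exclusion_mask,
                 arcsinh_cofactor = arcsinh_cofactor,
                 min_cells = as.integer(min_cells)),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("panel_config:", length(x$cell_types), "cell types,",
      length(x$functional_markers), "functional markers\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "),
      sprintf("(reference: %s)\n", x$reference_condition))
  cat("  exclusion mask:", nrow(x$exclusion_mask), "triples; arcsinh cofactor",
      x$arcsinh_cofactor, "\n")
  invisible(x)
}

# full set of (cell_type, marker, condition) stim triples after the mask
included_stim_triples <- function(panel) {
  stim_conditions <- setdiff(panel$conditions, panel$reference_condition)
  if (length(stim_conditions) == 0L)
    return(data.frame(cell_type = character(), marker = character(),
                      condition = character(), stringsAsFactors = FALSE))
  grid <- expand.grid(cell_type = panel$cell_types,
                      marker = panel$functional_markers,
                      condition = stim_conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(panel$exclusion_mask)) {
    key <- function(d) paste(d$cell_type, d$marker, d$condition, sep = "\r")
    grid <- grid[!(key(grid) %in% key(panel$exclusion_mask)), , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

# canonical feature ids; markers/subsets may contain any characters, the id
# separator "|" is reserved
feature_id <- function(category, cell_type, marker = NA_character_,
                       condition = NA_character_) {
  switch(category,
         frequency = paste("freq", cell_type, sep = "|"),
         basal = paste("basal", cell_type, marker, sep = "|"),
         stim_response = paste("stim", condition, cell_type, marker, sep = "|"),
         id_stop(paste("unknown feature category:", category), "immunodyn_config_error"))
}

# feature metadata table for a panel: one row per feature column, in canonical
# order (frequencies, then basal, then included stim triples)
panel_feature_meta <- function(panel) {
  freq <- data.frame(category = "frequency", cell_type = panel$cell_types,
                     marker = NA_character_, condition = NA_character_,
                     stringsAsFactors = FALSE)
  basal <- expand.grid(cell_type = panel$cell_types,
                       marker = panel$functional_markers,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  basal <- data.frame(category = "basal", cell_type = basal$cell_type,
                      marker = basal$marker, condition = NA_character_,
                      stringsAsFactors = FALSE)
  stim <- included_stim_triples(panel)
  stim <- if (nrow(stim))
    data.frame(category = "stim_response", cell_type = stim$cell_type,
               marker = stim$marker, condition = stim$condition,
               stringsAsFactors = FALSE)
  else
    data.frame(category = character(), cell_type = character(),
               marker = character(), condition = character(),
               stringsAsFactors = FALSE)
  meta <- rbind(freq, basal, stim)
  meta$feature <- mapply(feature_id, meta$category, meta$cell_type,
                         meta$marker, meta$condition, USE.NAMES = FALSE)
  rownames(meta) <- NULL
  meta[, c("feature", "category", "cell_type", "marker", "condition")]
}
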