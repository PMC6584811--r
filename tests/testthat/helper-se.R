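# per-sample, per-feature standard errors of extracted features, computed from
# the event tables themselves; used to test extraction against the generator's
# intended means at a 3-4 SE level
feature_se_matrices <- function(events, panel, sheet, dirichlet_conc = Inf) {
  meta <- panel_feature_meta(panel)
  out <- list()
  key <- function(ev) paste(attr(ev, "patient"), attr(ev, "timepoint"),
                            attr(ev, "condition"), sep = "\r")
  index <- vapply(events, key, character(1))
  get_ev <- function(pid, tp, cond)
    events[[which(index == paste(pid, tp, cond, sep = "\r"))[1]]]
  for (tp in c("T1", "T2")) {
    se <- matrix(NA_real_, nrow(sheet), nrow(meta),
                 dimnames = list(sheet$patient, meta$feature))
    for (pid in sheet$patient) {
      unstim <- get_ev(pid, tp, panel$reference_condition)
      N <- nrow(unstim)
      dm_factor <- if (is.finite(dirichlet_conc))
        1 + (N - 1) / (dirichlet_conc + 1) else 1
      tvals <- asinh(as.matrix(as.data.frame(unstim)[panel$functional_markers]) /
                       panel$arcsinh_cofactor)
      ct <- factor(unstim$cell_type, levels = panel$cell_types)
      n_ct <- tabulate(ct, nbins = length(panel$cell_types))
      names(n_ct) <- panel$cell_types
      for (k in seq_along(panel$cell_types)) {
        ctn <- panel$cell_types[k]
        ph <- n_ct[k] / N
        se[pid, paste0("freq|", ctn)] <-
          100 * sqrt(max(ph * (1 - ph), 1 / N) / N * dm_factor)
        if (n_ct[k] >= 2) {
          for (m in panel$functional_markers) {
            se[pid, paste("basal", ctn, m, sep = "|")] <-
              sd(tvals[ct == ctn, m]) / sqrt(n_ct[k])
          }
        }
      }
      for (cond in setdiff(panel$conditions, panel$reference_condition)) {
        stim <- get_ev(pid, tp, cond)
        svals <- asinh(as.matrix(as.data.frame(stim)[panel$functional_markers]) /
                         panel$arcsinh_cofactor)
        sct <- factor(stim$cell_type, levels = panel$cell_types)
        sn <- tabulate(sct, nbins = length(panel$cell_types))
        names(sn) <- panel$cell_types
        for (k in seq_along(panel$cell_types)) {
          ctn <- panel$cell_types[k]
          if (sn[k] < 2 || n_ct[k] < 2) next
          for (m in panel$functional_markers) {
            fid <- paste("stim", cond, ctn, m, sep = "|")
            if (!fid %in% meta$feature) next
            se[pid, fid] <- sqrt(var(svals[sct == ctn, m]) / sn[k] +
                                   var(tvals[ct == ctn, m]) / n_ct[k])
          }
        }
      }
    }
    out[[tolower(paste0("t", substr(tp, 2, 2)))]] <- se
  }
  out
}
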