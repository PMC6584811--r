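# shared small cohort designs for tests

# deterministic design: no noise, no latent structure
clean_design <- function(..., planted = list(), seed = 1L) {
  cohort_design(n_control = 4L, n_case = 4L,
                cell_types = paste0("ct", 1:4),
                functional_markers = paste0("m", 1:3),
                planted_effects = planted,
                n_latent_factors = 0L, factor_loading_sd = 0,
                noise_sd = 0, seed = seed, ...)
}

# p-feature panel with no stimulation condition: n_ct + n_ct*n_m features
flat_design <- function(n_ct, n_m, ..., seed = 1L) {
  cohort_design(cell_types = paste0("ct", seq_len(n_ct)),
                functional_markers = paste0("m", seq_len(n_m)),
                conditions = "unstim", seed = seed, ...)
}

basal_effect <- function(ct, m, slope, shift = 0) {
  planted_effect(ct, "basal", m, control_slope = slope, case_slope = -slope,
                 baseline_shift_case = shift)
}
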