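# Small cohort configurations reused across tests.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_normal = 12, n_tumor = 12, n_mets = 8, n_matched_pairs = 4,
               n_mirna = 30, n_mrna = 20, n_negctrl = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# tumor-only cohort for survival work
survival_config <- function(n_tumor = 80, betas = numeric(0),
                            censoring = 0.2, noise_sd = 1, seed = 1, ...) {
  args <- list(n_normal = 0, n_tumor = n_tumor, n_mets = 0,
               n_matched_pairs = 0, n_mirna = max(2, length(betas)),
               n_mrna = 2, noise_sd = noise_sd,
               baseline_log2_range = c(8, 8),
               survival = list(betas = betas, baseline_hazard = 0.01,
                               censoring_fraction = censoring),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

tumor_log2 <- function(cohort) {
  tum <- cohort$samples$tissue == "tumor"
  log2(cohort$mirna_counts[, tum, drop = FALSE] + 1)
}
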