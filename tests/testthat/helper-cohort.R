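# Shared small synthetic cohort, built once per test run.
.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synthetic_config(n_patients = 3, n_cells_per_sample = 300, seed = 101L)
    .fixtures$small <- generate_cohort(cfg)
  }
  .fixtures$small
}

# identity-calibration, noise-free cohort for exact-recovery checks
clean_cohort <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- synthetic_config(
      n_patients = 2, n_cells_per_sample = 5000,
      capture_efficiency_range = c(1, 1), technical_sd = 0,
      flow_noise_sd = 0, bead_curve = c(slope = 1, intercept = 0),
      seed = 202L)
    .fixtures$clean <- generate_cohort(cfg)
  }
  .fixtures$clean
}

toy_adt <- function(counts, isotypes = character(), ...) {
  adt_sample("toy", counts, isotype_controls = isotypes, ...)
}
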