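#' Configuration of the synthetic paired-cohort generator
#'
#' Defines the study conditions for a simulated cohort of paired
#' diagnosis/relapse bone-marrow samples with matched CITE-seq and
#' bead-calibrated flow readouts, known per-cell ground-truth antigen
#' counts, blast lineage compositions, and survival. Defaults describe a
#' cohort whose antigen abundances span roughly 200 to 10,000 molecules
#' per cell, the range quantitative flow work in AML reports for
#' established myeloid targets.
#'
#' @param n_patients Number of patients; each contributes a diagnosis and
#'   a relapse sample.
#' @param n_cells_per_sample Cells per sample (both modalities).
#' @param antigen_panel Antigen names; must contain the bridge antigens.
#' @param bridge_antigens Antigens measured by quantitative flow as well
#'   as CITE-seq (at least 4 for leave-one-antigen-out validation).
#' @param n_isotype_controls Isotype-control antibodies in the panel.
#' @param abc_log10_mean_range Interval for the per-(sample, antigen)
#'   mean of true log10 ABC (default `log10(c(200, 10000))`).
#' @param abc_log10_sd Per-cell SD of true log10 ABC around the
#'   sample-antigen mean.
#' @param capture_efficiency_range Interval in `(0, 1]` for the
#'   sample-level ADT capture efficiency.
#' @param nb_dispersion Negative-binomial size parameter of ADT counts.
#' @param technical_sd SD (log scale) of the per-cell lognormal technical
#'   factor multiplying all antibody means of a cell, isotypes included.
#' @param background_mean Mean ambient/isotype background count at capture
#'   efficiency 1.
#' @param n_empty_droplets Empty droplets emitted per sample for
#'   background estimation.
#' @param qc_noise_sd Noise of the antibody-library QC metrics, as a
#'   fraction of each metric's dependence on capture efficiency.
#' @param flow_noise_sd SD (log scale) of multiplicative lognormal noise
#'   on flow fluorescence.
#' @param bead_curve Length-2 numeric `c(slope, intercept)` of the true
#'   calibration `log10(ABC) = slope * log10(MFI) + intercept`.
#' @param fmo_abc ABC level at which the simulated FMO gate sits.
#' @param n_lineage_states Number of blast lineage states (default 9).
#' @param composition_alpha Symmetric Dirichlet parameter of diagnosis
#'   compositions.
#' @param shift_magnitude_range Interval of true diagnosis-to-relapse
#'   Aitchison shifts (per patient, uniform).
#' @param hazard_coefficient Log-hazard per unit true Aitchison distance
#'   (negative = protective shift).
#' @param baseline_log_hazard Baseline log hazard (per month).
#' @param censor_horizon Administrative censoring time, months.
#' @param lsc_fraction Fraction of flow events labeled as the CD34+CD38-
#'   LSC-enriched gate.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 10,
                             n_cells_per_sample = 2000,
                             antigen_panel = default_antigen_panel(),
                             bridge_antigens = c("CD33", "CLL-1", "CD123", "ADGRE2"),
                             n_isotype_controls = 3,
                             abc_log10_mean_range = log10(c(200, 10000)),
                             abc_log10_sd = 0.25,
                             capture_efficiency_range = c(0.2, 1),
                             nb_dispersion = 10,
                             technical_sd = 0.3,
                             background_mean = 5,
                             n_empty_droplets = 500,
                             qc_noise_sd = 0.05,
                             flow_noise_sd = 0.1,
                             bead_curve = c(slope = 1, intercept = 0.3),
                             fmo_abc = 150,
                             n_lineage_states = 9,
                             composition_alpha = 1,
                             shift_magnitude_range = c(0, 2),
                             hazard_coefficient = -0.6,
                             baseline_log_hazard = log(1 / 36),
                             censor_horizon = 60,
                             lsc_fraction = 0.2,
                             seed = 1L) {
  cfg <- list(n_patients = n_patients, n_cells_per_sample = n_cells_per_sample,
              antigen_panel = antigen_panel, bridge_antigens = bridge_antigens,
              n_isotype_controls = n_isotype_controls,
              abc_log10_mean_range = abc_log10_mean_range,
              abc_log10_sd = abc_log10_sd,
              capture_efficiency_range = capture_efficiency_range,
              nb_dispersion = nb_dispersion, technical_sd = technical_sd,
              background_mean = background_mean,
              n_empty_droplets = n_empty_droplets,
              qc_noise_sd = qc_noise_sd, flow_noise_sd = flow_noise_sd,
              bead_curve = unname(bead_curve), fmo_abc = fmo_abc,
              n_lineage_states = n_lineage_states,
              composition_alpha = composition_alpha,
              shift_magnitude_range = shift_magnitude_range,
              hazard_coefficient = hazard_coefficient,
              baseline_log_hazard = baseline_log_hazard,
              censor_horizon = censor_horizon, lsc_fraction = lsc_fraction,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Default 12-antigen panel (4 bridge antigens + 8 additional targets)
#' @return Character vector.
#' @export
default_antigen_panel <- function() {
  c("CD33", "CLL-1", "CD123", "ADGRE2",
    "LAIR1", "ITGA4", "DEC-205", "CD244", "CD34", "CD38", "IL1RAP", "CD117")
}

validate_synthetic_config <- function(cfg) {
  for (f in c("n_patients", "n_cells_per_sample", "n_isotype_controls",
              "n_lineage_states", "n_empty_droplets")) {
    assert_positive_scalar(cfg[[f]], f)
  }
  assert_positive_scalar(cfg$abc_log10_sd, "abc_log10_sd")
  assert_positive_scalar(cfg$qc_noise_sd, "qc_noise_sd")
  assert_range(cfg$abc_log10_mean_range, "abc_log10_mean_range")
  assert_range(cfg$capture_efficiency_range, "capture_efficiency_range",
               lower = 1e-12, upper = 1)
  assert_range(cfg$shift_magnitude_range, "shift_magnitude_range", lower = 0)
  if (!all(cfg$bridge_antigens %in% cfg$antigen_panel)) {
    stop("bridge antigens must be part of the antigen panel", call. = FALSE)
  }
  if (length(cfg$bridge_antigens) < 2L) {
    stop("need at least 2 bridge antigens", call. = FALSE)
  }
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

clr_vec <- function(p) log(p) - mean(log(p))
inv_clr <- function(z) { e <- exp(z - max(z)); e / sum(e) }

#' Simulate paired lineage compositions and survival only
#'
#' The composition/outcome slice of the generator, usable on its own for
#' survival power studies where the antigen modalities are not needed.
#' Diagnosis compositions are Dirichlet draws; the relapse composition is
#' the diagnosis composition moved a patient-specific distance along a
#' random direction in centered-log-ratio space, so the true Aitchison
#' shift equals that distance exactly. Survival is exponential with
#' log-hazard `baseline + hazard_coefficient * true_shift`, with
#' administrative censoring at the configured horizon.
#'
#' @param config A [synthetic_config()].
#' @return List with `patients` (data.frame: patient_id, sex, os_time,
#'   event, time_to_relapse, relapse_event, true_shift), `pairs` (list of
#'   per-patient diagnosis/relapse label vectors and true frequency
#'   vectors), and `states`.
#' @export
simulate_composition_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "composition"))
  states <- if (config$n_lineage_states == 9L) lineage_states() else
    sprintf("state-%02d", seq_len(config$n_lineage_states))
  n <- config$n_patients
  pairs <- vector("list", n)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%02d", i)
    p_diag <- rdirichlet1(rep(config$composition_alpha, length(states)))
    # floor tiny frequencies so every state stays representable
    p_diag <- pmax(p_diag, 1e-4); p_diag <- p_diag / sum(p_diag)
    delta <- runif(1, config$shift_magnitude_range[1],
                   config$shift_magnitude_range[2])
    u <- rnorm(length(states)); u <- u - mean(u)
    u <- if (sqrt(sum(u^2)) < 1e-12) rep(0, length(states)) else u / sqrt(sum(u^2))
    p_rel <- inv_clr(clr_vec(p_diag) + delta * u)
    names(p_diag) <- names(p_rel) <- states
    nc <- config$n_cells_per_sample
    diag_labels <- sample(states, nc, replace = TRUE, prob = p_diag)
    rel_labels <- sample(states, nc, replace = TRUE, prob = p_rel)
    loghaz <- config$baseline_log_hazard + config$hazard_coefficient * delta
    t_death <- rexp(1, rate = exp(loghaz))
    t_rel <- rexp(1, rate = 2 * exp(loghaz))
    horizon <- config$censor_horizon
    pts[[i]] <- data.frame(
      patient_id = pid, sex = rbinom(1, 1, 0.5),
      os_time = min(t_death, horizon), event = as.integer(t_death <= horizon),
      time_to_relapse = min(t_rel, horizon),
      relapse_event = as.integer(t_rel <= horizon),
      true_shift = delta, stringsAsFactors = FALSE)
    pairs[[i]] <- list(patient_id = pid, diag_freq = p_diag, relapse_freq = p_rel,
                       diag_labels = diag_labels, relapse_labels = rel_labels)
  }
  list(patients = do.call(rbind, pts), pairs = pairs, states = states)
}

# deterministic links between capture efficiency and the 13 library QC
# metrics: intercept + slope * efficiency, plus Gaussian noise scaled by
# qc_noise_sd * |slope|; percentages are clipped to [0, 100]
qc_metric_model <- function() {
  data.frame(
    metric = qc_metric_names(),
    intercept = c(2e8, 2000, 90, 40, 92, 88, 90, 85, 60, 5, 8, 50, 500),
    slope = c(2e8, 4000, 8, 30, 5, 8, 6, 10, 25, -4, -6, 30, 3000),
    is_pct = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

simulate_qc_metrics <- function(efficiency, noise_sd) {
  m <- qc_metric_model()
  v <- m$intercept + m$slope * efficiency +
    rnorm(nrow(m), 0, noise_sd * abs(m$slope))
  v[m$is_pct] <- pmin(100, pmax(0, v[m$is_pct]))
  v[!m$is_pct] <- pmax(0, v[!m$is_pct])
  setNames(v, m$metric)
}

#' Generate a full synthetic paired cohort
#'
#' For every patient and timepoint the generator draws per-cell true
#' antigen counts (log10 ABC normal around a uniform sample-antigen mean),
#' then emits: (i) a CITE-seq ADT count matrix — negative-binomial counts
#' whose mean is true ABC times a sample capture efficiency times a
#' per-cell lognormal technical factor — with isotype-control columns and
#' ambient empty droplets drawn from a shared low background; (ii) flow
#' cytometry events per bridge antigen, obtained by pushing an independent
#' aliquot's true ABC through the inverse bead calibration curve with
#' multiplicative lognormal noise; (iii) library QC metrics that are noisy
#' deterministic functions of the capture efficiency; (iv) blast lineage
#' labels; and (v) per-patient survival tied to the true compositional
#' shift. One bead standard is shared by the flow batch.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: list with `config`,
#'   `bead_standard`, `curve` (the true calibration), `samples` (named
#'   list, one per patient-timepoint), `patients` and `states`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  comp <- simulate_composition_cohort(config)
  set.seed(derive_seed(config$seed, "modalities"))

  curve <- structure(list(slope = config$bead_curve[1],
                          intercept = config$bead_curve[2], r_squared = 1),
                     class = "standard_curve")
  pe <- c(500, 5000, 24000, 62000)  # typical 4-population PE bead lot
  beads <- bead_standard(pe, abc_to_fluorescence(pe, curve))

  antigens <- config$antigen_panel
  isotypes <- sprintf("IgG-isotype-%d", seq_len(config$n_isotype_controls))
  nc <- config$n_cells_per_sample
  samples <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- comp$patients$patient_id[i]
    for (tp in c("diagnosis", "relapse")) {
      sid <- paste0(pid, "_", tp)
      eff <- runif(1, config$capture_efficiency_range[1],
                   config$capture_efficiency_range[2])
      mu_sa <- runif(length(antigens), config$abc_log10_mean_range[1],
                     config$abc_log10_mean_range[2])
      truth <- 10^(matrix(rnorm(nc * length(antigens),
                                mean = rep(mu_sa, each = nc),
                                sd = config$abc_log10_sd),
                          nrow = nc, dimnames = list(NULL, antigens)))
      tech <- if (config$technical_sd > 0) {
        rlnorm(nc, 0, config$technical_sd)
      } else rep(1, nc)
      adt_mean <- truth * eff * tech
      counts <- matrix(rnbinom(length(adt_mean), mu = adt_mean,
                               size = config$nb_dispersion),
                       nrow = nc, dimnames = list(NULL, antigens))
      iso_counts <- matrix(rnbinom(nc * length(isotypes),
                                   mu = config$background_mean * eff *
                                     rep(tech, length(isotypes)),
                                   size = config$nb_dispersion),
                           nrow = nc, dimnames = list(NULL, isotypes))
      all_counts <- cbind(counts, iso_counts)
      rownames(all_counts) <- sprintf("%s-cell-%05d", sid, seq_len(nc))
      empty <- matrix(rnbinom(config$n_empty_droplets * ncol(all_counts),
                              mu = config$background_mean * eff,
                              size = config$nb_dispersion),
                      nrow = config$n_empty_droplets,
                      dimnames = list(NULL, colnames(all_counts)))
      cell_qc <- data.frame(
        total_counts = round(rlnorm(nc, log(5000), 0.4)),
        detected_features = round(rlnorm(nc, log(1500), 0.3)),
        mito_fraction = rbeta(nc, 2, 28))
      adt <- adt_sample(sid, all_counts, isotype_controls = isotypes,
                        cell_qc = cell_qc,
                        qc_metrics = simulate_qc_metrics(eff, config$qc_noise_sd),
                        empty_droplets = empty)

      flow <- list()
      fmo_thr <- abc_to_fluorescence(config$fmo_abc, curve)
      gate <- ifelse(runif(nc) < config$lsc_fraction, "lsc", "blast")
      for (a in config$bridge_antigens) {
        # separate flow aliquot: same true distribution, independent cells
        abc_flow <- 10^rnorm(nc, mu_sa[match(a, antigens)], config$abc_log10_sd)
        intens <- abc_to_fluorescence(abc_flow, curve)
        if (config$flow_noise_sd > 0) {
          intens <- intens * rlnorm(nc, 0, config$flow_noise_sd)
        }
        flow[[a]] <- flow_sample(sid, a, intens, gate = gate,
                                 fmo_threshold = fmo_thr)
      }
      labels <- if (tp == "diagnosis") comp$pairs[[i]]$diag_labels else
        comp$pairs[[i]]$relapse_labels
      samples[[sid]] <- list(sample_id = sid, patient_id = pid, timepoint = tp,
                             adt = adt, truth = truth, flow = flow,
                             lineage = labels, capture_efficiency = eff,
                             abc_log10_mean = setNames(mu_sa, antigens))
    }
  }
  structure(list(config = config, bead_standard = beads, curve = curve,
                 samples = samples, patients = comp$patients,
                 pairs = comp$pairs, states = comp$states),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic paired cohort: %d patients x 2 timepoints, %d cells/sample, %d antigens (%d bridge)\n",
              x$config$n_patients, x$config$n_cells_per_sample,
              length(x$config$antigen_panel), length(x$config$bridge_antigens)))
  invisible(x)
}

#' Simulate a minimal expression matrix for module-score testing
#'
#' Log-normal gene means with Gaussian per-cell noise; just enough
#' structure for average-expression binning and control-gene sampling.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param gene_mean_log_sd SD of log gene means.
#' @param noise_sd Per-cell noise SD.
#' @param seed Integer seed.
#' @return Matrix cells x genes, genes named `gene-001`...
#' @export
simulate_expression <- function(n_cells = 500, n_genes = 200,
                                gene_mean_log_sd = 0.5, noise_sd = 0.3,
                                seed = 1) {
  set.seed(derive_seed(seed, "expression"))
  means <- rlnorm(n_genes, meanlog = 0, sdlog = gene_mean_log_sd)
  mat <- matrix(rnorm(n_cells * n_genes, mean = rep(means, each = n_cells),
                      sd = noise_sd), nrow = n_cells)
  colnames(mat) <- sprintf("gene-%03d", seq_len(n_genes))
  rownames(mat) <- sprintf("cell-%04d", seq_len(n_cells))
  mat
}

#' Write a synthetic cohort to disk
#'
#' One directory per sample holding the ADT matrix as Matrix Market plus
#' barcode/feature TSVs (isotype controls flagged), flow events and QC
#' metrics and truth matrices as CSV, lineage labels as CSV; plus a bead
#' standard CSV, a patient survival CSV and a JSON manifest.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bead_standard(cohort$bead_standard, file.path(dir, "bead_standard.csv"))
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  for (s in cohort$samples) {
    sdir <- file.path(dir, s$sample_id)
    write_adt_sample(s$adt, sdir)
    write.csv(data.frame(cell = rownames(s$adt$counts), s$truth,
                         check.names = FALSE),
              file.path(sdir, "truth_abc.csv"), row.names = FALSE)
    fl <- do.call(rbind, lapply(s$flow, function(f) {
      data.frame(cell_id = seq_along(f$intensities), antigen = f$antigen,
                 fluorescence = f$intensities, gate = f$gate,
                 fmo_threshold = f$fmo_threshold)
    }))
    write.csv(fl, file.path(sdir, "flow_events.csv"), row.names = FALSE)
    write.csv(data.frame(cell = rownames(s$adt$counts), state = s$lineage),
              file.path(sdir, "lineage_labels.csv"), row.names = FALSE)
  }
  manifest <- list(
    n_patients = cohort$config$n_patients,
    n_cells_per_sample = cohort$config$n_cells_per_sample,
    antigen_panel = cohort$config$antigen_panel,
    bridge_antigens = cohort$config$bridge_antigens,
    seed = cohort$config$seed,
    samples = names(cohort$samples))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
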