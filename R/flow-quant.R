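#' Bead standard for quantitative flow cytometry
#'
#' A calibration standard (e.g. BD QuantiBRITE PE beads) consists of several
#' bead populations with a lot-specified number of PE molecules per bead and
#' a measured geometric mean fluorescence intensity (gMFI) for each
#' population. The standard defines the fluorescence-to-molecule calibration
#' curve for a flow batch.
#'
#' @param pe_per_bead Numeric vector of known PE molecules per bead
#'   population (lot values), strictly positive.
#' @param gmfi Numeric vector of measured geometric mean fluorescence
#'   intensities, same length, strictly positive.
#' @return An object of class `bead_standard`.
#' @export
bead_standard <- function(pe_per_bead, gmfi) {
  if (length(pe_per_bead) != length(gmfi)) {
    stop("pe_per_bead and gmfi must have the same length", call. = FALSE)
  }
  if (length(pe_per_bead) < 2L) {
    stop("a bead standard needs at least 2 bead populations", call. = FALSE)
  }
  if (any(pe_per_bead <= 0) || any(gmfi <= 0)) {
    stop("bead standard values must be strictly positive", call. = FALSE)
  }
  ord <- order(pe_per_bead)
  if (is.unsorted(gmfi[ord])) {
    warning("bead gMFI is not monotone in PE per bead; check the standard")
  }
  structure(list(pe_per_bead = as.numeric(pe_per_bead),
                 gmfi = as.numeric(gmfi)),
            class = "bead_standard")
}

#' Fit a bead calibration standard curve
#'
#' Ordinary least squares of `log10(pe_per_bead)` on `log10(gmfi)`, the
#' standard QuantiBRITE protocol regression. The fitted curve maps a
#' fluorescence intensity to antibodies bound per cell (ABC):
#' `log10(ABC) = slope * log10(MFI) + intercept`.
#'
#' @param beads A [bead_standard()].
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept` and `r_squared`.
#' @export
fit_standard_curve <- function(beads) {
  if (!inherits(beads, "bead_standard")) beads <- do.call(bead_standard, beads)
  fit <- lm(y ~ x, data = data.frame(x = log10(beads$gmfi),
                                     y = log10(beads$pe_per_bead)))
  cf <- coef(fit)
  y <- log10(beads$pe_per_bead)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  r2 <- min(max(r2, 0), 1)
  curve <- structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                          r_squared = r2),
                     class = "standard_curve")
  if (curve$slope <= 0) {
    warning("fitted calibration slope is not positive; curve is not usable")
  }
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Bead standard curve: log10(ABC) = %.4f * log10(MFI) + %.4f  (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert fluorescence intensities to antibodies bound per cell
#'
#' @param intensities Strictly positive per-cell fluorescence intensities.
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return Per-cell ABC values, `10^(slope * log10(I) + intercept)`.
#' @export
fluorescence_to_abc <- function(intensities, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("fluorescence intensities must be strictly positive", call. = FALSE)
  }
  10^(curve$slope * log10(intensities) + curve$intercept)
}

#' Invert a standard curve: ABC to expected fluorescence
#'
#' Used by the synthetic generator to emit fluorescence values whose
#' calibrated readout recovers a known ABC.
#'
#' @param abc Strictly positive ABC values.
#' @param curve A `standard_curve`.
#' @return Fluorescence intensities `10^((log10(abc) - intercept) / slope)`.
#' @export
abc_to_fluorescence <- function(abc, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(abc <= 0)) stop("ABC values must be strictly positive", call. = FALSE)
  10^((log10(abc) - curve$intercept) / curve$slope)
}

#' Per-antigen flow cytometry event table for one sample
#'
#' @param sample_id Sample identifier.
#' @param antigen Antigen name.
#' @param intensities Strictly positive per-cell fluorescence intensities.
#' @param gate Character vector of gate labels per event (e.g. `"blast"` for
#'   CD45-mid blasts, `"lsc"` for the CD34+CD38- LSC-enriched subset; LSC
#'   events are also blasts).
#' @param fmo_threshold Optional positivity threshold derived from a
#'   fluorescence-minus-one (FMO) control.
#' @param fmo_events Optional raw FMO control intensities from which the
#'   threshold is derived when `fmo_threshold` is missing.
#' @return An object of class `flow_sample`.
#' @export
flow_sample <- function(sample_id, antigen, intensities, gate = NULL,
                        fmo_threshold = NULL, fmo_events = NULL) {
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("flow intensities must be strictly positive", call. = FALSE)
  }
  gate <- gate %||% rep("blast", length(intensities))
  stopifnot(length(gate) == length(intensities))
  structure(list(sample_id = sample_id, antigen = antigen,
                 intensities = as.numeric(intensities),
                 gate = as.character(gate),
                 fmo_threshold = fmo_threshold,
                 fmo_events = fmo_events),
            class = "flow_sample")
}

#' Derive an FMO positivity threshold from control events
#'
#' The threshold is the 99.9th percentile of the FMO control intensity
#' distribution, a standard gating convention.
#'
#' @param fmo_events Positive FMO control intensities.
#' @param probs Percentile used for the gate (default 0.999).
#' @return A scalar threshold.
#' @export
fmo_threshold <- function(fmo_events, probs = 0.999) {
  if (length(fmo_events) == 0L) stop("no FMO events supplied", call. = FALSE)
  unname(quantile(fmo_events, probs, type = 7))
}

#' Fraction of gated events positive for the antigen
#'
#' Positivity is defined as intensity strictly above the FMO threshold,
#' computed over events in the requested gate.
#'
#' @param sample A [flow_sample()].
#' @param gate Gate to evaluate (default `"blast"`; events labeled `"lsc"`
#'   are counted as blasts too).
#' @return Fraction in `[0, 1]`.
#' @export
percent_positive <- function(sample, gate = "blast") {
  stopifnot(inherits(sample, "flow_sample"))
  thr <- sample$fmo_threshold
  if (is.null(thr)) {
    if (is.null(sample$fmo_events)) {
      stop("no FMO threshold and no FMO events to derive one", call. = FALSE)
    }
    thr <- fmo_threshold(sample$fmo_events)
  }
  keep <- in_gate(sample$gate, gate)
  if (!any(keep)) stop("no events in gate '", gate, "'", call. = FALSE)
  mean(sample$intensities[keep] > thr)
}

# lsc events are a subset of blasts: asking for the blast gate includes them
in_gate <- function(labels, gate) {
  if (identical(gate, "blast")) labels %in% c("blast", "lsc") else labels == gate
}

#' Summarize one flow sample: positivity, gMFI and mean ABC
#'
#' @param sample A [flow_sample()].
#' @param curve A `standard_curve` used to convert intensities to ABC.
#' @param gate Gate to summarize.
#' @return One-row data.frame with `sample_id`, `antigen`, `gate`,
#'   `pct_positive`, `gmfi_positive`, `mean_abc_positive` and `mean_abc`
#'   (unconditional mean over gated events).
#' @export
summarize_flow_sample <- function(sample, curve, gate = "blast") {
  keep <- in_gate(sample$gate, gate)
  intens <- sample$intensities[keep]
  abc <- fluorescence_to_abc(intens, curve)
  pct <- percent_positive(sample, gate = gate)
  thr <- sample$fmo_threshold %||% fmo_threshold(sample$fmo_events)
  pos <- intens > thr
  data.frame(sample_id = sample$sample_id, antigen = sample$antigen,
             gate = gate, pct_positive = pct,
             gmfi_positive = if (any(pos)) geometric_mean(intens[pos]) else NA_real_,
             mean_abc_positive = if (any(pos)) mean(abc[pos]) else NA_real_,
             mean_abc = mean(abc),
             stringsAsFactors = FALSE)
}

#' Read a bead standard table from CSV
#'
#' Expected columns: `population`, `pe_per_bead`, `gmfi`.
#' @param path CSV path.
#' @return A [bead_standard()].
#' @export
read_bead_standard <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pe_per_bead", "gmfi") %in% names(df)))
  bead_standard(df$pe_per_bead, df$gmfi)
}

#' Write a bead standard table to CSV
#' @param beads A [bead_standard()].
#' @param path CSV path.
#' @export
write_bead_standard <- function(beads, path) {
  write.csv(data.frame(population = seq_along(beads$pe_per_bead),
                       pe_per_bead = beads$pe_per_bead, gmfi = beads$gmfi),
            path, row.names = FALSE)
}
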