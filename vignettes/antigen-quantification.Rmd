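---
title: "Methods: bridging CITE-seq ADT counts to absolute antigen numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bridging CITE-seq ADT counts to absolute antigen numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antigenbridge)
```

## Overview

CITE-seq antibody-derived tag (ADT) counts are a relative readout of
surface-protein abundance: the same cell assayed in two libraries can
yield counts differing by an order of magnitude because of capture
efficiency, sequencing depth and antibody-specific artifacts.
Quantitative flow cytometry calibrated with PE bead standards yields
absolute antibodies bound per cell (ABC) but only one antigen per panel
and no per-cell multiplexing. This package estimates absolute per-cell
antigen numbers for a whole CITE-seq panel by learning, from a handful
of *bridge antigens* measured on both platforms, how normalized ADT
values map onto calibrated ABC values — and how that mapping bends with
per-sample technical artifacts.

## The calibration and mapping model

**Bead curve.** A bead standard supplies pairs (PE molecules per bead,
measured geometric MFI). `fit_standard_curve()` regresses
`log10(pe_per_bead)` on `log10(gmfi)` by ordinary least squares. The
direction is fixed so prediction maps intensity to molecule count; with
the near-perfect r² of bead standards the choice of direction is
numerically immaterial, but one must be fixed for reproducibility.
`fluorescence_to_abc()` applies `10^(slope·log10 I + intercept)` to
gated blast events.

**Quantile maps.** Flow and CITE-seq assay *different aliquots* of the
same sample, so cells cannot be matched individually. For each sample
and bridge antigen we therefore compute empirical quantiles of the
log10 ABC distribution and of the normalized ADT distribution at a
common grid and pair them by rank. This assumes the two aliquots draw
from the same underlying abundance distribution and that both gates
(CD45-mid blasts) capture the same population — the central
identifiability assumption of the whole method. The grid is
`seq(0.05, 0.95, by = 0.05)` (19 levels): the extreme levels 0 and 1
are excluded because extreme order statistics have high sampling
variance at typical per-sample cell numbers. Quantiles use linear
interpolation between closest order statistics (R type 7), fixed so
maps are bit-reproducible.

**Artifact-aware regression.** The training table holds one row per
(sample, antigen, grid level): the ADT quantile value plus the sample's
13 antibody-library QC metrics as features, the log10 ABC quantile as
target. A random forest (500 trees, ⌊p/3⌋ candidate features per split,
unlimited depth; all overridable) learns both the monotone ADT→ABC
trend and its sample-specific distortions, for which the QC metrics are
proxies. Cross-validated error is reported from a 10-fold, 10-repeat
resampling. The grid level itself is *not* a feature: at prediction
time a single cell has no meaningful quantile level, and including it
would make the model inapplicable per cell. At prediction the cell's
normalized ADT value substitutes for the quantile-value feature, the
sample's QC metrics fill the rest, and predictions are unlogged.
Predictions are clipped to the training target range ± 0.5 log10 before
unlogging; tree ensembles cannot extrapolate, and the clip prevents
spurious blow-ups on out-of-range inputs (clip events are counted in
the result object).

**Validation.** `leave_one_antigen_out()` retrains the model once per
bridge antigen with that antigen's rows excluded (an internal assertion
verifies the exclusion), predicts it per cell, and compares sample-mean
predictions with flow-measured means: per-antigen Spearman correlation
and median absolute log10 bias. Because it compares *sample means*, it
validates cross-sample transfer, not per-cell accuracy — per-cell
accuracy is unobservable on real data and is checked against ground
truth only on synthetic cohorts.

## ADT normalization

Three transforms are provided; the bridge consumes the last two.

- `clr_normalize()`: per cell, `ln(x+1)` centered by its mean across
  antibodies. Used for the CD34/CD38 gate thresholds.
- `dsb_normalize()`: per antibody, `ln(x+1)` is z-scored against a
  background mean/SD — taken from an empty-droplet (ambient) matrix
  when available, otherwise from the lowest decile of cells per
  antibody (an in-sample proxy, flagged in the output attribute, and
  noticeably weaker: the low tail of an abundant antigen is not true
  background). Then each cell's mean isotype-control z-score, an
  estimate of its multiplicative technical factor, is subtracted from
  all its values. Natural log and +1 pseudocount are used throughout;
  the base only rescales and the pseudocount handles zeros.
- `quantile_normalize_cells()`: classical matrix quantile normalization
  with cells as the normalized units (reference = mean of sorted
  profiles; ties averaged), placing every cell on a common scale so
  that quantiles of a given antigen are comparable across cells and
  samples. Whether profile-wise normalization should run across cells
  or across antibodies is genuinely ambiguous; cells-as-units was
  chosen because the downstream quantile map needs a common scale
  across cells, and the convention is switchable by simply not calling
  the step.

## Target prioritization

Positivity on estimates uses strict `> threshold` (default 1000
antigens/cell, the density scale at which antibody–drug conjugates
kill); flow positivity via FMO gates (99.9th percentile of the control
distribution when raw FMO events are given) is a separate reported
quantity, and the two are not forced to agree. The ranking criterion —
≥80% positivity AND ≥1000 median antigens among positive cells — is
evaluated per sample/population and aggregated as the fraction of
samples passing, because pass rates per timepoint and compartment are
the decision-relevant summary. Ties in the count-ordered ranking break
alphabetically. Antibodies known to be undersaturated at staining
concentration (CD13, CD45, CD47, CD99, HLA-DR) carry a caution flag;
their estimates are reported, not suppressed.

The LSC-enriched gate combines a stemness module score (> 0) with CLR
CD34 > 1 and CLR CD38 < 1, all strict. The module score bins genes into
24 equal-frequency strata by pooled average expression (ties to the
lower bin) and samples 100 control genes per gene-set gene from the
matching stratum (with replacement when a stratum is small), seeded for
reproducibility.

## Composition and outcome

Shannon diversity uses the natural log (the printed maximum 2.19 for
nine states equals ln 9 truncated). The Aitchison distance is the
Euclidean distance between CLR-transformed frequency vectors; states
with zero cells receive a pseudocount of 10 *in count space, zeros
only*, before frequencies are recomputed (the all-states variant is
available by flag). Two robustness procedures: a fraction bootstrap
(5%–100%, without replacement — it is a subsampling check, and at 100%
must reproduce the full-data value exactly) and a fixed-size bootstrap
(default 344 cells, with replacement — equalizing cell numbers across
samples before survival modeling).

Survival: patients split at the *mean* distance (median by flag) and
compared by two-group log-rank; Cox proportional hazards on the
continuous distance with patient sex as covariate, Efron tie handling,
Wald p-values. On degenerate inputs (a split group below two patients,
a constant covariate) the pipeline records NA rows with a note rather
than aborting, since tiny smoke cohorts legitimately produce them.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws, per sample and antigen, a mean log10 ABC
uniform on `log10(c(200, 10000))` — the abundance span reported for
established myeloid targets — and per-cell true values normal around it
(SD 0.25 log10). ADT counts are negative binomial (size 10) with mean
= truth × sample capture efficiency (uniform on 0.2–1) × per-cell
lognormal technical factor (SD 0.3) that also scales the isotype
background (mean 5 counts), giving the DSB step something real to
remove; 500 empty droplets per sample provide an ambient background
that is abundance-independent, as droplet ambient approximately is. QC
metrics are linear functions of capture efficiency plus Gaussian noise
(5% of the slope), making them informative artifact covariates.
Flow events push an independent aliquot's truth through the inverse
bead curve (slope 1, intercept 0.3) with 10% lognormal noise; the FMO
gate sits at 150 ABC. Diagnosis compositions are Dirichlet(1) over the
nine lineage states; the relapse composition moves a patient-specific
distance (uniform on 0–2) along a random unit direction in CLR space,
so the true Aitchison shift is exactly that distance. Survival is
exponential with log-hazard `log(1/36) − 0.6 × shift` (a protective
effect of the same direction and magnitude class as reported
associations between compositional shift and overall survival) and
administrative censoring at 60 months.

Deliberately *not* modeled: transcriptome structure beyond a minimal
expression matrix for module-score testing, doublets and ambient RNA
contamination of the ADT signal, antigen-dependent lineage labels
(composition and antigen analyses are decoupled), gate mismatch between
flow and CITE-seq aliquots, and any joint flow/CITE-seq noise beyond
conditional independence given true ABC. Passing tests therefore
demonstrate correctness of the algorithms and recoverability under the
stated noise model — not robustness to ambient contamination, gating
drift or label error in real data.

## Numerical choices and problem sizes

Fixed seeds derive per-stage seeds by hashing the stage name into the
global seed (`derive_seed()`), so any stage re-run in isolation
reproduces the full run; all derived seeds stay below 2³¹. The test
suite and the acceptance script use scaled-down cohorts chosen to make
every estimate stable while keeping a full run in tens of seconds: the
main validation cohort is 10 patients (20 samples) × 2,000 cells × 12
antigens with 4 bridge antigens; survival direction/coverage use 50
replicate cohorts of 200 patients × 500 cells; the bootstrap plateau
uses 6,000 cells per timepoint; the end-to-end smoke run uses 4
patients × 500 cells × 8 antigens. Under these conditions
leave-one-antigen-out recovery is typically Spearman ≥ 0.95 per antigen
(median absolute log10 bias ≈ 0.15–0.25), the protective Cox direction
is recovered in every replicate, and the null 95% CI covers 1 at the
nominal rate.

## Known limitations

- The in-sample background proxy for DSB (no empty droplets) removes
  part of the biological between-antigen signal; supply ambient
  droplets whenever possible.
- Cell-profile quantile normalization over a small panel (12 antigens)
  discretizes each cell's values to at most 12 distinct levels, which
  bounds per-cell resolution; the paper-scale setting (≈80 antigens)
  suffers much less.
- Tree ensembles do not guarantee monotonicity of predicted ABC in the
  ADT value at fixed QC; violations are possible and the estimate
  container counts range-clip events as a related diagnostic.
- Antigens whose true abundance lies outside the bridge antigens' range
  are extrapolations and carry the training-range clip; treat their
  absolute values as hypothesis-generating.
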