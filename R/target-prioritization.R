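#' Positivity and intensity summary for one antigen
#'
#' The fraction of gated cells whose estimated count lies strictly above
#' the threshold, plus mean and median count among those positive cells.
#'
#' @param estimates An `abc_estimates` object (see [predict_cell_abc()])
#'   or a plain cells x antigens count matrix.
#' @param antigen Antigen name.
#' @param threshold Positivity threshold in antigens per cell (default
#'   1000, the density reported necessary for antibody-drug-conjugate
#'   killing).
#' @param gate Gate to evaluate when the estimates carry gate labels.
#' @return One-row data.frame: `sample_id`, `antigen`, `population`,
#'   `pct_positive`, `mean_positive`, `median_positive`, `median_all`,
#'   `caution` (undersaturated antibody flag).
#' @export
positivity_and_intensity <- function(estimates, antigen, threshold = 1000,
                                     gate = "blast") {
  counts <- estimate_counts(estimates, gate)
  if (!antigen %in% colnames(counts)) {
    stop("unknown antigen '", antigen, "'", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (nrow(counts) == 0L) stop("no cells in gate '", gate, "'", call. = FALSE)
  v <- counts[, antigen]
  pos <- v > threshold
  data.frame(sample_id = estimate_id(estimates), antigen = antigen,
             population = gate, pct_positive = mean(pos),
             mean_positive = if (any(pos)) mean(v[pos]) else NA_real_,
             median_positive = if (any(pos)) median(v[pos]) else NA_real_,
             median_all = median(v),
             caution = antigen %in% undersaturated_antigens(),
             stringsAsFactors = FALSE)
}

estimate_counts <- function(estimates, gate = "blast") {
  if (inherits(estimates, "abc_estimates")) {
    counts <- estimates$counts
    if (!is.null(estimates$gates)) {
      counts <- counts[in_gate(estimates$gates, gate), , drop = FALSE]
    }
    counts
  } else {
    as.matrix(estimates)
  }
}

estimate_id <- function(estimates) {
  if (inherits(estimates, "abc_estimates")) estimates$sample_id else NA_character_
}

#' Fraction of cells co-expressing two antigens above a threshold
#'
#' @param estimates See [positivity_and_intensity()].
#' @param antigen_a,antigen_b Antigen names (symmetric).
#' @param threshold Count threshold (strict `>` on both antigens).
#' @param gate Gate to evaluate.
#' @return Fraction in `[0, 1]`.
#' @export
co_expression_fraction <- function(estimates, antigen_a, antigen_b,
                                   threshold = 1000, gate = "blast") {
  counts <- estimate_counts(estimates, gate)
  for (a in c(antigen_a, antigen_b)) {
    if (!a %in% colnames(counts)) stop("unknown antigen '", a, "'", call. = FALSE)
  }
  mean(counts[, antigen_a] > threshold & counts[, antigen_b] > threshold)
}

#' Rank antigens by the positivity / antigen-number criterion
#'
#' Evaluates the dual criterion — at least `positivity_min` of gated cells
#' positive AND median count among positive cells at least `count_min` —
#' per (sample, population) summary, then aggregates per antigen: the
#' fraction of summaries passing both criteria and the median count
#' pooled across samples. Antigens are sorted by pooled median count
#' descending, ties broken alphabetically.
#'
#' @param summaries data.frame of [positivity_and_intensity()] rows.
#' @param positivity_min Minimum positive fraction (default 0.8).
#' @param count_min Minimum median count among positives (default 1000).
#' @return data.frame: `antigen`, `n_samples`, `criterion_fraction`,
#'   `pooled_median_count`, `caution`, `annotation` (free text, empty),
#'   sorted; plus attribute `per_sample` with per-summary pass flags.
#' @export
rank_targets <- function(summaries, positivity_min = 0.8, count_min = 1000) {
  stopifnot(nrow(summaries) >= 1L)
  pass <- summaries$pct_positive >= positivity_min &
    !is.na(summaries$median_positive) & summaries$median_positive >= count_min
  per_sample <- cbind(summaries, pass = pass)
  agg <- lapply(split(per_sample, per_sample$antigen), function(d) {
    data.frame(antigen = d$antigen[1], n_samples = nrow(d),
               criterion_fraction = mean(d$pass),
               pooled_median_count = median(d$median_all),
               caution = any(d$caution), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out$annotation <- ""
  out <- out[order(-out$pooled_median_count, out$antigen), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  out
}

#' Gating parameters for the LSC-enriched population
#'
#' Strict thresholds: module score > `module_score_min`, CLR-normalized
#' CD34 > `cd34_clr_min`, CLR-normalized CD38 < `cd38_clr_max`.
#'
#' @param module_score_min,cd34_clr_min,cd38_clr_max Finite thresholds.
#' @return A list of class `lsc_gate_params`.
#' @export
lsc_gate_params <- function(module_score_min = 0, cd34_clr_min = 1,
                            cd38_clr_max = 1) {
  stopifnot(is.finite(module_score_min), is.finite(cd34_clr_min),
            is.finite(cd38_clr_max))
  structure(list(module_score_min = module_score_min,
                 cd34_clr_min = cd34_clr_min, cd38_clr_max = cd38_clr_max),
            class = "lsc_gate_params")
}

#' Identify the LSC-enriched population among blasts
#'
#' Cells with a positive stemness (LSC17-style) module score, high CLR
#' CD34 and low CLR CD38 — all strict inequalities.
#'
#' @param scores Per-cell module scores.
#' @param cd34_clr,cd38_clr Per-cell CLR-normalized ADT values.
#' @param params A [lsc_gate_params()].
#' @return Logical mask, `TRUE` for cells in the gate.
#' @export
lsc_gate <- function(scores, cd34_clr, cd38_clr, params = lsc_gate_params()) {
  n <- length(scores)
  if (length(cd34_clr) != n || length(cd38_clr) != n) {
    stop("score and ADT vectors have mismatched lengths", call. = FALSE)
  }
  scores > params$module_score_min & cd34_clr > params$cd34_clr_min &
    cd38_clr < params$cd38_clr_max
}

#' Expression module score with binned control genes
#'
#' Per cell, the mean expression of a gene set minus the mean expression
#' of control genes drawn from matching expression strata: genes are
#' binned into `n_bins` equal-frequency bins by pooled average expression
#' (ties to the lower bin) and, for each gene-set gene, `n_ctrl` control
#' genes are sampled (seeded, with replacement when a bin is small) from
#' its bin.
#'
#' @param expression Matrix cells x genes.
#' @param gene_set Character vector of gene names; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per gene-set gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return Numeric per-cell score vector.
#' @export
module_score <- function(expression, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  expression <- as.matrix(expression)
  genes <- colnames(expression)
  if (length(genes) < n_bins) {
    stop("need at least ", n_bins, " genes for binning", call. = FALSE)
  }
  missing_g <- setdiff(gene_set, genes)
  if (length(missing_g)) {
    warning("dropping genes absent from the matrix: ",
            paste(missing_g, collapse = ", "))
  }
  gene_set <- intersect(gene_set, genes)
  if (!length(gene_set)) stop("empty gene set after intersection", call. = FALSE)
  avg <- colMeans(expression)
  ranks <- rank(avg, ties.method = "min")  # ties to the lower bin
  bin <- ceiling(ranks / (length(genes) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  set.seed(derive_seed(seed, "module-score"))
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- genes[bin == bin[match(g, genes)]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  rowMeans(expression[, gene_set, drop = FALSE]) -
    rowMeans(expression[, ctrl, drop = FALSE])
}
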