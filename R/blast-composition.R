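#' The blast lineage-state vocabulary
#'
#' The nine hematopoietic lineage states blasts are projected onto, in
#' fixed order.
#' @return Character vector of length 9.
#' @export
lineage_states <- function() {
  c("HSC-like", "GMP-like", "MEP-like", "Pre/pro-B-like", "MkP-like",
    "erythroblast-like", "monocyte-like", "cDC-like", "pDC-like")
}

#' Lineage-state counts from per-cell labels
#'
#' @param labels Character vector of per-cell lineage labels.
#' @param states State vocabulary (default [lineage_states()]).
#' @return Named integer vector of counts over the full vocabulary.
#' @export
composition_from_labels <- function(labels, states = lineage_states()) {
  bad <- setdiff(unique(labels), states)
  if (length(bad)) {
    stop("labels outside the state vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table(factor(labels, levels = states)) |> c()
}

check_composition <- function(x, name = "composition") {
  if (is.null(names(x))) stop(name, " must be a named count vector", call. = FALSE)
  if (any(x < 0)) stop(name, " counts must be nonnegative", call. = FALSE)
  x
}

#' Shannon diversity index of a lineage-state composition
#'
#' `-sum(p_i * log(p_i))` over nonzero state frequencies, natural log, so
#' the maximum for 9 states is `log(9) = 2.1972`. Computed with
#' `vegan::diversity()`.
#'
#' @param counts Named nonnegative count (or frequency) vector.
#' @return Nonnegative scalar.
#' @export
shannon_index <- function(counts) {
  counts <- check_composition(counts)
  if (sum(counts) <= 0) stop("all-zero composition has no diversity", call. = FALSE)
  unname(vegan::diversity(counts / sum(counts), index = "shannon"))
}

#' Aitchison distance between two lineage-state compositions
#'
#' The Euclidean distance between the centered log-ratio (CLR) transforms
#' of the two frequency vectors:
#' `sqrt(sum_i (log(x_i / g(x)) - log(y_i / g(y)))^2)` with `g()` the
#' geometric mean. States with zero cells receive a pseudocount (default
#' 10, added in count space to zero-count states only) before frequencies
#' are recomputed, keeping the distance finite and continuous.
#'
#' @param x,y Named nonnegative count vectors on the same state vocabulary.
#' @param pseudocount Count added to zero states (default 10).
#' @param zeros_only If `TRUE` (default), the pseudocount goes to
#'   zero-count states only; if `FALSE`, to every state.
#' @return Nonnegative scalar.
#' @export
aitchison_distance <- function(x, y, pseudocount = 10, zeros_only = TRUE) {
  x <- check_composition(x, "x"); y <- check_composition(y, "y")
  if (!identical(names(x), names(y))) {
    stop("compositions use different state vocabularies", call. = FALSE)
  }
  x <- add_pseudocount(x, pseudocount, zeros_only)
  y <- add_pseudocount(y, pseudocount, zeros_only)
  lx <- log(x / sum(x)); ly <- log(y / sum(y))
  dx <- (lx - mean(lx)) - (ly - mean(ly))
  sqrt(sum(dx^2))
}

add_pseudocount <- function(v, pseudocount, zeros_only) {
  if (zeros_only) v[v == 0] <- v[v == 0] + pseudocount else v <- v + pseudocount
  if (any(v <= 0)) stop("composition still has non-positive states after pseudocount",
                        call. = FALSE)
  v
}

#' Aitchison distance robustness under fractional subsampling
#'
#' Subsamples a fraction of cells without replacement from each timepoint,
#' recomputes the diagnosis-relapse Aitchison distance, and summarizes
#' replicates per fraction. Used to check that the distance has plateaued
#' at the observed cell numbers.
#'
#' @param diag_labels,relapse_labels Per-cell lineage labels at each
#'   timepoint.
#' @param fractions Subsampling fractions in `(0, 1]` (default 5% steps).
#' @param reps Replicates per fraction.
#' @param seed Integer seed.
#' @param states State vocabulary.
#' @param pseudocount Passed to [aitchison_distance()].
#' @return data.frame with columns `fraction`, `mean_distance`,
#'   `sd_distance`, `n_diag`, `n_relapse`.
#' @export
bootstrap_distance_curve <- function(diag_labels, relapse_labels,
                                     fractions = seq(0.05, 1, by = 0.05),
                                     reps = 50, seed = 1,
                                     states = lineage_states(),
                                     pseudocount = 10) {
  if (!length(diag_labels) || !length(relapse_labels)) {
    stop("empty label vectors", call. = FALSE)
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  out <- lapply(fractions, function(f) {
    nd <- ceiling(f * length(diag_labels))
    nr <- ceiling(f * length(relapse_labels))
    d <- vapply(seq_len(reps), function(r) {
      cd <- composition_from_labels(sample(diag_labels, nd), states)
      cr <- composition_from_labels(sample(relapse_labels, nr), states)
      aitchison_distance(cd, cr, pseudocount = pseudocount)
    }, numeric(1))
    data.frame(fraction = f, mean_distance = mean(d), sd_distance = sd(d),
               n_diag = nd, n_relapse = nr)
  })
  do.call(rbind, out)
}

#' Fixed-size bootstrap of the compositional shift
#'
#' Draws a fixed number of blasts (default 344, matching the smallest
#' sample a paired-cohort analysis would admit) with replacement from each
#' timepoint's label pool, recomputing the Aitchison distance per
#' replicate. Equalizes cell numbers across patients before survival
#' modeling.
#'
#' @param pairs List of pairs; each element needs `patient_id`,
#'   `diag_labels` and `relapse_labels`.
#' @param n Cells drawn per timepoint per replicate (default 344).
#' @param reps Replicates.
#' @param seed Integer seed.
#' @param states State vocabulary.
#' @param pseudocount Passed to [aitchison_distance()].
#' @return List with `replicates` (data.frame patient_id, rep, distance)
#'   and `patient_means` (data.frame patient_id, mean_distance).
#' @export
fixed_size_bootstrap <- function(pairs, n = 344, reps = 100, seed = 1,
                                 states = lineage_states(), pseudocount = 10) {
  set.seed(seed)
  rows <- lapply(pairs, function(p) {
    stopifnot(length(p$diag_labels) >= 1L, length(p$relapse_labels) >= 1L)
    d <- vapply(seq_len(reps), function(r) {
      cd <- composition_from_labels(sample(p$diag_labels, n, replace = TRUE), states)
      cr <- composition_from_labels(sample(p$relapse_labels, n, replace = TRUE), states)
      aitchison_distance(cd, cr, pseudocount = pseudocount)
    }, numeric(1))
    data.frame(patient_id = p$patient_id, rep = seq_len(reps), distance = d)
  })
  replicates <- do.call(rbind, rows)
  means <- aggregate(distance ~ patient_id, replicates, mean)
  names(means)[2] <- "mean_distance"
  list(replicates = replicates, patient_means = means)
}
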