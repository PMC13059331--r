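#' Default quantile grid for the cross-modality map
#'
#' 5% steps from 0.05 to 0.95. The extreme levels 0 and 1 are excluded
#' because extreme order statistics are noisy at per-sample cell numbers.
#' @return Numeric vector of 19 levels.
#' @export
default_quantile_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Antibodies known to be undersaturated at staining concentration
#'
#' Estimates for these antigens carry a caution flag through ranking
#' output; estimation itself is not suppressed.
#' @return Character vector.
#' @export
undersaturated_antigens <- function() {
  c("CD13", "CD45", "CD47", "CD99", "HLA-DR")
}

#' Build a per-sample, per-antigen ADT-to-ABC quantile map
#'
#' Computes empirical quantiles (linear interpolation between closest
#' order statistics, R type 7) of the flow-derived ABC distribution (log10
#' scale) and of the normalized ADT distribution at a common grid of
#' levels. Because flow and CITE-seq assay separate aliquots, cells cannot
#' be matched individually; the map assumes rank alignment — the lowest
#' ADT quantile corresponds to the lowest ABC quantile.
#'
#' @param abc_values Strictly positive flow-derived ABC values of gated
#'   blasts.
#' @param adt_values Normalized ADT values of gated blasts for the same
#'   antigen.
#' @param grid Quantile levels in `(0, 1)` (default
#'   [default_quantile_grid()]).
#' @param sample_id,antigen Identifiers carried into the map.
#' @return An object of class `quantile_map` with fields `sample_id`,
#'   `antigen`, `grid`, `adt_quantiles`, `abc_log10_quantiles`.
#' @export
build_quantile_map <- function(abc_values, adt_values,
                               grid = default_quantile_grid(),
                               sample_id = NA_character_,
                               antigen = NA_character_) {
  if (!length(abc_values) || !length(adt_values)) {
    stop("empty input distributions", call. = FALSE)
  }
  if (any(abc_values <= 0)) stop("ABC values must be strictly positive", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid >= 1)) {
    stop("quantile grid must be strictly increasing within (0, 1)", call. = FALSE)
  }
  if (min(length(abc_values), length(adt_values)) < length(grid)) {
    warning("fewer observations than grid points; quantiles are interpolated")
  }
  structure(list(
    sample_id = sample_id, antigen = antigen, grid = grid,
    adt_quantiles = unname(quantile(adt_values, grid, type = 7)),
    abc_log10_quantiles = unname(quantile(log10(abc_values), grid, type = 7))),
    class = "quantile_map")
}

#' Assemble the bridge-model training table
#'
#' One row per unique (sample, antigen, grid-level) combination. Feature
#' columns are the normalized ADT quantile value and the 13 antibody
#' library QC metrics of the sample; the target is the log10 ABC quantile.
#'
#' @param maps List of [build_quantile_map()] objects.
#' @param qc data.frame of QC metrics with a `sample_id` column plus the
#'   [qc_metric_names()] columns, one row per sample.
#' @return data.frame with provenance columns `sample_id`, `antigen`,
#'   `level`, feature columns `adt_value` + QC metrics, and target
#'   `abc_log10`.
#' @export
build_training_table <- function(maps, qc) {
  stopifnot(is.data.frame(qc), "sample_id" %in% names(qc))
  miss <- setdiff(qc_metric_names(), names(qc))
  if (length(miss)) stop("QC table missing metrics: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rows <- lapply(maps, function(m) {
    stopifnot(inherits(m, "quantile_map"))
    j <- match(m$sample_id, qc$sample_id)
    if (is.na(j)) stop("no QC metrics for sample '", m$sample_id, "'", call. = FALSE)
    data.frame(sample_id = m$sample_id, antigen = m$antigen, level = m$grid,
               adt_value = m$adt_quantiles,
               qc[j, qc_metric_names(), drop = FALSE],
               abc_log10 = m$abc_log10_quantiles,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out)) stop("training table contains missing values", call. = FALSE)
  out
}

bridge_features <- function() c("adt_value", qc_metric_names())

#' Train the artifact-aware ADT-to-ABC regression model
#'
#' A random forest (500 trees, `floor(p/3)` candidate features per split,
#' unlimited depth — the customary regression defaults) fit to the
#' quantile training table, with an optional 10-fold, 10-repeat
#' cross-validated RMSE summary. Predictions are deterministic under a
#' fixed seed.
#'
#' @param table A [build_training_table()] result.
#' @param seed Integer seed.
#' @param ntree,mtry Forest hyperparameters (defaults 500 and
#'   `floor(p/3)`).
#' @param cv Compute the repeated cross-validation summary (default
#'   `TRUE`; skip for speed in resampling loops).
#' @param cv_folds,cv_repeats Cross-validation layout.
#' @return An object of class `abc_model`: `forest`, `features`,
#'   `target_range`, `cv` (data.frame rmse_mean/rmse_sd or NULL), `seed`.
#' @export
train_model <- function(table, seed = 1, ntree = 500, mtry = NULL,
                        cv = TRUE, cv_folds = 10, cv_repeats = 10) {
  feats <- bridge_features()
  miss <- setdiff(c(feats, "abc_log10"), names(table))
  if (length(miss)) stop("training table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(table) < 50L) stop("need at least 50 training rows", call. = FALSE)
  x <- table[, feats, drop = FALSE]
  y <- table$abc_log10
  mtry <- mtry %||% max(1L, floor(length(feats) / 3))
  if (sd(y) < 1e-12) warning("constant training target; model will predict the constant")
  set.seed(derive_seed(seed, "fit"))
  forest <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  cv_summary <- NULL
  if (cv) {
    set.seed(derive_seed(seed, "cv"))
    rmse <- numeric(0)
    n <- nrow(table)
    for (r in seq_len(cv_repeats)) {
      fold <- sample(rep_len(seq_len(cv_folds), n))
      for (k in seq_len(cv_folds)) {
        tr <- fold != k
        f <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                        ntree = ntree, mtry = mtry)
        pred <- predict(f, x[!tr, , drop = FALSE])
        rmse <- c(rmse, sqrt(mean((pred - y[!tr])^2)))
      }
    }
    cv_summary <- data.frame(rmse_mean = mean(rmse), rmse_sd = sd(rmse))
  }
  structure(list(forest = forest, features = feats,
                 target_range = range(y), cv = cv_summary,
                 seed = as.integer(seed)),
            class = "abc_model")
}

#' @export
print.abc_model <- function(x, ...) {
  cat(sprintf("ADT->ABC bridge model: %d trees, %d features, target range [%.2f, %.2f] log10\n",
              x$forest$ntree, length(x$features),
              x$target_range[1], x$target_range[2]))
  if (!is.null(x$cv)) {
    cat(sprintf("  repeated-CV RMSE: %.4f (sd %.4f) log10 units\n",
                x$cv$rmse_mean, x$cv$rmse_sd))
  }
  invisible(x)
}

#' Predict per-cell absolute antigen counts
#'
#' Applies the bridge model to every cell and antigen of a normalized ADT
#' matrix: the cell's normalized ADT value stands in for the quantile
#' feature and the sample's QC metrics supply the artifact covariates.
#' Predicted log10 values are clipped to the training target range plus
#' or minus 0.5 log10 (to prevent unlog blow-ups; clipping is counted in
#' the result) and unlogged.
#'
#' @param model An [train_model()] result.
#' @param normalized Matrix cells x antigens of normalized ADT values.
#' @param qc Named numeric vector (or one-row data.frame) of the sample's
#'   QC metrics.
#' @param sample_id Identifier carried into the result.
#' @param antigens Antigens to predict (default: all columns).
#' @param gates Optional per-cell gate labels carried through.
#' @return An object of class `abc_estimates`: `sample_id`, `counts`
#'   (cells x antigens, linear scale), `gates`, `n_clipped`.
#' @export
predict_cell_abc <- function(model, normalized, qc, sample_id = NA_character_,
                             antigens = colnames(normalized), gates = NULL) {
  stopifnot(inherits(model, "abc_model"))
  normalized <- as.matrix(normalized)
  missing_a <- setdiff(antigens, colnames(normalized))
  if (length(missing_a)) {
    stop("antigens absent from the normalized matrix: ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(qc)) qc <- unlist(qc[1, , drop = TRUE])
  qvals <- qc[qc_metric_names()]
  if (anyNA(qvals)) stop("QC metrics incomplete for prediction", call. = FALSE)
  nc <- nrow(normalized)
  lo <- model$target_range[1] - 0.5
  hi <- model$target_range[2] + 0.5
  preds <- matrix(NA_real_, nrow = nc, ncol = length(antigens),
                  dimnames = list(rownames(normalized), antigens))
  n_clipped <- 0L
  qc_block <- as.data.frame(as.list(qvals))[rep(1L, nc), , drop = FALSE]
  for (a in antigens) {
    newdata <- cbind(data.frame(adt_value = normalized[, a]), qc_block)
    p <- predict(model$forest, newdata)
    n_clipped <- n_clipped + sum(p < lo | p > hi)
    preds[, a] <- pmin(pmax(p, lo), hi)
  }
  structure(list(sample_id = sample_id, counts = 10^preds,
                 gates = gates, n_clipped = n_clipped),
            class = "abc_estimates")
}

#' Normalized matrices, quantile maps, QC table and flow means of a cohort
#'
#' Runs the upstream stages (normalization, bead calibration, quantile
#' mapping, flow summarization) over a synthetic cohort and returns the
#' pieces the bridge consumes. Convenience wrapper used by the pipeline
#' and by validation runs.
#'
#' @param cohort A `synthetic_cohort`.
#' @param grid Quantile grid.
#' @return List with `normalized` (named list of matrices), `maps`,
#'   `qc` (data.frame), `flow_means` (data.frame sample_id, antigen,
#'   mean_abc), `curve`.
#' @export
prepare_bridge_inputs <- function(cohort, grid = default_quantile_grid()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  curve <- fit_standard_curve(cohort$bead_standard)
  normalized <- lapply(cohort$samples, function(s) normalize_adt_for_bridge(s$adt))
  qc <- do.call(rbind, lapply(cohort$samples, function(s) {
    data.frame(sample_id = s$sample_id,
               as.data.frame(as.list(s$adt$qc_metrics)),
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  maps <- list()
  fm <- list()
  for (s in cohort$samples) {
    for (a in names(s$flow)) {
      f <- s$flow[[a]]
      blast <- in_gate(f$gate, "blast")
      abc <- fluorescence_to_abc(f$intensities[blast], curve)
      maps[[paste(s$sample_id, a, sep = ":")]] <-
        build_quantile_map(abc, normalized[[s$sample_id]][, a], grid,
                           sample_id = s$sample_id, antigen = a)
      fm[[paste(s$sample_id, a, sep = ":")]] <-
        data.frame(sample_id = s$sample_id, antigen = a, mean_abc = mean(abc),
                   stringsAsFactors = FALSE)
    }
  }
  list(normalized = normalized, maps = maps, qc = qc,
       flow_means = do.call(rbind, c(fm, list(make.row.names = FALSE))),
       curve = curve)
}

#' Leave-one-antigen-out concordance validation
#'
#' For each bridge antigen in turn, the model is trained on the quantile
#' maps of the remaining antigens only, then used to predict the excluded
#' antigen per cell in every sample. Sample-level mean predicted ABC is
#' compared with the flow-measured mean ABC: the report carries the
#' per-antigen Spearman correlation across samples and the median
#' absolute log10 bias.
#'
#' @param maps List of quantile maps covering the bridge antigens.
#' @param qc QC metric data.frame (see [build_training_table()]).
#' @param normalized Named list (by sample) of normalized ADT matrices.
#' @param flow_means data.frame `sample_id`, `antigen`, `mean_abc` of
#'   flow-measured sample means.
#' @param seed Integer seed.
#' @param ... Passed to [train_model()] (e.g. `ntree`).
#' @return List with `report` (data.frame antigen, spearman,
#'   median_abs_log10_bias, n_samples) and `sample_level` (data.frame
#'   antigen, sample_id, predicted_mean_abc, flow_mean_abc).
#' @export
leave_one_antigen_out <- function(maps, qc, normalized, flow_means, seed = 1,
                                  ...) {
  antigens <- unique(vapply(maps, `[[`, character(1), "antigen"))
  if (length(antigens) < 2L) {
    stop("leave-one-antigen-out needs at least 2 bridge antigens", call. = FALSE)
  }
  rows <- list(); detail <- list()
  for (a in antigens) {
    keep <- vapply(maps, function(m) m$antigen != a, logical(1))
    table <- build_training_table(maps[keep], qc)
    stopifnot(!a %in% table$antigen)  # leakage guard
    model <- train_model(table, seed = derive_seed(seed, paste0("loao-", a)),
                         cv = FALSE, ...)
    per_sample <- lapply(names(normalized), function(sid) {
      est <- predict_cell_abc(model, normalized[[sid]],
                              qc[match(sid, qc$sample_id), ],
                              sample_id = sid, antigens = a)
      data.frame(antigen = a, sample_id = sid,
                 predicted_mean_abc = mean(est$counts[, a]),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_sample)
    df <- merge(df, flow_means[flow_means$antigen == a,
                               c("sample_id", "mean_abc")], by = "sample_id")
    names(df)[names(df) == "mean_abc"] <- "flow_mean_abc"
    detail[[a]] <- df
    rows[[a]] <- data.frame(
      antigen = a,
      spearman = cor(df$predicted_mean_abc, df$flow_mean_abc,
                     method = "spearman"),
      median_abs_log10_bias = median(abs(log10(df$predicted_mean_abc) -
                                           log10(df$flow_mean_abc))),
      n_samples = nrow(df), stringsAsFactors = FALSE)
  }
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       sample_level = do.call(rbind, c(detail, list(make.row.names = FALSE))))
}
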