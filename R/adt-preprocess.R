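#' CITE-seq ADT sample container
#'
#' Holds a cells-by-antibodies tag-count matrix with its isotype-control
#' columns, the per-cell RNA QC triple used for cell filtering, the
#' antibody-library QC metrics of the sample, and (optionally) an
#' empty-droplet count matrix used for background estimation.
#'
#' @param sample_id Sample identifier.
#' @param counts Nonnegative integer matrix, cells in rows, antibodies in
#'   columns (column names required).
#' @param isotype_controls Character vector of isotype-control column names.
#' @param cell_qc Optional data.frame with columns `total_counts`,
#'   `detected_features`, `mito_fraction` (one row per cell).
#' @param qc_metrics Optional named numeric vector of antibody-library QC
#'   metrics (see [qc_metric_names()]).
#' @param empty_droplets Optional nonnegative matrix of ambient (empty
#'   droplet) counts with the same antibody columns.
#' @return An object of class `adt_sample`.
#' @export
adt_sample <- function(sample_id, counts, isotype_controls = character(),
                       cell_qc = NULL, qc_metrics = NULL,
                       empty_droplets = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("ADT counts need antibody column names", call. = FALSE)
  if (any(counts < 0)) stop("ADT counts must be nonnegative", call. = FALSE)
  if (!all(isotype_controls %in% colnames(counts))) {
    stop("isotype control columns absent from the count matrix", call. = FALSE)
  }
  if (!is.null(cell_qc)) {
    stopifnot(nrow(cell_qc) == nrow(counts),
              all(c("total_counts", "detected_features", "mito_fraction") %in% names(cell_qc)))
  }
  if (!is.null(empty_droplets)) {
    empty_droplets <- as.matrix(empty_droplets)
    stopifnot(identical(colnames(empty_droplets), colnames(counts)))
  }
  structure(list(sample_id = sample_id, counts = counts,
                 isotype_controls = isotype_controls, cell_qc = cell_qc,
                 qc_metrics = qc_metrics, empty_droplets = empty_droplets),
            class = "adt_sample")
}

#' Antigen (non-isotype) column names of an ADT sample
#' @param adt An [adt_sample()].
#' @return Character vector.
#' @export
antigen_names <- function(adt) {
  setdiff(colnames(adt$counts), adt$isotype_controls)
}

#' The 13 antibody-library QC metric names
#'
#' Sequencing and barcode-processing metrics reported for an antibody
#' capture library; used as artifact covariates in the bridge model.
#' @return Character vector of length 13.
#' @export
qc_metric_names <- function() {
  c("total_reads", "mean_reads_per_cell", "pct_valid_barcodes",
    "antibody_sequencing_saturation", "pct_q30_barcode",
    "pct_q30_antibody_read", "pct_q30_umi", "pct_reads_with_barcode",
    "pct_reads_antibody_valid_umi_cell", "pct_reads_aggregate_barcodes",
    "pct_reads_unrecognized_antibody",
    "pct_reads_antibody_valid_umi_cell_in_cells", "median_umis_per_cell")
}

#' Remove low-quality cells using the RNA library QC triple
#'
#' Cells with fewer than 1,000 total counts, fewer than 200 detected
#' features, or more than 15% mitochondrial expression are removed. The
#' thresholds are strict removal conditions: a cell sitting exactly on a
#' threshold is kept. Row order of the survivors is preserved, and the
#' filter is idempotent.
#'
#' @param adt An [adt_sample()] carrying `cell_qc`.
#' @param min_counts,min_features,max_mito Removal thresholds.
#' @return The filtered `adt_sample`.
#' @export
qc_filter_cells <- function(adt, min_counts = 1000, min_features = 200,
                            max_mito = 0.15) {
  stopifnot(inherits(adt, "adt_sample"))
  qc <- adt$cell_qc
  if (is.null(qc)) {
    warning("no per-cell RNA QC available for sample '", adt$sample_id,
            "'; cell filter skipped")
    return(adt)
  }
  keep <- !(qc$total_counts < min_counts | qc$detected_features < min_features |
              qc$mito_fraction > max_mito)
  out <- adt
  out$counts <- adt$counts[keep, , drop = FALSE]
  out$cell_qc <- qc[keep, , drop = FALSE]
  out
}

#' Centered log-ratio normalization of ADT counts
#'
#' Within each cell, `log(x + 1)` values are centered by their mean across
#' all antibodies, so every row of the result sums to zero.
#'
#' @param adt An [adt_sample()] or a nonnegative matrix (cells x antibodies).
#' @return Matrix of CLR values, same dimensions.
#' @export
clr_normalize <- function(adt) {
  x <- if (inherits(adt, "adt_sample")) adt$counts else as.matrix(adt)
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  lx <- log1p(x)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Background-corrected, technical-factor-denoised ADT normalization
#'
#' A two-step correction in the spirit of denoised-and-scaled-by-background
#' (DSB) normalization. Step 1: per antibody, `log(x + 1)` values are
#' z-scored against a background mean and SD, taken from an empty-droplet
#' (ambient) matrix when one is available and otherwise from the lowest
#' `background_quantile` of cells for that antibody (an in-sample proxy,
#' flagged in the result). Step 2: each cell's technical component is
#' estimated as the mean of its isotype-control z-scores and subtracted
#' from every antibody value of that cell.
#'
#' @param adt An [adt_sample()] with at least one isotype-control column.
#' @param background Optional empty-droplet count matrix (same antibody
#'   columns); overrides any matrix stored in `adt`.
#' @param background_quantile Fraction of lowest cells used for the
#'   in-sample background proxy (default 0.1).
#' @return Matrix of normalized values with attribute `background_source`
#'   (`"empty_droplets"` or `"low_cells_proxy"`); isotype columns included.
#' @export
dsb_normalize <- function(adt, background = NULL, background_quantile = 0.1) {
  stopifnot(inherits(adt, "adt_sample"))
  if (length(adt$isotype_controls) == 0L) {
    stop("DSB-style normalization needs at least one isotype control", call. = FALSE)
  }
  x <- log1p(adt$counts)
  background <- background %||% adt$empty_droplets
  if (!is.null(background)) {
    bg <- log1p(as.matrix(background)[, colnames(x), drop = FALSE])
    mu <- colMeans(bg)
    s <- apply(bg, 2L, sd)
    source <- "empty_droplets"
  } else {
    n_low <- max(2L, ceiling(background_quantile * nrow(x)))
    mu <- s <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
      low <- sort(x[, j], partial = n_low)[seq_len(n_low)]
      mu[j] <- mean(low)
      s[j] <- sd(low)
    }
    source <- "low_cells_proxy"
  }
  s[!is.finite(s) | s < 1e-8] <- 1
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  tech <- rowMeans(z[, adt$isotype_controls, drop = FALSE])
  out <- z - tech
  attr(out, "background_source") <- source
  out
}

#' Quantile-normalize cell profiles within a sample
#'
#' Classical matrix quantile normalization with cells as the normalized
#' units: every cell's value vector is replaced so all cells share the
#' common reference distribution (the mean of sorted profiles), preserving
#' ranks within each cell. Ties receive the average of the tied reference
#' values.
#'
#' @param mat Numeric matrix, cells in rows, antibodies in columns.
#' @return Matrix of the same dimensions.
#' @export
quantile_normalize_cells <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) return(mat)  # single antibody: nothing to normalize
  if (nrow(mat) < 2L) {
    stop("quantile normalization needs at least 2 cells", call. = FALSE)
  }
  # limma normalizes columns; our profiles are rows
  out <- t(limma::normalizeQuantiles(t(mat), ties = TRUE))
  dimnames(out) <- dimnames(mat)
  out
}

#' Normalize an ADT sample for the cross-modality bridge
#'
#' The normalization the quantile-mapping stage consumes: background/
#' technical correction via [dsb_normalize()] followed by
#' [quantile_normalize_cells()] over the antigen (non-isotype) columns.
#'
#' @param adt An [adt_sample()].
#' @param background Optional empty-droplet matrix passed to
#'   [dsb_normalize()].
#' @return Matrix cells x antigens of normalized ADT values.
#' @export
normalize_adt_for_bridge <- function(adt, background = NULL) {
  z <- dsb_normalize(adt, background = background)
  quantile_normalize_cells(z[, antigen_names(adt), drop = FALSE])
}

#' Read an ADT sample from a Matrix Market directory
#'
#' Expects `matrix.mtx` (antibodies x cells or cells x antibodies, see
#' `cells_in_rows`), `barcodes.tsv` and `features.tsv` (columns: id, name,
#' type, where type `"Isotype"` flags isotype controls), plus optional
#' `cell_qc.csv`, `qc_metrics.csv` and `empty_droplets.csv`.
#'
#' @param dir Directory path.
#' @param cells_in_rows Orientation of the MTX matrix (default `FALSE`,
#'   i.e. features x cells as written by common single-cell tools).
#' @return An [adt_sample()].
#' @export
read_adt_sample <- function(dir, cells_in_rows = FALSE) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  counts <- as.matrix(m)
  if (!cells_in_rows) counts <- t(counts)
  rownames(counts) <- barcodes
  colnames(counts) <- feats[[2]]
  iso <- feats[[2]][feats[[3]] == "Isotype"]
  cell_qc <- NULL
  qc_path <- file.path(dir, "cell_qc.csv")
  if (file.exists(qc_path)) cell_qc <- read.csv(qc_path, stringsAsFactors = FALSE)
  qcm <- NULL
  qcm_path <- file.path(dir, "qc_metrics.csv")
  if (file.exists(qcm_path)) {
    df <- read.csv(qcm_path, stringsAsFactors = FALSE)
    qcm <- unlist(df[1, qc_metric_names()])
  }
  empty <- NULL
  empty_path <- file.path(dir, "empty_droplets.csv")
  if (file.exists(empty_path)) {
    empty <- as.matrix(read.csv(empty_path, check.names = FALSE))
  }
  adt_sample(basename(dir), counts, isotype_controls = iso,
             cell_qc = cell_qc, qc_metrics = qcm, empty_droplets = empty)
}

#' Write an ADT sample as a Matrix Market directory
#'
#' @param adt An [adt_sample()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_adt_sample <- function(adt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- adt$counts
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  barcodes <- rownames(counts) %||% sprintf("cell-%05d", seq_len(nrow(counts)))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  type <- ifelse(colnames(counts) %in% adt$isotype_controls,
                 "Isotype", "Antibody Capture")
  write.table(data.frame(colnames(counts), colnames(counts), type),
              file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(adt$cell_qc)) {
    write.csv(adt$cell_qc, file.path(dir, "cell_qc.csv"), row.names = FALSE)
  }
  if (!is.null(adt$qc_metrics)) {
    write.csv(as.data.frame(as.list(adt$qc_metrics)),
              file.path(dir, "qc_metrics.csv"), row.names = FALSE)
  }
  if (!is.null(adt$empty_droplets)) {
    write.csv(as.data.frame(adt$empty_droplets),
              file.path(dir, "empty_droplets.csv"), row.names = FALSE)
  }
  invisible(dir)
}
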