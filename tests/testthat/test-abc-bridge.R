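test_that("quantile maps are identity maps for identical distributions", {
  set.seed(21)
  v <- rnorm(500, 3, 0.4)
  map <- build_quantile_map(10^v, v, sample_id = "s", antigen = "CD33")
  expect_equal(map$adt_quantiles, map$abc_log10_quantiles, tolerance = 1e-9)
  expect_length(map$grid, 19)
  # monotone along the grid
  expect_true(all(diff(map$adt_quantiles) >= 0))
  expect_true(all(diff(map$abc_log10_quantiles) >= 0))
})

test_that("quantile maps commute with monotone transforms", {
  set.seed(22)
  # n chosen so every 5% grid level lands exactly on an order statistic,
  # where empirical quantiles commute with any monotone transform
  adt <- rlnorm(401, 1, 0.5)
  map <- build_quantile_map(100 * adt, adt)
  expect_equal(map$abc_log10_quantiles, log10(100 * map$adt_quantiles),
               tolerance = 1e-9)
})

test_that("empirical quantiles match the order-statistic interpolation oracle", {
  x <- 1:100
  map <- build_quantile_map(10^x, x, grid = c(0.25, 0.5, 0.75))
  # linear interpolation between closest order statistics:
  # h = (n-1)p + 1; q = x[h0] + (h - h0) * (x[h0+1] - x[h0])
  oracle <- vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (100 - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  }, numeric(1))
  expect_equal(map$adt_quantiles, oracle, tolerance = 1e-12)
  expect_equal(map$abc_log10_quantiles, oracle, tolerance = 1e-12)
})

test_that("quantile map rejects bad input and warns on tiny samples", {
  expect_error(build_quantile_map(numeric(0), 1:5), "empty")
  expect_error(build_quantile_map(c(-1, 2), 1:2), "positive")
  expect_error(build_quantile_map(1:5, 1:5, grid = c(0.5, 0.2)), "increasing")
  expect_warning(build_quantile_map(1:5, 1:5), "interpolated")
})

fake_qc <- function(sample_ids, efficiency = NULL) {
  set.seed(23)
  rows <- lapply(seq_along(sample_ids), function(i) {
    e <- if (is.null(efficiency)) runif(1, 0.3, 1) else efficiency[i]
    v <- antigenbridge:::simulate_qc_metrics(e, 0.05)
    data.frame(sample_id = sample_ids[i], as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}

test_that("training table has one row per sample-antigen-level combination", {
  set.seed(24)
  sids <- c("s1", "s2")
  maps <- list()
  for (s in sids) for (a in c("CD33", "CLL-1", "CD123", "ADGRE2")) {
    maps[[paste(s, a)]] <- build_quantile_map(rlnorm(100, 6, 1), rnorm(100),
                                              sample_id = s, antigen = a)
  }
  qc <- fake_qc(sids)
  tab <- build_training_table(maps, qc)
  expect_equal(nrow(tab), 2 * 4 * 19)
  expect_true(all(c("adt_value", qc_metric_names(), "abc_log10") %in% names(tab)))
  expect_error(build_training_table(maps, qc[1, , drop = FALSE]), "s2")

  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$abc_log10, tab$abc_log10, tolerance = 1e-12)
  expect_equal(back$adt_value, tab$adt_value, tolerance = 1e-12)
})

linear_table <- function(n = 500, seed = 25) {
  set.seed(seed)
  # QC metrics vary across rows but carry no information about the target
  qc <- do.call(rbind, lapply(runif(n, 0.2, 1), function(e) {
    as.data.frame(as.list(antigenbridge:::simulate_qc_metrics(e, 0.05)))
  }))
  tab <- qc[sample(n), , drop = FALSE]
  tab$adt_value <- runif(n, -2, 2)
  tab$abc_log10 <- 2 + 0.8 * tab$adt_value
  tab$sample_id <- "s1"; tab$antigen <- "X"; tab$level <- NA_real_
  rownames(tab) <- NULL
  tab
}

test_that("the forest recovers a linear ADT-ABC relationship", {
  tab <- linear_table()
  # full-feature splits (bagged trees) isolate the regression capability:
  # with a single informative feature, subsampled splits mostly land on
  # noise covariates and inflate the error floor
  model <- train_model(tab, seed = 5, mtry = length(qc_metric_names()) + 1,
                       cv = TRUE, cv_repeats = 2)
  expect_lt(model$cv$rmse_mean, 0.1 * sd(tab$abc_log10))
})

test_that("a constant target yields constant predictions with a warning", {
  tab <- linear_table()
  tab$abc_log10 <- 3
  w <- capture_warnings(model <- train_model(tab, seed = 5, cv = FALSE))
  expect_match(w, "constant", all = FALSE)
  est <- predict_cell_abc(model,
                          matrix(rnorm(10), 10, 1, dimnames = list(NULL, "X")),
                          tab[1, qc_metric_names()])
  expect_equal(unname(est$counts[, 1]), rep(1000, 10), tolerance = 1e-9)
  expect_true(all(est$counts > 0))
})

test_that("training and prediction are deterministic under a fixed seed", {
  tab <- linear_table(n = 200)
  m1 <- train_model(tab, seed = 42, cv = TRUE, cv_folds = 5, cv_repeats = 1)
  m2 <- train_model(tab, seed = 42, cv = TRUE, cv_folds = 5, cv_repeats = 1)
  expect_equal(m1$cv, m2$cv)
  newx <- matrix(seq(-1, 1, length.out = 20), 20, 1,
                 dimnames = list(NULL, "X"))
  p1 <- predict_cell_abc(m1, newx, tab[1, qc_metric_names()])
  p2 <- predict_cell_abc(m2, newx, tab[1, qc_metric_names()])
  expect_identical(p1$counts, p2$counts)
})

test_that("per-cell predictions track the trained identity relationship", {
  tab <- linear_table()
  model <- train_model(tab, seed = 6, cv = TRUE, cv_repeats = 1)
  cells <- matrix(runif(200, -1.5, 1.5), ncol = 1,
                  dimnames = list(NULL, "X"))
  est <- predict_cell_abc(model, cells, tab[1, qc_metric_names()],
                          sample_id = "s1")
  resid <- log10(est$counts[, "X"]) - (2 + 0.8 * cells[, 1])
  expect_lt(sqrt(mean(resid^2)), 3 * model$cv$rmse_mean + 0.05)
  expect_error(predict_cell_abc(model, cells, tab[1, qc_metric_names()],
                                antigens = "missing"), "absent")
})

test_that("predictions are clipped to the training range plus 0.5 log10", {
  tab <- linear_table()
  model <- train_model(tab, seed = 7, cv = FALSE)
  hi <- max(tab$abc_log10) + 0.5
  lo <- min(tab$abc_log10) - 0.5
  cells <- matrix(c(-50, 50), ncol = 1, dimnames = list(NULL, "X"))
  est <- predict_cell_abc(model, cells, tab[1, qc_metric_names()])
  expect_true(all(log10(est$counts) <= hi + 1e-9))
  expect_true(all(log10(est$counts) >= lo - 1e-9))
})

test_that("sample-mean predictions recover the true antigen abundances", {
  co <- small_cohort()
  inp <- prepare_bridge_inputs(co)
  tab <- build_training_table(inp$maps, inp$qc)
  model <- train_model(tab, seed = 8, cv = FALSE)
  rows <- list()
  for (sid in names(co$samples)) {
    est <- predict_cell_abc(model, inp$normalized[[sid]],
                            inp$qc[match(sid, inp$qc$sample_id), ],
                            sample_id = sid)
    rows[[sid]] <- data.frame(pred = colMeans(est$counts),
                              truth = colMeans(co$samples[[sid]]$truth))
  }
  df <- do.call(rbind, rows)
  expect_gte(nrow(df), 20)
  expect_gte(cor(df$pred, df$truth, method = "spearman"), 0.9)
})

test_that("leave-one-antigen-out is structured per excluded antigen without leakage", {
  co <- small_cohort()
  inp <- prepare_bridge_inputs(co)
  res <- leave_one_antigen_out(inp$maps, inp$qc, inp$normalized,
                               inp$flow_means, seed = 9, ntree = 150)
  expect_setequal(res$report$antigen, co$config$bridge_antigens)
  expect_equal(nrow(res$report), 4)
  expect_equal(unique(res$report$n_samples), length(co$samples))
  # leakage check: the excluded antigen's rows are absent from its
  # iteration's training table
  for (a in co$config$bridge_antigens) {
    keep <- vapply(inp$maps, function(m) m$antigen != a, logical(1))
    tab <- build_training_table(inp$maps[keep], inp$qc)
    expect_false(a %in% tab$antigen)
  }
  short <- inp$maps[vapply(inp$maps, function(m) m$antigen == "CD33", logical(1))]
  expect_error(leave_one_antigen_out(short, inp$qc, inp$normalized,
                                     inp$flow_means), "at least 2")
})
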