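named_counts <- function(v) setNames(v, lineage_states()[seq_along(v)])

test_that("Shannon index reaches ln(9) only at the uniform composition", {
  expect_equal(shannon_index(setNames(rep(10, 9), lineage_states())), log(9),
               tolerance = 1e-12)
  expect_equal(floor(shannon_index(setNames(rep(1, 9), lineage_states())) *
                       100) / 100, 2.19)
  one <- setNames(c(50, rep(0, 8)), lineage_states())
  expect_equal(shannon_index(one), 0)
  expect_equal(shannon_index(named_counts(c(5, 5))), log(2), tolerance = 1e-12)

  set.seed(41)
  for (r in 1:20) {
    x <- setNames(rpois(9, 20) + 1, lineage_states())
    expect_lte(shannon_index(x), log(9) + 1e-12)
  }
  expect_error(shannon_index(setNames(rep(0, 9), lineage_states())), "zero")
})

test_that("Aitchison distance matches hand computation and the CLR oracle", {
  x <- named_counts(c(1, 1)); y <- named_counts(c(1, 4))
  expect_equal(aitchison_distance(x, y), sqrt(2) * log(2), tolerance = 1e-10)
  expect_equal(aitchison_distance(x, x), 0)

  set.seed(42)
  for (r in 1:25) {
    a <- setNames(rpois(9, 50) + 1, lineage_states())
    b <- setNames(rpois(9, 50) + 1, lineage_states())
    pa <- a / sum(a); pb <- b / sum(b)
    clr <- function(p) log(p) - mean(log(p))
    oracle <- sqrt(sum((clr(pa) - clr(pb))^2))
    expect_equal(aitchison_distance(a, b), oracle, tolerance = 1e-10)
    # vegan computes the same distance from the raw compositions
    expect_equal(aitchison_distance(a, b),
                 as.numeric(vegan::vegdist(rbind(pa, pb), method = "aitchison")),
                 tolerance = 1e-10)
  }
  expect_error(aitchison_distance(a, setNames(b, rev(names(b)))), "vocabular")
})

test_that("Aitchison distance is a metric, scale invariant and zero-safe", {
  set.seed(43)
  for (r in 1:15) {
    a <- setNames(rpois(9, 30) + 1, lineage_states())
    b <- setNames(rpois(9, 30) + 1, lineage_states())
    c_ <- setNames(rpois(9, 30) + 1, lineage_states())
    dab <- aitchison_distance(a, b)
    expect_equal(dab, aitchison_distance(b, a), tolerance = 1e-12)
    expect_lte(dab, aitchison_distance(a, c_) + aitchison_distance(c_, b) + 1e-12)
    expect_equal(aitchison_distance(a * 17, b), dab, tolerance = 1e-10)
  }
  # zeros receive the pseudocount, keeping the distance finite and
  # continuous as the count crosses the pseudocount value
  z <- setNames(c(0, rep(20, 8)), lineage_states())
  w <- setNames(c(10, rep(20, 8)), lineage_states())
  expect_true(is.finite(aitchison_distance(z, w)))
  expect_equal(aitchison_distance(z, w), 0, tolerance = 1e-12)
  # the +10-to-all variant remains available
  expect_true(is.finite(aitchison_distance(z, w, zeros_only = FALSE)))
})

test_that("fraction bootstrap reproduces the full-data distance at 100%", {
  set.seed(44)
  diag_l <- sample(lineage_states(), 600, replace = TRUE,
                   prob = c(5, 4, 3, 2, 2, 1, 1, 1, 1))
  rel_l <- sample(lineage_states(), 600, replace = TRUE,
                  prob = c(1, 1, 1, 2, 2, 3, 4, 5, 1))
  full <- aitchison_distance(composition_from_labels(diag_l),
                             composition_from_labels(rel_l))
  curve <- bootstrap_distance_curve(diag_l, rel_l, fractions = c(0.25, 1),
                                    reps = 10, seed = 1)
  expect_equal(curve$mean_distance[curve$fraction == 1], full, tolerance = 1e-12)
  expect_equal(curve$sd_distance[curve$fraction == 1], 0, tolerance = 1e-12)

  # identical pools: zero distance at full resampling
  same <- bootstrap_distance_curve(diag_l, diag_l, fractions = 1, reps = 3,
                                   seed = 1)
  expect_equal(same$mean_distance, 0, tolerance = 1e-12)

  expect_error(bootstrap_distance_curve(diag_l, rel_l, fractions = c(0, 0.5)),
               "fractions")
  expect_error(bootstrap_distance_curve(character(0), rel_l), "empty")
})

test_that("fixed-size bootstrap is consistent, seeded and degenerates to zero", {
  set.seed(45)
  pool_d <- sample(lineage_states(), 344, replace = TRUE)
  pool_r <- sample(lineage_states(), 344, replace = TRUE,
                   prob = c(6, 1, 1, 1, 1, 1, 1, 1, 1))
  pairs <- list(list(patient_id = "P1", diag_labels = pool_d,
                     relapse_labels = pool_r))
  full <- aitchison_distance(composition_from_labels(pool_d),
                             composition_from_labels(pool_r))
  bs <- fixed_size_bootstrap(pairs, n = 344, reps = 200, seed = 2)
  mc_se <- sd(bs$replicates$distance) / sqrt(200)
  # resampling with replacement is a noisy but nearly unbiased estimate of
  # the full-data distance at this pool size
  expect_lt(abs(bs$patient_means$mean_distance - full),
            2 * mc_se + 0.05 * full)

  bs2 <- fixed_size_bootstrap(pairs, n = 344, reps = 200, seed = 2)
  expect_identical(bs$replicates, bs2$replicates)

  single <- list(list(patient_id = "P2",
                      diag_labels = rep("HSC-like", 50),
                      relapse_labels = rep("HSC-like", 40)))
  bs3 <- fixed_size_bootstrap(single, n = 344, reps = 20, seed = 3)
  expect_true(all(bs3$replicates$distance == 0))
})

test_that("labels map to counts on the fixed vocabulary", {
  counts <- composition_from_labels(c("HSC-like", "HSC-like", "GMP-like"))
  expect_equal(unname(counts[1:3]), c(2, 1, 0))
  expect_equal(sum(counts), 3)
  expect_error(composition_from_labels(c("HSC-like", "weird")), "vocabulary")
})
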