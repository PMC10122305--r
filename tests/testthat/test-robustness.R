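make_tiny_dataset <- function(seed = 1L) {
  bench <- tiny_benchmark(seed = seed)
  prepare_dataset(bench$profile, bench$pairs, tl = 6)
}

test_that("noise injection corrupts exactly the rounded fraction of pairs", {
  ds <- make_tiny_dataset(2)
  n <- nrow(ds$pairs)
  out <- inject_noise(ds, fraction = 0.05, seed = 4)
  changed <- sum(out$pairs$tf_series != ds$pairs$tf_series)
  hit <- round(0.05 * n)
  expect_lte(changed, hit)           # a replacement can draw the same gene
  expect_gte(changed, hit * 0.5)
  expect_identical(out$pairs$label, ds$pairs$label)  # labels untouched
  expect_identical(out$pairs$gene_series, ds$pairs$gene_series)
  # purity: the input dataset is unchanged
  expect_identical(ds$pairs$tf_series, ds$pairs$tf)
  # determinism
  out2 <- inject_noise(ds, fraction = 0.05, seed = 4)
  expect_identical(out$pairs, out2$pairs)
  expect_error(inject_noise(ds, fraction = 1e-4, seed = 1), "zero")
})

test_that("subsampling preserves prevalence within one pair", {
  ds <- make_tiny_dataset(3)
  n <- nrow(ds$pairs)
  out <- subsample_pairs(ds, fraction = 0.7, seed = 5)
  expect_equal(nrow(out$pairs), round(0.7 * n))
  expect_equal(sum(out$pairs$label), round(0.7 * sum(ds$pairs$label)))
  expect_identical(subsample_pairs(ds, fraction = 1, seed = 1)$pairs, ds$pairs)
  o1 <- subsample_pairs(ds, fraction = 0.7, seed = 6)
  o2 <- subsample_pairs(ds, fraction = 0.7, seed = 7)
  expect_false(identical(o1$pairs, o2$pairs))
})

test_that("repeated experiments report recomputable summaries", {
  ds <- make_tiny_dataset(4)
  rep1 <- repeat_experiment("original", ds, tiny_config(), n_repeats = 1,
                            base_seed = 9, epochs = 1, batch_size = 32,
                            patience = 1)
  expect_equal(rep1$variance, 0)
  rep2 <- repeat_experiment("noise", ds, tiny_config(), n_repeats = 2,
                            base_seed = 9, epochs = 1, batch_size = 32,
                            patience = 1)
  expect_equal(rep2$mean, mean(rep2$aupr), tolerance = 1e-12)
  expect_equal(rep2$variance,
               mean((rep2$aupr - mean(rep2$aupr))^2), tolerance = 1e-12)
  expect_length(rep2$aupr, 2L)
  rep3 <- repeat_experiment("noise", ds, tiny_config(), n_repeats = 2,
                            base_seed = 9, epochs = 1, batch_size = 32,
                            patience = 1)
  expect_identical(rep2$aupr, rep3$aupr)  # same base seed, same report
})

test_that("condition transforms never mutate the base dataset", {
  ds <- make_tiny_dataset(5)
  snapshot <- ds$pairs
  invisible(inject_noise(ds, 0.05, seed = 1))
  invisible(subsample_pairs(ds, 0.7, seed = 1))
  invisible(repeat_experiment("incomplete", ds, tiny_config(), n_repeats = 1,
                              base_seed = 2, epochs = 1, batch_size = 32,
                              patience = 1))
  expect_identical(ds$pairs, snapshot)
})

test_that("the ablation harness pairs seeds across variants", {
  ds <- make_tiny_dataset(6)
  ab <- ablation_suite(ds, c("PSGRN", "FM-DN"), base = tiny_config(),
                       n_repeats = 1, base_seed = 3, epochs = 1,
                       batch_size = 32, patience = 1)
  expect_named(ab$reports, c("PSGRN", "FM-DN"))
  expect_identical(ab$reports$PSGRN$seeds, ab$reports$`FM-DN`$seeds)
  expect_equal(nrow(ab$ranking), 2L)
  expect_true(all(diff(ab$ranking$mean_aupr) <= 0))
  single <- repeat_experiment("original", ds, tiny_config(), n_repeats = 1,
                              base_seed = 3, epochs = 1, batch_size = 32,
                              patience = 1)
  expect_equal(ab$reports$PSGRN$aupr, single$aupr)
  expect_error(ablation_suite(ds, "NOPE", base = tiny_config()),
               "valid names")
})
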