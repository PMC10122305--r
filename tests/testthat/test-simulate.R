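test_that("simulated networks have exactly the rounded edge count", {
  cfg <- simulation_config(n_genes = 506, n_tfs = 101, density = 0.190,
                           seed = 2)
  grn <- simulate_grn(cfg)
  expect_equal(nrow(grn), round(0.190 * 101 * 506))  # 9710
  expect_equal(round(network_density(nrow(grn), 101, 506), 3), 0.190)
  expect_true(all(grn$p_value < 0.01))
  expect_false(anyDuplicated(paste(grn$tf, grn$target)) > 0)
  # every simulated edge survives the credibility filter
  expect_equal(nrow(filter_credible_edges(grn)), nrow(grn))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- simulation_config(n_genes = 30, n_tfs = 6, density = 0.2, seed = 7)
  expect_identical(simulate_grn(cfg), simulate_grn(cfg))
  cfg2 <- cfg; cfg2$seed <- 8L
  e1 <- simulate_grn(cfg); e2 <- simulate_grn(cfg2)
  expect_false(identical(e1, e2))
  p1 <- simulate_expression(e1, cfg)
  p2 <- simulate_expression(e1, cfg)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("degenerate densities are rejected", {
  expect_error(simulation_config(n_genes = 30, n_tfs = 6, density = 0),
               "density")
  cfg <- simulation_config(n_genes = 30, n_tfs = 6, density = 0.002)
  expect_error(simulate_grn(cfg), "zero edges")
})

test_that("null generator makes regulated and unregulated genes alike", {
  cfg <- simulation_config(n_genes = 20, n_tfs = 4, density = 0.25,
                           effect_size = 0, noise_sd = 0, seed = 3)
  grn <- simulate_grn(cfg)
  prof <- simulate_expression(grn, cfg)
  regulated <- unique(grn$target)
  others <- setdiff(gene_ids(prof), c(regulated, unique(grn$tf)))
  # with no effect and no noise every gene is a pure baseline course:
  # distributional identity checked through matching moment ranges
  v <- unclass(prof)
  expect_true(all(v >= 0))
  rng_reg <- range(apply(v[regulated, , drop = FALSE], 1, sd))
  rng_oth <- range(apply(v[others, , drop = FALSE], 1, sd))
  expect_lt(max(rng_reg) / max(rng_oth), 3)
  expect_gt(min(rng_reg) / min(rng_oth), 1 / 3)
})

test_that("with baselines silenced a target is the lag-shifted regulator", {
  cfg <- simulation_config(n_genes = 12, n_tfs = 3, density = 0.2,
                           n_timepoints = 40, signal_lag = 5,
                           effect_size = 1.5, noise_sd = 0,
                           target_baseline_scale = 0, seed = 9)
  grn <- simulate_grn(cfg)
  # pick a target with exactly one regulator that is itself unregulated
  deg <- table(grn$target)
  singles <- names(deg)[deg == 1 & !(names(deg) %in% grn$target[grn$tf %in% names(deg)])]
  singles <- setdiff(singles, grn$tf)
  skip_if(length(singles) == 0, "no single-regulator target in this draw")
  tgt <- singles[1]
  tf <- grn$tf[grn$target == tgt]
  prof <- simulate_expression(grn, cfg)
  v <- unclass(prof)
  t_idx <- (cfg$signal_lag + 1):cfg$n_timepoints
  expected <- cfg$effect_size * v[tf, t_idx - cfg$signal_lag]
  got <- v[tgt, t_idx]
  # the smooth non-negativity floor is indistinguishable from identity for
  # values well above zero
  big <- expected > 1
  expect_true(any(big))
  expect_lt(max(abs(got[big] - expected[big]) / expected[big]), 1e-6)
  # before the lag has elapsed the silenced target sits at the floor
  expect_true(all(v[tgt, 1:cfg$signal_lag] < 0.1))
})

test_that("the default benchmark meets its documented contract", {
  bench <- make_benchmark(simulation_config(seed = 12))
  expect_equal(dim(unclass(bench$profile)), c(60L, 107L))
  expect_true(all(is.finite(unclass(bench$profile))))
  expect_true(all(rowMeans(bench$profile) >= 1))
  expect_equal(nrow(bench$pairs), 720L)
  # label prevalence equals the configured density up to edge rounding
  expect_equal(mean(bench$pairs$label), round(0.15 * 720) / 720)
})

test_that("benchmark files are byte-identical across same-seed calls", {
  cfg <- simulation_config(n_genes = 15, n_tfs = 3, density = 0.2,
                           n_timepoints = 30, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_benchmark(cfg, dir = d1)
  make_benchmark(cfg, dir = d2)
  for (f in c("expression.tsv", "edges.tsv", "labels.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  cfg2 <- cfg; cfg2$seed <- 5L
  b2 <- make_benchmark(cfg2)
  b1 <- make_benchmark(cfg)
  expect_false(identical(b1$edges, b2$edges))
})

test_that("true edges carry more lagged cross-correlation than non-edges", {
  cfg <- simulation_config(seed = 31)  # default study conditions
  bench <- make_benchmark(cfg)
  dv <- t(apply(unclass(bench$profile), 1, diff))
  n <- ncol(dv)
  lag <- cfg$signal_lag
  lc <- function(tf, tg) {
    suppressWarnings(abs(cor(dv[tf, 1:(n - lag)], dv[tg, (lag + 1):n])))
  }
  pos <- bench$pairs[bench$pairs$label == 1, ]
  neg <- bench$pairs[bench$pairs$label == 0, ]
  set.seed(31)
  neg <- neg[sample(nrow(neg), min(1000, nrow(neg))), ]
  m_pos <- mean(mapply(lc, pos$tf, pos$gene))
  m_neg <- mean(mapply(lc, neg$tf, neg$gene))
  expect_gt(m_pos, m_neg)
})
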