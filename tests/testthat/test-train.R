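test_that("stratified split hits exact 3:1:1 counts per label class", {
  pairs <- data.frame(label = c(rep(1, 190), rep(0, 810)))
  sp <- stratified_split(pairs, seed = 3)
  expect_equal(as.vector(table(sp)), c(600L, 200L, 200L))
  pos <- table(sp[pairs$label == 1])
  expect_equal(as.vector(pos), c(114L, 38L, 38L))
})

test_that("stratified split is deterministic and a partition", {
  pairs <- data.frame(label = rbinom(203, 1, 0.2))
  pairs$label[1:6] <- 1
  expect_identical(stratified_split(pairs, seed = 11),
                   stratified_split(pairs, seed = 11))
  for (s in 1:20) {
    sp <- stratified_split(pairs, seed = s)
    expect_equal(length(sp), nrow(pairs))
    expect_false(anyNA(sp))  # disjoint and exhaustive by construction
    counts <- table(sp)
    expect_equal(sum(counts), nrow(pairs))
    # per-split prevalence within one pair of exact stratification
    for (lev in levels(sp)) {
      got <- sum(pairs$label[sp == lev])
      want <- sum(pairs$label) * counts[[lev]] / nrow(pairs)
      expect_lte(abs(got - want), 1)
    }
  }
})

test_that("splitting requires both labels", {
  expect_error(stratified_split(data.frame(label = rep(1, 20))),
               "at least 5")
})

test_that("training runs, records history, and is seed-reproducible", {
  bench <- tiny_benchmark(seed = 5)
  ds <- prepare_dataset(bench$profile, bench$pairs, tl = 6)
  sp <- stratified_split(ds$pairs, seed = 5)
  fit1 <- psgrn_train(tiny_config(seed = 5), ds, sp, epochs = 2,
                      batch_size = 32, patience = 5, seed = 5)
  expect_equal(nrow(fit1$history), 2L)
  expect_true(all(is.finite(fit1$history$train_loss)))
  expect_true(all(fit1$history$val_aupr >= 0 & fit1$history$val_aupr <= 1))
  fit2 <- psgrn_train(tiny_config(seed = 5), ds, sp, epochs = 2,
                      batch_size = 32, patience = 5, seed = 5)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  s1 <- predict_pairs(fit1, ds, sp, subset = "test")
  s2 <- predict_pairs(fit2, ds, sp, subset = "test")
  expect_identical(s1, s2)
})

test_that("evaluation reports metrics and a coherent confusion at top-k", {
  bench <- tiny_benchmark(seed = 6)
  ds <- prepare_dataset(bench$profile, bench$pairs, tl = 6)
  sp <- stratified_split(ds$pairs, seed = 6)
  fit <- psgrn_train(tiny_config(seed = 6), ds, sp, epochs = 1,
                     batch_size = 32, patience = 2, seed = 6)
  ev <- evaluate_pairs(fit, ds, split = NULL, subset = "all", top_k = 30)
  n <- nrow(ds$pairs)
  expect_equal(sum(ev$confusion), n)
  expect_equal(ev$confusion[["TP"]] + ev$confusion[["FN"]],
               sum(ds$pairs$label))
  expect_gte(sum(ev$scores$score >= ev$threshold), 30)
  expect_true(all(diff(ev$scores$score) <= 0))  # sorted descending
  expect_gte(ev$aupr, 0); expect_lte(ev$aupr, 1)
  expect_gte(ev$auroc, 0); expect_lte(ev$auroc, 1)
})
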