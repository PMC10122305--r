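test_that("configuration validates the merge/spatial combination", {
  expect_error(psgrn_config(merge = "multiply"), "only valid")
  cfg <- psgrn_config(merge = "multiply", spatial_type = "none")
  expect_s3_class(cfg, "psgrn_config")
})

test_that("variants mutate the base configuration as defined", {
  base <- tiny_config()
  ps <- build_variant("PSGRN", base)
  expect_equal(ps$branch_type, "gru")
  expect_equal(ps$spatial_type, "densenet")
  expect_equal(ps$head, "sigmoid")
  expect_equal(ps$merge, "concat_rows")
  expect_equal(build_variant("FM-DN", base)$branch_type, "none")
  expect_equal(build_variant("RNN-DN", base)$branch_type, "rnn")
  expect_equal(build_variant("LSTM-DN", base)$branch_type, "lstm")
  fg <- build_variant("FM-GRU", base)
  expect_equal(fg$spatial_type, "none")
  expect_equal(fg$merge, "multiply")
  expect_equal(build_variant("GRU-VGG", base)$spatial_type, "vgg")
  expect_equal(build_variant("GRU-RN", base)$spatial_type, "resnet")
  sm <- build_variant("PS-SM", base)
  expect_equal(sm$head, "softmax")
  sm$head <- "sigmoid"
  expect_equal(unclass(sm), unclass(ps))  # PS-SM differs only in the head
  expect_error(build_variant("GRU-GRU", base), "valid names")
})

test_that("model building is a deterministic function of the seed", {
  m1 <- psgrn_model(tiny_config(seed = 5), input_steps = 10)
  m2 <- psgrn_model(tiny_config(seed = 5), input_steps = 10)
  m3 <- psgrn_model(tiny_config(seed = 6), input_steps = 10)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("branch encoding honours the shape contract", {
  cfg <- tiny_config()
  m <- psgrn_model(cfg, input_steps = 12)
  fm <- matrix(rnorm(12 * cfg$tl), 12, cfg$tl)
  h <- encode_branch(m, fm, "tf_branch")
  expect_equal(dim(h), c(12L, cfg$hidden_dim))
  expect_error(encode_branch(m, fm[1:5, ]), "must be 12 x 6")
})

test_that("zero input with zero biases is a fixed point of the gated cell", {
  cfg <- tiny_config()
  m <- psgrn_model(cfg, input_steps = 9)
  z <- matrix(0, 9, cfg$tl)
  expect_true(all(encode_branch(m, z, "tf_branch") == 0))
  expect_true(all(encode_branch(m, z, "target_branch") == 0))
})

test_that("one gated step matches the four gate equations evaluated by hand", {
  cfg <- psgrn_config(tl = 1, hidden_dim = 1, dense_blocks = 1,
                      block_layers = 1, growth_rate = 2, stem_channels = 2,
                      stem_pool = FALSE, head_units = 2, seed = 1)
  m <- psgrn_model(cfg, input_steps = 2)
  m$params$tf_Wx <- matrix(c(0.3, -0.2, 0.5), 1, 3)
  m$params$tf_Wh <- matrix(c(0.4, -0.3, 0.2), 1, 3)
  m$params$tf_b <- c(0.1, 0.2, -0.1)
  x1 <- 0.7
  h <- encode_branch(m, matrix(c(x1, -0.4), 2, 1), "tf_branch")
  # step 1 from h0 = 0: h1 = z1 * tanh(candidate), reset gate irrelevant
  sig <- function(u) 1 / (1 + exp(-u))
  z1 <- sig(-0.2 * x1 + 0.2)
  c1 <- tanh(0.5 * x1 - 0.1)
  expect_equal(h[1, 1], z1 * c1, tolerance = 1e-12)
  # step 2 uses all four equations with h1 as the previous state
  x2 <- -0.4
  r2 <- sig(0.3 * x2 + 0.4 * h[1, 1] + 0.1)
  z2 <- sig(-0.2 * x2 - 0.3 * h[1, 1] + 0.2)
  c2 <- tanh(0.5 * x2 + 0.2 * r2 * h[1, 1] - 0.1)
  expect_equal(h[2, 1], (1 - z2) * h[1, 1] + z2 * c2, tolerance = 1e-12)
})

test_that("the two branches hold independent parameters", {
  cfg <- tiny_config()
  m <- psgrn_model(cfg, input_steps = 10)
  fm <- matrix(rnorm(10 * cfg$tl), 10, cfg$tl)
  before <- encode_branch(m, fm, "target_branch")
  m$params$tf_Wx <- m$params$tf_Wx * 2 + 0.3
  m$params$tf_Wh <- m$params$tf_Wh * -1
  expect_identical(encode_branch(m, fm, "target_branch"), before)
  expect_false(identical(encode_branch(m, fm, "tf_branch"), before))
})

test_that("merging stacks TF rows first or multiplies", {
  a <- matrix(1:6, 3, 2)
  b <- matrix(7:12, 3, 2)
  cc <- merge_branches(a, b, "concat_rows")
  expect_equal(dim(cc), c(6L, 2L))
  expect_equal(cc[1:3, ], a)
  expect_false(identical(merge_branches(b, a, "concat_rows"), cc))
  mm <- merge_branches(a, a, "multiply")
  expect_equal(mm, t(mm))  # symmetric product for identical inputs
  expect_equal(merge_branches(a, b, "multiply"), a %*% t(b))
  expect_error(merge_branches(a, b[1:2, ]), "identical shapes")
})

test_that("dense connectivity gives layer k an input of c0 + (k-1) * growth", {
  cfg <- tiny_config()
  m <- psgrn_model(cfg, input_steps = 10)
  for (l in seq_len(cfg$block_layers)) {
    expect_equal(nrow(m$params[[sprintf("b1l%d_K", l)]]),
                 9L * (cfg$stem_channels + (l - 1L) * cfg$growth_rate))
  }
})

test_that("spatial feature length under gap pooling ignores the input size", {
  cfg <- tiny_config(pooling = "gap")
  m1 <- psgrn_model(cfg, input_steps = 10)
  m2 <- psgrn_model(cfg, input_steps = 17)
  expect_equal(m1$dims$feat_len, m2$dims$feat_len)
  # channel plan: stem 4, block1 +8 = 12, transition floor(12/2) = 6,
  # block2 +8 = 14
  expect_equal(m1$dims$feat_len, 14L)
  fm <- matrix(rnorm(20 * cfg$tl), 20, cfg$tl)
  v <- spatial_module(m1, fm)
  expect_length(v, 14L)
})

test_that("too-small merged inputs are rejected with the minimum stated", {
  cfg <- tiny_config()  # one transition needs >= 2x2 there
  expect_error(psgrn_model(cfg, input_steps = 1), ">= 2x2")
})

test_that("pair scores are probabilities, deterministic, and direction-sensitive", {
  cfg <- tiny_config()
  m <- psgrn_model(cfg, input_steps = 10)
  set.seed(31)
  f1 <- matrix(rnorm(10 * cfg$tl), 10, cfg$tl)
  f2 <- matrix(rnorm(10 * cfg$tl), 10, cfg$tl)
  s1 <- predict_pair(m, f1, f2, "tfA", "geneB")
  expect_gt(s1$score, 0); expect_lt(s1$score, 1)
  expect_identical(predict_pair(m, f1, f2)$score, s1$score)
  s2 <- predict_pair(m, f2, f1)
  expect_false(identical(s1$score, s2$score))
  expect_error(predict_pair(m, f1[1:3, ], f2), "fm_tf")
})

test_that("softmax head also yields a probability for the positive class", {
  cfg <- tiny_config()
  cfg$head <- "softmax"
  m <- psgrn_model(cfg, input_steps = 10)
  f1 <- matrix(rnorm(10 * cfg$tl), 10, cfg$tl)
  s <- predict_pair(m, f1, f1)$score
  expect_gt(s, 0); expect_lt(s, 1)
})

test_that("binary cross-entropy matches its closed form", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(0, 0.5), bce_loss(1, 0.5))
  expect_error(bce_loss(c(1, 0), 0.5), "equal length")
})

test_that("compiled recurrent kernels agree with the plain-R reference", {
  set.seed(13)
  X <- array(rnorm(3 * 7 * 4), c(3, 7, 4))
  dH <- array(rnorm(3 * 7 * 5), c(3, 7, 5))
  for (cell in c("rnn", "gru", "lstm")) {
    p <- psgrn:::init_recurrent_params(4, 5, psgrn:::n_gates_for(cell))
    a <- psgrn:::rnn_forward(X, p, cell)
    b <- psgrn:::rnn_forward_ref(X, p, cell)
    expect_equal(a$H, b$H, tolerance = 1e-12)
    ga <- psgrn:::rnn_backward(dH, p, a$cache)
    gb <- psgrn:::rnn_backward_ref(dH, p, b$cache)
    expect_equal(ga$Wx, gb$Wx, tolerance = 1e-10)
    expect_equal(ga$Wh, gb$Wh, tolerance = 1e-10)
    expect_equal(ga$b, gb$b, tolerance = 1e-10)
  }
})

test_that("compiled convolution agrees with the plain-R reference", {
  set.seed(14)
  X <- array(rnorm(2 * 9 * 6 * 3), c(2, 9, 6, 3))
  K <- psgrn:::init_conv(3, 3, 3, 4)
  b <- rnorm(4)
  for (s in 1:2) for (pd in 0:1) {
    fa <- psgrn:::conv_forward(X, K, b, 3L, 3L, s, pd)
    fb <- psgrn:::conv_forward_ref(X, K, b, 3L, 3L, s, pd)
    expect_equal(fa$Y, fb$Y, tolerance = 1e-12)
    dY <- array(rnorm(length(fa$Y)), dim(fa$Y))
    ba <- psgrn:::conv_backward(dY, K, fa$cache)
    bb <- psgrn:::conv_backward_ref(dY, K, fb$cache)
    expect_equal(ba$dX, bb$dX, tolerance = 1e-12)
    expect_equal(ba$dK, bb$dK, tolerance = 1e-12)
    expect_equal(ba$db, bb$db, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences on tiny models", {
  set.seed(77)
  steps <- 9L
  for (variant in c("PSGRN", "FM-GRU", "PS-SM")) {
    cfg <- build_variant(variant, tiny_config(seed = 7))
    cfg$hidden_dim <- 4L
    m <- psgrn_model(cfg, input_steps = steps)
    B <- 2L
    Xtf <- array(rnorm(B * steps * cfg$tl), c(B, steps, cfg$tl))
    Xtg <- array(rnorm(B * steps * cfg$tl), c(B, steps, cfg$tl))
    y <- c(1, 0)
    fw <- psgrn:::model_forward(m, Xtf, Xtg, keep_cache = TRUE)
    an <- psgrn:::model_backward(m, fw$cache, y)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      bce_loss(y, psgrn:::model_forward(m2, Xtf, Xtg, FALSE)$prob)
    }
    for (nm in c("tf_Wh", "fc1_W", "fc2_b",
                 grep("_K$", names(m$params), value = TRUE)[1])) {
      p0 <- m$params[[nm]]
      ii <- if (length(p0) > 6) sort(sample(length(p0), 6)) else seq_along(p0)
      for (i in ii) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
        num <- (loss_at(pp) - loss_at(pm)) / 2e-5
        expect_equal(an[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("grouped forward/backward equals the per-pair path exactly", {
  bench <- tiny_benchmark(seed = 21)
  ds <- prepare_dataset(bench$profile, bench$pairs, tl = 6)
  cfg <- tiny_config(seed = 3)
  m <- psgrn_model(cfg, input_steps = nrow(ds$features[[1]]))
  rows <- 1:20
  y <- ds$pairs$label[rows]
  Xtf <- psgrn:::stack_features(ds$features, ds$pairs$tf_series[rows])
  Xtg <- psgrn:::stack_features(ds$features, ds$pairs$gene_series[rows])
  f1 <- psgrn:::model_forward(m, Xtf, Xtg, TRUE)
  f2 <- psgrn:::model_forward_grouped(m, ds$features, ds$pairs$tf_series[rows],
                                      ds$pairs$gene_series[rows], TRUE)
  expect_equal(f1$prob, f2$prob, tolerance = 1e-12)
  g1 <- psgrn:::model_backward(m, f1$cache, y)
  g2 <- psgrn:::model_backward_grouped(m, f2$cache, y)
  for (nm in names(g1)) expect_equal(g1[[nm]], g2[[nm]], tolerance = 1e-10)
})
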