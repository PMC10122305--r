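#' Model configuration for the pseudo-Siamese pair classifier
#'
#' Collects every architecture hyperparameter. The default configuration is
#' the full model: two independent (non-weight-sharing) GRU branch encoders
#' with 128-dimensional hidden state, row-wise concatenation of the two
#' hidden-state sequences into a single one-channel matrix, a densely
#' connected convolutional spatial module, and a sigmoid relatedness head.
#'
#' @param tl Time lag of the difference-matrix encoding (default 32).
#' @param hidden_dim Hidden-state size of each recurrent branch (default 128).
#' @param branch_type Recurrent cell: `"gru"`, `"rnn"`, `"lstm"`, or
#'   `"none"` (feature matrices feed the spatial module directly).
#' @param spatial_type Spatial module: `"densenet"`, `"vgg"`, `"resnet"`, or
#'   `"none"`.
#' @param head Output head: `"sigmoid"` (one probability) or `"softmax"`
#'   (two class logits, normalised).
#' @param merge How the two branch outputs are combined:
#'   `"concat_rows"` (TF rows stacked above target rows) or `"multiply"`
#'   (correlation-style product; only valid with `spatial_type = "none"`).
#' @param dense_blocks Number of dense blocks (default 3).
#' @param block_layers Convolutional layers per dense block (default 4).
#' @param growth_rate Channels added by each dense layer (default 12).
#' @param compression Channel compression of transition layers (default 0.5).
#' @param stem_channels Channels of the stride-2 stem convolution (default 16).
#' @param stem_pool Follow the stem convolution with 2x2 average pooling, as
#'   the reference convolutional architectures do (default `TRUE`); disable
#'   for very small merged inputs.
#' @param pooling How the spatial module's final feature map reaches the
#'   head: `"flatten"` (2x2 average pooling, then flatten — keeps the
#'   spatial correspondence between the TF half and the target half of the
#'   merged matrix) or `"gap"` (global average pooling to one value per
#'   channel, so the feature length is independent of the input size).
#' @param head_units Units of the hidden fully connected layer in the head
#'   (default 32); the head applies pairwise max-pooling over `2 * head_units`
#'   units before the final linear map.
#' @param normalize Per-gene series normalization applied before the
#'   difference encoding (see [normalize_series()]).
#' @param seed Integer seed controlling weight initialization.
#' @return A list of class `psgrn_config`.
#' @export
psgrn_config <- function(tl = 32, hidden_dim = 128,
                         branch_type = c("gru", "rnn", "lstm", "none"),
                         spatial_type = c("densenet", "vgg", "resnet", "none"),
                         head = c("sigmoid", "softmax"),
                         merge = c("concat_rows", "multiply"),
                         dense_blocks = 3, block_layers = 4, growth_rate = 12,
                         compression = 0.5, stem_channels = 16,
                         stem_pool = TRUE, pooling = c("flatten", "gap"),
                         head_units = 32,
                         normalize = "zscore", seed = 1L) {
  pooling <- match.arg(pooling)
  branch_type <- match.arg(branch_type)
  spatial_type <- match.arg(spatial_type)
  head <- match.arg(head)
  merge <- match.arg(merge)
  stopifnot(hidden_dim >= 1, tl >= 1, dense_blocks >= 1, block_layers >= 1,
            growth_rate >= 1, compression > 0, compression <= 1,
            stem_channels >= 1, head_units >= 1)
  if (merge == "multiply" && spatial_type != "none") {
    stop("merge = \"multiply\" is only valid with spatial_type = \"none\"",
         call. = FALSE)
  }
  structure(list(tl = tl, hidden_dim = hidden_dim, branch_type = branch_type,
                 spatial_type = spatial_type, head = head, merge = merge,
                 dense_blocks = dense_blocks, block_layers = block_layers,
                 growth_rate = growth_rate, compression = compression,
                 stem_channels = stem_channels, stem_pool = stem_pool,
                 pooling = pooling, head_units = head_units,
                 normalize = normalize, seed = as.integer(seed)),
            class = "psgrn_config")
}

#' Architecture ablation variants
#'
#' Returns the base configuration mutated into one of the named variants used
#' to probe the contribution of each module: `PSGRN` (the full model),
#' `FM-DN` (no recurrent branches; feature matrices go straight into the
#' dense convolutional module), `RNN-DN` / `LSTM-DN` (vanilla RNN / LSTM
#' branches), `FM-GRU` (no spatial module; the two GRU outputs are combined
#' by multiplication), `GRU-VGG` / `GRU-RN` (VGG-style / residual spatial
#' module), and `PS-SM` (softmax head instead of sigmoid).
#'
#' @param name Variant name.
#' @param base A `psgrn_config` to start from.
#' @return A `psgrn_config`.
#' @export
build_variant <- function(name, base = psgrn_config()) {
  valid <- c("PSGRN", "FM-DN", "RNN-DN", "LSTM-DN", "FM-GRU",
             "GRU-VGG", "GRU-RN", "PS-SM")
  if (!name %in% valid) {
    stop("unknown variant '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  cfg <- unclass(base)
  switch(name,
    "PSGRN"   = {
      cfg$branch_type <- "gru"; cfg$spatial_type <- "densenet"
      cfg$head <- "sigmoid"; cfg$merge <- "concat_rows"
    },
    "FM-DN"   = { cfg$branch_type <- "none" },
    "RNN-DN"  = { cfg$branch_type <- "rnn" },
    "LSTM-DN" = { cfg$branch_type <- "lstm" },
    "FM-GRU"  = { cfg$spatial_type <- "none"; cfg$merge <- "multiply" },
    "GRU-VGG" = { cfg$spatial_type <- "vgg" },
    "GRU-RN"  = { cfg$spatial_type <- "resnet" },
    "PS-SM"   = { cfg$head <- "softmax" }
  )
  structure(cfg, class = "psgrn_config")
}

# spatial dimensions and channel bookkeeping of the spatial module; also
# validates that the input is large enough for every pooling stage
plan_spatial <- function(config, in_h, in_w) {
  need <- function(h, w, stage) {
    if (h < 2L || w < 2L) {
      stop(sprintf(paste0("merged input %dx%d too small at %s: every pooled",
                          " stage needs spatial size >= 2x2"),
                   in_h, in_w, stage), call. = FALSE)
    }
  }
  if (config$spatial_type == "densenet") {
    h <- conv_out_dim(in_h, 3L, 2L, 1L); w <- conv_out_dim(in_w, 3L, 2L, 1L)
    if (config$stem_pool) {
      need(h, w, "stem pool"); h <- h %/% 2L; w <- w %/% 2L
    }
    ch <- config$stem_channels
    for (b in seq_len(config$dense_blocks)) {
      ch <- ch + config$block_layers * config$growth_rate
      if (b < config$dense_blocks) {
        ch <- floor(ch * config$compression)
        need(h, w, sprintf("transition %d", b))
        h <- h %/% 2L; w <- w %/% 2L
      }
    }
  } else if (config$spatial_type == "vgg") {
    ch <- 4L * config$stem_channels
    h <- in_h; w <- in_w
    need(h, w, "pool 1"); h <- h %/% 2L; w <- w %/% 2L
    need(h, w, "pool 2"); h <- h %/% 2L; w <- w %/% 2L
  } else if (config$spatial_type == "resnet") {
    h <- conv_out_dim(in_h, 3L, 2L, 1L); w <- conv_out_dim(in_w, 3L, 2L, 1L)
    if (config$stem_pool) {
      need(h, w, "stem pool"); h <- h %/% 2L; w <- w %/% 2L
    }
    h <- conv_out_dim(h, 3L, 2L, 1L); w <- conv_out_dim(w, 3L, 2L, 1L)
    ch <- 2L * config$stem_channels
  }
  # final stage before the head: global average pooling, or 2x2 average
  # pooling (when the map allows it) followed by flattening
  final_pool <- config$pooling == "flatten" && h >= 2L && w >= 2L
  feat_len <- if (config$pooling == "gap") {
    ch
  } else {
    fh <- if (final_pool) h %/% 2L else h
    fw <- if (final_pool) w %/% 2L else w
    fh * fw * ch
  }
  list(out_channels = ch, out_h = h, out_w = w, final_pool = final_pool,
       feat_len = feat_len)
}

#' Build an untrained pair-classifier model
#'
#' Allocates and initialises all parameters for a given configuration and
#' input geometry. The two branch encoders receive independent parameter
#' sets (pseudo-Siamese: same structure, unshared weights). Recurrent
#' hidden-to-hidden weights are initialised block-orthogonally,
#' convolutional kernels with Kaiming-style scaling, biases at zero; all
#' initialisation is driven by `config$seed`.
#'
#' @param config A `psgrn_config`.
#' @param input_steps Number of rows of each feature matrix
#'   (`n_timepoints - tl - 1`).
#' @param input_dim Number of columns of each feature matrix (`tl`).
#' @return A list of class `psgrn_model` with elements `config`, `dims`,
#'   and `params`.
#' @export
psgrn_model <- function(config, input_steps, input_dim = config$tl) {
  stopifnot(inherits(config, "psgrn_config"), input_steps >= 1)
  if (input_dim != config$tl) {
    stop(sprintf("input_dim = %d does not match config tl = %d",
                 input_dim, config$tl), call. = FALSE)
  }
  with_seed(config$seed, {
    params <- list()
    H <- config$hidden_dim
    if (config$branch_type != "none") {
      ng <- n_gates_for(config$branch_type)
      for (side in c("tf", "tgt")) {
        p <- init_recurrent_params(input_dim, H, ng)
        params[[paste0(side, "_Wx")]] <- p$Wx
        params[[paste0(side, "_Wh")]] <- p$Wh
        params[[paste0(side, "_b")]] <- p$b
      }
      branch_w <- H
    } else {
      branch_w <- input_dim
    }
    if (config$merge == "concat_rows") {
      merged_h <- 2L * input_steps
      merged_w <- branch_w
    } else {
      merged_h <- input_steps
      merged_w <- input_steps
    }
    if (config$spatial_type != "none") {
      plan <- plan_spatial(config, merged_h, merged_w)
      feat_len <- plan$feat_len
      if (config$spatial_type == "densenet") {
        params$stem_K <- init_conv(3L, 3L, 1L, config$stem_channels)
        params$stem_b <- rep(0, config$stem_channels)
        ch <- config$stem_channels
        for (b in seq_len(config$dense_blocks)) {
          for (l in seq_len(config$block_layers)) {
            nm <- sprintf("b%dl%d", b, l)
            params[[paste0(nm, "_K")]] <- init_conv(3L, 3L, ch,
                                                    config$growth_rate)
            params[[paste0(nm, "_b")]] <- rep(0, config$growth_rate)
            ch <- ch + config$growth_rate
          }
          if (b < config$dense_blocks) {
            out_ch <- floor(ch * config$compression)
            params[[sprintf("tr%d_K", b)]] <- init_conv(1L, 1L, ch, out_ch)
            params[[sprintf("tr%d_b", b)]] <- rep(0, out_ch)
            ch <- out_ch
          }
        }
      } else if (config$spatial_type == "vgg") {
        ch <- config$stem_channels
        params$v1_K <- init_conv(3L, 3L, 1L, ch); params$v1_b <- rep(0, ch)
        params$v2_K <- init_conv(3L, 3L, ch, 2L * ch)
        params$v2_b <- rep(0, 2L * ch)
        params$v3_K <- init_conv(3L, 3L, 2L * ch, 4L * ch)
        params$v3_b <- rep(0, 4L * ch)
      } else { # resnet
        ch <- config$stem_channels
        params$rs_K <- init_conv(3L, 3L, 1L, ch); params$rs_b <- rep(0, ch)
        params$r1a_K <- init_conv(3L, 3L, ch, ch); params$r1a_b <- rep(0, ch)
        params$r1b_K <- init_conv(3L, 3L, ch, ch); params$r1b_b <- rep(0, ch)
        params$r2a_K <- init_conv(3L, 3L, ch, 2L * ch)
        params$r2a_b <- rep(0, 2L * ch)
        params$r2b_K <- init_conv(3L, 3L, 2L * ch, 2L * ch)
        params$r2b_b <- rep(0, 2L * ch)
        params$r2s_K <- init_conv(1L, 1L, ch, 2L * ch)
        params$r2s_b <- rep(0, 2L * ch)
      }
    } else {
      # no spatial module: pooled summary of the merged representation
      feat_len <- if (config$merge == "concat_rows") branch_w
                  else 2L * input_steps
    }
    k <- config$head_units
    params$fc1_W <- init_glorot(feat_len, 2L * k)
    params$fc1_b <- rep(0, 2L * k)
    out_dim <- if (config$head == "softmax") 2L else 1L
    params$fc2_W <- init_glorot(k, out_dim)
    params$fc2_b <- rep(0, out_dim)
    structure(list(config = config,
                   dims = list(input_steps = as.integer(input_steps),
                               input_dim = as.integer(input_dim),
                               merged_h = merged_h, merged_w = merged_w,
                               feat_len = feat_len),
                   params = params),
              class = "psgrn_model")
  })
}

#' @export
print.psgrn_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<psgrn_model> branch=%s hidden=%d merge=%s spatial=%s",
                     " head=%s\n  input %d x %d, merged %d x %d,",
                     " %d pooled features, %d parameters\n"),
              cfg$branch_type, cfg$hidden_dim, cfg$merge, cfg$spatial_type,
              cfg$head, x$dims$input_steps, x$dims$input_dim,
              x$dims$merged_h, x$dims$merged_w, x$dims$feat_len, n_par))
  invisible(x)
}

# ---- forward passes (batched, with caches for backward) --------------------

# final stage between the spatial module's feature map (pre-activation) and
# the fully connected head: ReLU, then either global average pooling or
# 2x2 average pooling + flatten, per config$pooling
head_input_forward <- function(Apre, config) {
  a <- relu(Apre)
  cc <- list(pre = Apre)
  if (config$pooling == "gap") {
    gp <- gap_forward(a)
    cc$gap_dims <- gp$dims
    Y <- gp$Y
  } else {
    d <- dim(a)
    if (d[2L] >= 2L && d[3L] >= 2L) {
      pl <- avgpool2_forward(a)
      cc$pool_dims <- pl$dims
      a <- pl$Y
    }
    cc$flat_dims <- dim(a)
    Y <- matrix(a, d[1L], prod(dim(a)[-1L]))
  }
  list(Y = Y, cache = cc)
}

head_input_backward <- function(dY, config, cc) {
  if (config$pooling == "gap") {
    dA <- gap_backward(dY, cc$gap_dims)
  } else {
    dA <- array(dY, cc$flat_dims)
    if (!is.null(cc$pool_dims)) dA <- avgpool2_backward(dA, cc$pool_dims)
  }
  relu_backward(dA, cc$pre)
}

branch_forward <- function(X, params, side, config) {
  p <- list(Wx = params[[paste0(side, "_Wx")]],
            Wh = params[[paste0(side, "_Wh")]],
            b = params[[paste0(side, "_b")]])
  rnn_forward(X, p, config$branch_type)
}

densenet_forward <- function(X, params, config) {
  caches <- list()
  st <- conv_forward(X, params$stem_K, params$stem_b, 3L, 3L, 2L, 1L)
  caches$stem <- st$cache
  out <- st$Y
  if (config$stem_pool) {
    pl <- avgpool2_forward(out)
    caches$stem_pool_dims <- pl$dims
    out <- pl$Y
  }
  for (b in seq_len(config$dense_blocks)) {
    for (l in seq_len(config$block_layers)) {
      nm <- sprintf("b%dl%d", b, l)
      a <- relu(out)
      cv <- conv_forward(a, params[[paste0(nm, "_K")]],
                         params[[paste0(nm, "_b")]], 3L, 3L, 1L, 1L)
      caches[[nm]] <- list(conv = cv$cache, pre = out,
                           in_channels = dim(out)[4L])
      out <- concat_channels(out, cv$Y)
    }
    if (b < config$dense_blocks) {
      nm <- sprintf("tr%d", b)
      a <- relu(out)
      cv <- conv_forward(a, params[[paste0(nm, "_K")]],
                         params[[paste0(nm, "_b")]], 1L, 1L, 1L, 0L)
      pl <- avgpool2_forward(cv$Y)
      caches[[nm]] <- list(conv = cv$cache, pre = out, pool_dims = pl$dims)
      out <- pl$Y
    }
  }
  hi <- head_input_forward(out, config)
  caches$head_in <- hi$cache
  list(Y = hi$Y, caches = caches)
}

densenet_backward <- function(dY, params, config, caches) {
  grads <- list()
  dOut <- head_input_backward(dY, config, caches$head_in)
  for (b in rev(seq_len(config$dense_blocks))) {
    if (b < config$dense_blocks) {
      nm <- sprintf("tr%d", b)
      cc <- caches[[nm]]
      dP <- avgpool2_backward(dOut, cc$pool_dims)
      bk <- conv_backward(dP, params[[paste0(nm, "_K")]], cc$conv)
      grads[[paste0(nm, "_K")]] <- bk$dK
      grads[[paste0(nm, "_b")]] <- bk$db
      dOut <- relu_backward(bk$dX, cc$pre)
    }
    for (l in rev(seq_len(config$block_layers))) {
      nm <- sprintf("b%dl%d", b, l)
      cc <- caches[[nm]]
      cin <- cc$in_channels
      dPrev <- dOut[, , , seq_len(cin), drop = FALSE]
      dNew <- dOut[, , , -seq_len(cin), drop = FALSE]
      bk <- conv_backward(dNew, params[[paste0(nm, "_K")]], cc$conv)
      grads[[paste0(nm, "_K")]] <- bk$dK
      grads[[paste0(nm, "_b")]] <- bk$db
      dOut <- dPrev + relu_backward(bk$dX, cc$pre)
    }
  }
  if (config$stem_pool) {
    dOut <- avgpool2_backward(dOut, caches$stem_pool_dims)
  }
  bk <- conv_backward(dOut, params$stem_K, caches$stem)
  grads$stem_K <- bk$dK
  grads$stem_b <- bk$db
  list(grads = grads, dX = bk$dX)
}

vgg_forward <- function(X, params, config) {
  caches <- list()
  c1 <- conv_forward(X, params$v1_K, params$v1_b, 3L, 3L, 1L, 1L)
  caches$c1 <- c1$cache; caches$p1 <- c1$Y
  p1 <- avgpool2_forward(relu(c1$Y)); caches$p1dims <- p1$dims
  c2 <- conv_forward(p1$Y, params$v2_K, params$v2_b, 3L, 3L, 1L, 1L)
  caches$c2 <- c2$cache; caches$p2 <- c2$Y
  p2 <- avgpool2_forward(relu(c2$Y)); caches$p2dims <- p2$dims
  c3 <- conv_forward(p2$Y, params$v3_K, params$v3_b, 3L, 3L, 1L, 1L)
  caches$c3 <- c3$cache
  hi <- head_input_forward(c3$Y, config)
  caches$head_in <- hi$cache
  list(Y = hi$Y, caches = caches)
}

vgg_backward <- function(dY, params, config, caches) {
  grads <- list()
  d3 <- head_input_backward(dY, config, caches$head_in)
  bk3 <- conv_backward(d3, params$v3_K, caches$c3)
  grads$v3_K <- bk3$dK; grads$v3_b <- bk3$db
  d2 <- relu_backward(avgpool2_backward(bk3$dX, caches$p2dims), caches$p2)
  bk2 <- conv_backward(d2, params$v2_K, caches$c2)
  grads$v2_K <- bk2$dK; grads$v2_b <- bk2$db
  d1 <- relu_backward(avgpool2_backward(bk2$dX, caches$p1dims), caches$p1)
  bk1 <- conv_backward(d1, params$v1_K, caches$c1)
  grads$v1_K <- bk1$dK; grads$v1_b <- bk1$db
  list(grads = grads, dX = bk1$dX)
}

resnet_forward <- function(X, params, config) {
  caches <- list()
  st <- conv_forward(X, params$rs_K, params$rs_b, 3L, 3L, 2L, 1L)
  caches$st <- st$cache
  x1 <- relu(st$Y); caches$st_pre <- st$Y
  if (config$stem_pool) {
    pl <- avgpool2_forward(x1)
    caches$stem_pool_dims <- pl$dims
    x1 <- pl$Y
  }
  a1 <- conv_forward(x1, params$r1a_K, params$r1a_b, 3L, 3L, 1L, 1L)
  caches$a1 <- a1$cache; caches$a1_pre <- a1$Y
  b1 <- conv_forward(relu(a1$Y), params$r1b_K, params$r1b_b, 3L, 3L, 1L, 1L)
  caches$b1 <- b1$cache
  s1 <- x1 + b1$Y
  x2 <- relu(s1); caches$s1_pre <- s1
  a2 <- conv_forward(x2, params$r2a_K, params$r2a_b, 3L, 3L, 2L, 1L)
  caches$a2 <- a2$cache; caches$a2_pre <- a2$Y
  b2 <- conv_forward(relu(a2$Y), params$r2b_K, params$r2b_b, 3L, 3L, 1L, 1L)
  caches$b2 <- b2$cache
  sc <- conv_forward(x2, params$r2s_K, params$r2s_b, 1L, 1L, 2L, 0L)
  caches$sc <- sc$cache
  s2 <- sc$Y + b2$Y
  hi <- head_input_forward(s2, config)
  caches$head_in <- hi$cache
  list(Y = hi$Y, caches = caches)
}

resnet_backward <- function(dY, params, config, caches) {
  grads <- list()
  d3 <- head_input_backward(dY, config, caches$head_in)
  bkb2 <- conv_backward(d3, params$r2b_K, caches$b2)
  grads$r2b_K <- bkb2$dK; grads$r2b_b <- bkb2$db
  da2 <- relu_backward(bkb2$dX, caches$a2_pre)
  bka2 <- conv_backward(da2, params$r2a_K, caches$a2)
  grads$r2a_K <- bka2$dK; grads$r2a_b <- bka2$db
  bksc <- conv_backward(d3, params$r2s_K, caches$sc)
  grads$r2s_K <- bksc$dK; grads$r2s_b <- bksc$db
  dx2 <- bka2$dX + bksc$dX
  dx2 <- relu_backward(dx2, caches$s1_pre)
  bkb1 <- conv_backward(dx2, params$r1b_K, caches$b1)
  grads$r1b_K <- bkb1$dK; grads$r1b_b <- bkb1$db
  da1 <- relu_backward(bkb1$dX, caches$a1_pre)
  bka1 <- conv_backward(da1, params$r1a_K, caches$a1)
  grads$r1a_K <- bka1$dK; grads$r1a_b <- bka1$db
  dx1 <- bka1$dX + dx2
  if (config$stem_pool) {
    dx1 <- avgpool2_backward(dx1, caches$stem_pool_dims)
  }
  dx1 <- relu_backward(dx1, caches$st_pre)
  bkst <- conv_backward(dx1, params$rs_K, caches$st)
  grads$rs_K <- bkst$dK; grads$rs_b <- bkst$db
  list(grads = grads, dX = bkst$dX)
}

spatial_forward <- function(X, params, config) {
  switch(config$spatial_type,
         densenet = densenet_forward(X, params, config),
         vgg = vgg_forward(X, params, config),
         resnet = resnet_forward(X, params, config),
         stop("spatial_forward called with spatial_type = none"))
}

spatial_backward <- function(dY, params, config, caches) {
  switch(config$spatial_type,
         densenet = densenet_backward(dY, params, config, caches),
         vgg = vgg_backward(dY, params, config, caches),
         resnet = resnet_backward(dY, params, config, caches))
}

# Core of the pair classifier: from the two (possibly encoded) sequences to
# the relatedness probability. Htf/Htg: arrays (B, input_steps, width).
model_forward_core <- function(model, Htf, Htg, keep_cache = TRUE) {
  config <- model$config
  params <- model$params
  d <- dim(Htf)
  B <- d[1L]; Tn <- d[2L]
  cache <- list(B = B)
  Hw <- dim(Htf)[3L]
  if (config$merge == "concat_rows") {
    # merged one-channel image: TF rows first, then target rows
    merged <- array(0, c(B, 2L * Tn, Hw, 1L))
    merged[, seq_len(Tn), , 1L] <- Htf
    merged[, Tn + seq_len(Tn), , 1L] <- Htg
    if (config$spatial_type != "none") {
      sp <- spatial_forward(merged, params, config)
      feat <- sp$Y
      cache$sp <- sp$caches
    } else {
      # pooled summary: per-column mean over the merged rows
      m2 <- merged[, , , 1L, drop = FALSE]
      dim(m2) <- c(B, 2L * Tn, Hw)
      feat <- apply(m2, c(1L, 3L), mean)
      cache$pool_rows <- 2L * Tn
    }
    cache$merged_dims <- dim(merged)
  } else {
    # multiply merge: correlation summary of the two hidden sequences,
    # feat = [ (1/T) Htf %*% mean-target-row ; (1/T) Htg %*% mean-tf-row ]
    mtf <- apply(Htf, c(1L, 3L), mean)   # (B, Hw) row means over steps
    mtg <- apply(Htg, c(1L, 3L), mean)
    r1 <- matrix(0, B, Tn); r2 <- matrix(0, B, Tn)
    for (bidx in seq_len(B)) {
      r1[bidx, ] <- matrix(Htf[bidx, , ], Tn, Hw) %*% mtg[bidx, ]
      r2[bidx, ] <- matrix(Htg[bidx, , ], Tn, Hw) %*% mtf[bidx, ]
    }
    feat <- cbind(r1, r2)
    cache$Htf <- Htf; cache$Htg <- Htg
    cache$mtf <- mtf; cache$mtg <- mtg
  }
  z1 <- sweep(feat %*% params$fc1_W, 2L, params$fc1_b, "+")
  mo <- maxout_forward(z1)
  z2 <- sweep(mo$Y %*% params$fc2_W, 2L, params$fc2_b, "+")
  if (config$head == "sigmoid") {
    prob <- sigmoid(z2[, 1L])
  } else {
    ex <- exp(z2 - apply(z2, 1L, max))
    sm <- ex / rowSums(ex)
    prob <- sm[, 2L]
    cache$softmax <- sm
  }
  if (keep_cache) {
    cache$feat <- feat; cache$mo <- mo; cache$Tn <- Tn; cache$Hw <- Hw
    cache$prob <- prob
  }
  list(prob = prob, cache = if (keep_cache) cache else NULL)
}

# Full model forward on a batch of pairs.
# Xtf, Xtgt: arrays (B, input_steps, input_dim).
model_forward <- function(model, Xtf, Xtgt, keep_cache = TRUE) {
  config <- model$config
  if (config$branch_type != "none") {
    btf <- branch_forward(Xtf, model$params, "tf", config)
    btg <- branch_forward(Xtgt, model$params, "tgt", config)
    out <- model_forward_core(model, btf$H, btg$H, keep_cache)
    if (keep_cache) {
      out$cache$btf <- btf$cache
      out$cache$btg <- btg$cache
    }
    out
  } else {
    model_forward_core(model, Xtf, Xtgt, keep_cache)
  }
}

# Forward over pairs referencing shared per-gene feature matrices: each
# distinct gene is encoded once per branch, then the encodings are gathered
# into pair order. Exact same result as model_forward, much less recurrent
# work when pairs share genes.
model_forward_grouped <- function(model, features, tf_ids, gene_ids,
                                  keep_cache = TRUE) {
  config <- model$config
  utf <- unique(tf_ids); ug <- unique(gene_ids)
  itf <- match(tf_ids, utf); ig <- match(gene_ids, ug)
  Xtf_u <- stack_features(features, utf)
  Xtg_u <- stack_features(features, ug)
  if (config$branch_type != "none") {
    btf <- branch_forward(Xtf_u, model$params, "tf", config)
    btg <- branch_forward(Xtg_u, model$params, "tgt", config)
    Htf <- btf$H[itf, , , drop = FALSE]
    Htg <- btg$H[ig, , , drop = FALSE]
    out <- model_forward_core(model, Htf, Htg, keep_cache)
    if (keep_cache) {
      out$cache$btf <- btf$cache
      out$cache$btg <- btg$cache
      out$cache$itf <- itf
      out$cache$ig <- ig
      out$cache$n_utf <- length(utf)
      out$cache$n_ug <- length(ug)
    }
    out
  } else {
    model_forward_core(model, Xtf_u[itf, , , drop = FALSE],
                       Xtg_u[ig, , , drop = FALSE], keep_cache)
  }
}

# sum pair-level sequence gradients (B, T, H) onto unique-gene rows
accumulate_rows <- function(dH, group_idx, n_groups) {
  d <- dim(dH)
  m <- matrix(dH, d[1L], d[2L] * d[3L])
  acc <- rowsum(m, group = group_idx, reorder = TRUE)
  array(acc, c(n_groups, d[2L], d[3L]))
}

# Backward from labels through merge/spatial/head; returns parameter
# gradients plus the pair-level gradients of the two branch outputs.
# `weights` are optional per-sample loss weights (e.g. a positive-class
# weight for the unbalanced pair labels).
model_backward_core <- function(model, cache, labels, weights = NULL) {
  config <- model$config
  params <- model$params
  B <- cache$B
  if (is.null(weights)) weights <- rep(1, B)
  grads <- list()
  if (config$head == "sigmoid") {
    dz2 <- matrix(weights * (cache$prob - labels) / B, ncol = 1L)
  } else {
    dz2 <- cache$softmax
    dz2[, 1L] <- dz2[, 1L] - (1 - labels)
    dz2[, 2L] <- dz2[, 2L] - labels
    dz2 <- dz2 * weights / B
  }
  grads$fc2_W <- crossprod(cache$mo$Y, dz2)
  grads$fc2_b <- colSums(dz2)
  dmo <- dz2 %*% t(params$fc2_W)
  dz1 <- maxout_backward(dmo, cache$mo)
  grads$fc1_W <- crossprod(cache$feat, dz1)
  grads$fc1_b <- colSums(dz1)
  dfeat <- dz1 %*% t(params$fc1_W)
  Tn <- cache$Tn; Hw <- cache$Hw
  dHtf <- dHtg <- NULL
  if (config$merge == "concat_rows") {
    if (config$spatial_type != "none") {
      sp <- spatial_backward(dfeat, params, config, cache$sp)
      grads <- c(grads, sp$grads)
      if (config$branch_type != "none") {
        dM <- sp$dX  # (B, 2T, Hw, 1)
        dHtf <- array(dM[, seq_len(Tn), , 1L], c(B, Tn, Hw))
        dHtg <- array(dM[, Tn + seq_len(Tn), , 1L], c(B, Tn, Hw))
      }
    } else {
      scale <- 1 / cache$pool_rows
      dHtf <- array(0, c(B, Tn, Hw)); dHtg <- array(0, c(B, Tn, Hw))
      for (t in seq_len(Tn)) {
        dHtf[, t, ] <- dfeat * scale
        dHtg[, t, ] <- dfeat * scale
      }
    }
  } else {
    dHtf <- array(0, c(B, Tn, Hw)); dHtg <- array(0, c(B, Tn, Hw))
    dr1 <- dfeat[, seq_len(Tn), drop = FALSE]
    dr2 <- dfeat[, Tn + seq_len(Tn), drop = FALSE]
    for (bidx in seq_len(B)) {
      Hf <- matrix(cache$Htf[bidx, , ], Tn, Hw)
      Hg <- matrix(cache$Htg[bidx, , ], Tn, Hw)
      # r1 = Hf %*% mtg, mtg = colMeans(Hg)
      dHtf[bidx, , ] <- outer(dr1[bidx, ], cache$mtg[bidx, ]) +
        matrix(rep(crossprod(Hg, dr2[bidx, ]) / Tn, each = Tn), Tn, Hw)
      dHtg[bidx, , ] <- outer(dr2[bidx, ], cache$mtf[bidx, ]) +
        matrix(rep(crossprod(Hf, dr1[bidx, ]) / Tn, each = Tn), Tn, Hw)
    }
  }
  list(grads = grads, dHtf = dHtf, dHtg = dHtg)
}

branch_grads <- function(model, dHtf, dHtg, cache) {
  params <- model$params
  gtf <- rnn_backward(dHtf, list(Wx = params$tf_Wx, Wh = params$tf_Wh,
                                 b = params$tf_b), cache$btf)
  gtg <- rnn_backward(dHtg, list(Wx = params$tgt_Wx, Wh = params$tgt_Wh,
                                 b = params$tgt_b), cache$btg)
  list(tf_Wx = gtf$Wx, tf_Wh = gtf$Wh, tf_b = gtf$b,
       tgt_Wx = gtg$Wx, tgt_Wh = gtg$Wh, tgt_b = gtg$b)
}

# Backward from labels for a model_forward cache.
model_backward <- function(model, cache, labels, weights = NULL) {
  core <- model_backward_core(model, cache, labels, weights)
  grads <- core$grads
  if (model$config$branch_type != "none") {
    grads <- c(grads, branch_grads(model, core$dHtf, core$dHtg, cache))
  }
  grads
}

# Backward for a model_forward_grouped cache: pair-level branch gradients are
# summed onto each distinct gene before backpropagation through time.
model_backward_grouped <- function(model, cache, labels, weights = NULL) {
  core <- model_backward_core(model, cache, labels, weights)
  grads <- core$grads
  if (model$config$branch_type != "none") {
    dHu_tf <- accumulate_rows(core$dHtf, cache$itf, cache$n_utf)
    dHu_tg <- accumulate_rows(core$dHtg, cache$ig, cache$n_ug)
    grads <- c(grads, branch_grads(model, dHu_tf, dHu_tg, cache))
  }
  grads
}

# ---- user-facing single-pair operations ------------------------------------

#' Encode one feature matrix with a branch of the pseudo-Siamese model
#'
#' Runs the recurrent encoder of the requested branch over a single gene's
#' difference feature matrix and returns the full hidden-state sequence. The
#' two branches hold independent parameters: perturbing the TF branch leaves
#' target-branch encodings untouched.
#'
#' @param model A `psgrn_model`.
#' @param feature Feature matrix of shape `input_steps x tl`.
#' @param branch `"tf_branch"` or `"target_branch"`.
#' @return Matrix `input_steps x hidden_dim` of hidden states.
#' @export
encode_branch <- function(model, feature,
                          branch = c("tf_branch", "target_branch")) {
  branch <- match.arg(branch)
  config <- model$config
  if (config$branch_type == "none") {
    stop("this model has no recurrent branches (branch_type = \"none\")",
         call. = FALSE)
  }
  if (!is.matrix(feature) || ncol(feature) != config$tl ||
      nrow(feature) != model$dims$input_steps) {
    stop(sprintf("feature matrix must be %d x %d for this model, got %d x %d",
                 model$dims$input_steps, config$tl,
                 NROW(feature), NCOL(feature)), call. = FALSE)
  }
  side <- if (branch == "tf_branch") "tf" else "tgt"
  X <- array(0, c(1L, nrow(feature), ncol(feature)))
  X[1L, , ] <- feature
  out <- branch_forward(X, model$params, side, config)
  matrix(out$H[1L, , ], nrow(feature), config$hidden_dim)
}

#' Merge the two branch encodings
#'
#' @param h_tf,h_target Hidden-state sequences of equal shape
#'   (`steps x hidden_dim`).
#' @param mode `"concat_rows"` stacks the TF rows above the target rows into
#'   one `2*steps x hidden_dim` matrix; `"multiply"` returns the product
#'   `h_tf %*% t(h_target)`, a correlation-style `steps x steps` matrix.
#' @return The merged matrix.
#' @export
merge_branches <- function(h_tf, h_target,
                           mode = c("concat_rows", "multiply")) {
  mode <- match.arg(mode)
  if (!all(dim(h_tf) == dim(h_target))) {
    stop("branch outputs must have identical shapes", call. = FALSE)
  }
  if (mode == "concat_rows") rbind(h_tf, h_target)
  else h_tf %*% t(h_target)
}

#' Spatial feature vector of a merged matrix
#'
#' Treats the merged matrix as a one-channel image, runs the model's
#' convolutional spatial module (dense blocks and transition layers for the
#' DenseNet type) and returns the pooled feature vector — global average
#' pooling, or 2x2 average pooling plus flattening, per the model's
#' `pooling` setting. Under `"gap"` the output length depends only on the
#' channel plan, not on the input height/width (above the documented
#' 2x2-per-pooling-stage minimum).
#'
#' @param model A `psgrn_model` whose `spatial_type` is not `"none"`.
#' @param merged Merged matrix from [merge_branches()].
#' @return Numeric feature vector of length `model$dims$feat_len`.
#' @export
spatial_module <- function(model, merged) {
  config <- model$config
  if (config$spatial_type == "none") {
    stop("this model has no spatial module (spatial_type = \"none\")",
         call. = FALSE)
  }
  X <- array(0, c(1L, nrow(merged), ncol(merged), 1L))
  X[1L, , , 1L] <- merged
  out <- spatial_forward(X, model$params, config)
  as.numeric(out$Y[1L, ])
}

#' Score a single TF-target pair
#'
#' @param model A `psgrn_model`.
#' @param fm_tf,fm_target Feature matrices of the TF and the candidate
#'   target, each `input_steps x tl`.
#' @param tf_id,gene_id Optional identifiers echoed in the result.
#' @return A one-row data frame with columns `tf`, `gene`, `score`; the
#'   score is the relatedness coefficient, strictly inside (0, 1).
#' @export
predict_pair <- function(model, fm_tf, fm_target,
                         tf_id = NA_character_, gene_id = NA_character_) {
  chk <- function(m, what) {
    if (!is.matrix(m) || nrow(m) != model$dims$input_steps ||
        ncol(m) != model$dims$input_dim) {
      stop(sprintf("%s must be a %d x %d matrix", what,
                   model$dims$input_steps, model$dims$input_dim),
           call. = FALSE)
    }
  }
  chk(fm_tf, "fm_tf"); chk(fm_target, "fm_target")
  Xtf <- array(0, c(1L, nrow(fm_tf), ncol(fm_tf)))
  Xtf[1L, , ] <- fm_tf
  Xtg <- array(0, c(1L, nrow(fm_target), ncol(fm_target)))
  Xtg[1L, , ] <- fm_target
  out <- model_forward(model, Xtf, Xtg, keep_cache = FALSE)
  data.frame(tf = tf_id, gene = gene_id, score = out$prob,
             stringsAsFactors = FALSE)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with probabilities clamped to
#' `[eps, 1 - eps]`.
#'
#' @param labels Binary vector.
#' @param probs Predicted probabilities, same length.
#' @param eps Clamping constant, default `1e-7`.
#' @return Scalar loss.
#' @export
bce_loss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) != length(probs)) {
    stop("labels and probs must have equal length", call. = FALSE)
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# weighted mean binary cross-entropy (weights normalised by batch size, not
# by their sum, matching the gradient used in training)
weighted_bce <- function(labels, probs, weights, eps = 1e-7) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(weights * (labels * log(p) + (1 - labels) * log(1 - p)))
}
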