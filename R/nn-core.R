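# Internal neural-network primitives: parameter initialisers, recurrent cells
# (vanilla RNN / GRU / LSTM) with backpropagation through time, im2col-based
# 2-D convolution, pooling, and the Adam optimiser. Everything operates on
# base R arrays; batches of images use layout (batch, height, width, channel)
# and batches of sequences use (batch, step, feature).

sigmoid <- function(x) 1 / (1 + exp(-x))

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# block-orthogonal recurrent weights: each H x H block is orthogonal
init_recurrent_hidden <- function(hidden, n_gates) {
  blocks <- lapply(seq_len(n_gates), function(g) {
    a <- matrix(stats::rnorm(hidden * hidden), hidden, hidden)
    qr.Q(qr(a))
  })
  do.call(cbind, blocks)
}

init_glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Kaiming-style for convolutions: kernel stored as (kh*kw*c_in) x c_out
init_conv <- function(kh, kw, c_in, c_out) {
  fan_in <- kh * kw * c_in
  matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
}

# Biases start at zero except the LSTM forget gate, which opens at 1 (the
# usual forget-bias initialisation).
init_recurrent_params <- function(input_dim, hidden, n_gates) {
  b <- rep(0, n_gates * hidden)
  if (n_gates == 4L) b[hidden + seq_len(hidden)] <- 1        # lstm f gate
  list(Wx = init_glorot(input_dim, n_gates * hidden),
       Wh = init_recurrent_hidden(hidden, n_gates),
       b  = b)
}

n_gates_for <- function(cell) switch(cell, rnn = 1L, gru = 3L, lstm = 4L,
  stop("unknown recurrent cell: ", cell))

# ---- recurrent forward/backward -------------------------------------------
# X: array (B, T, D). Returns the full hidden sequence H (B, T, hidden) plus
# the caches backward needs. Gate layout in the 3H/4H axis:
#   gru: [reset r | update z | candidate c]    lstm: [i | f | o | g]
# The production path runs in compiled code; the *_ref functions are the
# plain-R reference implementations the tests compare against.

cell_code <- function(cell) switch(cell, rnn = 0L, gru = 1L, lstm = 2L,
  stop("unknown recurrent cell: ", cell))

rnn_forward <- function(X, p, cell) {
  out <- cpp_rnn_forward(X, p$Wx, p$Wh, p$b, cell_code(cell))
  list(H = out$H,
       cache = list(X = X, H = out$H, caches = out$caches, cell = cell))
}

rnn_backward <- function(dH, p, cache) {
  cpp_rnn_backward(dH, cache$X, cache$H, p$Wx, p$Wh, cache$caches,
                   cell_code(cache$cell))
}

rnn_forward_ref <- function(X, p, cell) {
  d <- dim(X); B <- d[1L]; Tn <- d[2L]; D <- d[3L]
  H <- ncol(p$Wh)
  ng <- n_gates_for(cell)
  Hd <- H / ng
  Xm <- matrix(X, nrow = B * Tn, ncol = D)
  pre <- sweep(Xm %*% p$Wx, 2L, p$b, "+")
  Hseq <- array(0, c(B, Tn, Hd))
  cache <- list(cell = cell, B = B, Tn = Tn, D = D, Hd = Hd, Xm = Xm)
  h <- matrix(0, B, Hd)
  if (cell == "gru") {
    R <- Z <- Cc <- array(0, c(B, Tn, Hd))
    for (t in seq_len(Tn)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      px <- pre[rows, , drop = FALSE]
      r <- sigmoid(px[, 1:Hd, drop = FALSE] +
                     h %*% p$Wh[, 1:Hd, drop = FALSE])
      z <- sigmoid(px[, Hd + 1:Hd, drop = FALSE] +
                     h %*% p$Wh[, Hd + 1:Hd, drop = FALSE])
      cc <- tanh(px[, 2 * Hd + 1:Hd, drop = FALSE] +
                   (r * h) %*% p$Wh[, 2 * Hd + 1:Hd, drop = FALSE])
      h <- (1 - z) * h + z * cc
      R[, t, ] <- r; Z[, t, ] <- z; Cc[, t, ] <- cc; Hseq[, t, ] <- h
    }
    cache$R <- R; cache$Z <- Z; cache$Cc <- Cc
  } else if (cell == "rnn") {
    for (t in seq_len(Tn)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      h <- tanh(pre[rows, , drop = FALSE] + h %*% p$Wh)
      Hseq[, t, ] <- h
    }
  } else { # lstm
    Ig <- Fg <- Og <- Gg <- Cs <- array(0, c(B, Tn, Hd))
    cst <- matrix(0, B, Hd)
    for (t in seq_len(Tn)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      a <- pre[rows, , drop = FALSE] + h %*% p$Wh
      i <- sigmoid(a[, 1:Hd, drop = FALSE])
      f <- sigmoid(a[, Hd + 1:Hd, drop = FALSE])
      o <- sigmoid(a[, 2 * Hd + 1:Hd, drop = FALSE])
      g <- tanh(a[, 3 * Hd + 1:Hd, drop = FALSE])
      cst <- f * cst + i * g
      h <- o * tanh(cst)
      Ig[, t, ] <- i; Fg[, t, ] <- f; Og[, t, ] <- o; Gg[, t, ] <- g
      Cs[, t, ] <- cst
      Hseq[, t, ] <- h
    }
    cache$Ig <- Ig; cache$Fg <- Fg; cache$Og <- Og; cache$Gg <- Gg
    cache$Cs <- Cs
  }
  cache$Hseq <- Hseq
  list(H = Hseq, cache = cache)
}

# dH: (B, T, Hd) gradient w.r.t. the full hidden sequence.
rnn_backward_ref <- function(dH, p, cache) {
  B <- cache$B; Tn <- cache$Tn; Hd <- cache$Hd
  cell <- cache$cell
  Hseq <- cache$Hseq
  dPre <- matrix(0, B * Tn, ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  h_at <- function(t) if (t >= 1L) Hseq[, t, , drop = TRUE] else matrix(0, B, Hd)
  as_mat <- function(x) matrix(x, B, Hd)
  dh <- as_mat(dH[, Tn, ])
  if (cell == "gru") {
    Whr <- p$Wh[, 1:Hd, drop = FALSE]
    Whz <- p$Wh[, Hd + 1:Hd, drop = FALSE]
    Whc <- p$Wh[, 2 * Hd + 1:Hd, drop = FALSE]
    dWhr <- matrix(0, Hd, Hd); dWhz <- matrix(0, Hd, Hd)
    dWhc <- matrix(0, Hd, Hd)
    for (t in rev(seq_len(Tn))) {
      hp <- as_mat(h_at(t - 1L))
      r <- as_mat(cache$R[, t, ]); z <- as_mat(cache$Z[, t, ])
      cc <- as_mat(cache$Cc[, t, ])
      dz <- dh * (cc - hp)
      dc <- dh * z
      dhp <- dh * (1 - z)
      dac <- dc * (1 - cc^2)
      drh <- dac %*% t(Whc)
      dr <- drh * hp
      dhp <- dhp + drh * r
      dar <- dr * r * (1 - r)
      daz <- dz * z * (1 - z)
      dhp <- dhp + dar %*% t(Whr) + daz %*% t(Whz)
      dWhr <- dWhr + crossprod(hp, dar)
      dWhz <- dWhz + crossprod(hp, daz)
      dWhc <- dWhc + crossprod(r * hp, dac)
      rows <- ((t - 1L) * B + 1L):(t * B)
      dPre[rows, ] <- cbind(dar, daz, dac)
      dh <- dhp + if (t > 1L) as_mat(dH[, t - 1L, ]) else 0
    }
    dWh <- cbind(dWhr, dWhz, dWhc)
  } else if (cell == "rnn") {
    for (t in rev(seq_len(Tn))) {
      h <- as_mat(Hseq[, t, ])
      da <- dh * (1 - h^2)
      hp <- as_mat(h_at(t - 1L))
      dWh <- dWh + crossprod(hp, da)
      rows <- ((t - 1L) * B + 1L):(t * B)
      dPre[rows, ] <- da
      dh <- da %*% t(p$Wh) + if (t > 1L) as_mat(dH[, t - 1L, ]) else 0
    }
  } else { # lstm
    dcs <- matrix(0, B, Hd)
    for (t in rev(seq_len(Tn))) {
      i <- as_mat(cache$Ig[, t, ]); f <- as_mat(cache$Fg[, t, ])
      o <- as_mat(cache$Og[, t, ]); g <- as_mat(cache$Gg[, t, ])
      cst <- as_mat(cache$Cs[, t, ])
      cprev <- if (t > 1L) as_mat(cache$Cs[, t - 1L, ]) else matrix(0, B, Hd)
      tc <- tanh(cst)
      do <- dh * tc
      dcs <- dcs + dh * o * (1 - tc^2)
      di <- dcs * g; dfg <- dcs * cprev; dg <- dcs * i
      dcs <- dcs * f
      da <- cbind(di * i * (1 - i), dfg * f * (1 - f),
                  do * o * (1 - o), dg * (1 - g^2))
      hp <- as_mat(h_at(t - 1L))
      dWh <- dWh + crossprod(hp, da)
      rows <- ((t - 1L) * B + 1L):(t * B)
      dPre[rows, ] <- da
      dh <- da %*% t(p$Wh) + if (t > 1L) as_mat(dH[, t - 1L, ]) else 0
    }
  }
  list(Wx = crossprod(cache$Xm, dPre),
       Wh = dWh,
       b = colSums(dPre))
}

# ---- convolution -----------------------------------------------------------

pad_spatial <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  out[, pad + seq_len(d[2L]), pad + seq_len(d[3L]), ] <- X
  out
}

conv_out_dim <- function(size, k, stride, pad) {
  (size + 2L * pad - k) %/% stride + 1L
}

# X (B,H,W,C) -> matrix (B*H2*W2) x (kh*kw*C); offset (i,j) varies i fastest
im2col <- function(X, kh, kw, stride, pad) {
  d <- dim(X); B <- d[1L]; Hh <- d[2L]; Ww <- d[3L]; C <- d[4L]
  H2 <- conv_out_dim(Hh, kh, stride, pad)
  W2 <- conv_out_dim(Ww, kw, stride, pad)
  Xp <- pad_spatial(X, pad)
  cols <- vector("list", kh * kw)
  idx <- 1L
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      ri <- i + (seq_len(H2) - 1L) * stride
      ci <- j + (seq_len(W2) - 1L) * stride
      block <- Xp[, ri, ci, , drop = FALSE]
      cols[[idx]] <- matrix(block, nrow = B * H2 * W2, ncol = C)
      idx <- idx + 1L
    }
  }
  list(mat = do.call(cbind, cols), H2 = H2, W2 = W2)
}

# K: (kh*kw*C_in) x C_out with the same (i fastest, then j, then channel)
# ordering as im2col columns. NB im2col emits [offset-block x C] per offset,
# i.e. columns grouped by offset then channel -- K rows must match; both use
# the grouping produced here, so they stay consistent.
conv_forward <- function(X, K, b, kh, kw, stride, pad) {
  list(Y = cpp_conv_fwd(X, K, b, kh, kw, stride, pad),
       cache = list(X = X, kh = kh, kw = kw, stride = stride, pad = pad))
}

conv_backward <- function(dY, K, cache) {
  cpp_conv_bwd(cache$X, K, dY, cache$kh, cache$kw, cache$stride, cache$pad)
}

conv_forward_ref <- function(X, K, b, kh, kw, stride, pad) {
  ic <- im2col(X, kh, kw, stride, pad)
  Y <- sweep(ic$mat %*% K, 2L, b, "+")
  B <- dim(X)[1L]
  list(Y = array(Y, c(B, ic$H2, ic$W2, ncol(K))),
       cache = list(Xcol = ic$mat, H2 = ic$H2, W2 = ic$W2, dims = dim(X),
                    kh = kh, kw = kw, stride = stride, pad = pad))
}

conv_backward_ref <- function(dY, K, cache) {
  d <- cache$dims; B <- d[1L]; Hh <- d[2L]; Ww <- d[3L]; C <- d[4L]
  H2 <- cache$H2; W2 <- cache$W2
  kh <- cache$kh; kw <- cache$kw; stride <- cache$stride; pad <- cache$pad
  dYm <- matrix(dY, nrow = B * H2 * W2, ncol = dim(dY)[4L])
  dK <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(K)
  dXp <- array(0, c(B, Hh + 2L * pad, Ww + 2L * pad, C))
  idx <- 1L
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      ri <- i + (seq_len(H2) - 1L) * stride
      ci <- j + (seq_len(W2) - 1L) * stride
      block <- array(dXcol[, ((idx - 1L) * C + 1L):(idx * C)],
                     c(B, H2, W2, C))
      dXp[, ri, ci, ] <- dXp[, ri, ci, , drop = FALSE] + block
      idx <- idx + 1L
    }
  }
  dX <- if (pad > 0L) {
    dXp[, pad + seq_len(Hh), pad + seq_len(Ww), , drop = FALSE]
  } else dXp
  list(dX = dX, dK = dK, db = db)
}

relu <- function(x) {
  out <- cpp_relu(x)
  attributes(out) <- attributes(x)
  out
}

relu_backward <- function(dY, Xin) {
  out <- cpp_relu_backward(dY, Xin)
  attributes(out) <- attributes(dY)
  out
}

# 2x2 average pooling, stride 2; odd trailing rows/columns are dropped
avgpool2_forward <- function(X) {
  d <- dim(X); B <- d[1L]; Hh <- d[2L]; Ww <- d[3L]; C <- d[4L]
  if (Hh < 2L || Ww < 2L) {
    stop(sprintf("average pooling needs spatial size >= 2x2, got %dx%d",
                 Hh, Ww), call. = FALSE)
  }
  H2 <- Hh %/% 2L; W2 <- Ww %/% 2L
  ri <- seq_len(H2) * 2L; ci <- seq_len(W2) * 2L
  Y <- (X[, ri - 1L, ci - 1L, , drop = FALSE] +
          X[, ri - 1L, ci, , drop = FALSE] +
          X[, ri, ci - 1L, , drop = FALSE] +
          X[, ri, ci, , drop = FALSE]) / 4
  list(Y = Y, dims = d)
}

avgpool2_backward <- function(dY, dims) {
  B <- dims[1L]; Hh <- dims[2L]; Ww <- dims[3L]; C <- dims[4L]
  H2 <- Hh %/% 2L; W2 <- Ww %/% 2L
  dX <- array(0, dims)
  ri <- seq_len(H2) * 2L; ci <- seq_len(W2) * 2L
  q <- dY / 4
  dX[, ri - 1L, ci - 1L, ] <- q
  dX[, ri - 1L, ci, ] <- q
  dX[, ri, ci - 1L, ] <- q
  dX[, ri, ci, ] <- q
  dX
}

# global average pooling (B,H,W,C) -> (B,C)
gap_forward <- function(X) {
  d <- dim(X)
  X3 <- X
  dim(X3) <- c(d[1L], d[2L] * d[3L], d[4L])
  Y <- matrix(0, d[1L], d[4L])
  for (cc in seq_len(d[4L])) {
    Y[, cc] <- rowMeans(X3[, , cc, drop = FALSE], dims = 1L)
  }
  list(Y = Y, dims = d)
}

gap_backward <- function(dY, dims) {
  B <- dims[1L]; Hh <- dims[2L]; Ww <- dims[3L]; C <- dims[4L]
  dX <- array(0, dims)
  scale <- 1 / (Hh * Ww)
  for (cc in seq_len(C)) {
    dX[, , , cc] <- array(rep(dY[, cc] * scale, Hh * Ww), c(B, Hh, Ww))
  }
  dX
}

concat_channels <- function(A, Bm) {
  da <- dim(A); db <- dim(Bm)
  out <- array(0, c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- A
  out[, , , da[4L] + seq_len(db[4L])] <- Bm
  out
}

# pairwise maxout (B x 2k) -> (B x k); cache keeps the winner mask
maxout_forward <- function(X) {
  k <- ncol(X) %/% 2L
  A <- X[, seq_len(k) * 2L - 1L, drop = FALSE]
  Bm <- X[, seq_len(k) * 2L, drop = FALSE]
  winA <- A >= Bm
  list(Y = ifelse(winA, A, Bm), winA = winA, k = k)
}

maxout_backward <- function(dY, cache) {
  k <- cache$k
  dX <- matrix(0, nrow(dY), 2L * k)
  dX[, seq_len(k) * 2L - 1L] <- dY * cache$winA
  dX[, seq_len(k) * 2L] <- dY * !cache$winA
  dX
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam with decoupled weight decay; decay is applied to weight matrices only
# (names ending in _W, _K, _Wx, _Wh), never to biases.
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    upd <- mh / (sqrt(vh) + eps)
    if (weight_decay > 0 && grepl("_(W|K|Wx|Wh)$", nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
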