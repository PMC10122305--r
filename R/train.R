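#' Stratified train / test / validation split
#'
#' Partitions the labelled pairs into training, test and validation sets at
#' the given ratio (default 3:1:1) while keeping the proportion of positive
#' and negative labels in each split equal to the global prevalence within
#' one pair. Remainder pairs left over by the integer division go to the
#' training split. Deterministic for a fixed seed.
#'
#' @param pairs A `pair_labels` data frame (or any data frame with a `label`
#'   column).
#' @param ratios Length-3 positive weights for train, test, validation.
#' @param seed Integer seed.
#' @return Factor of length `nrow(pairs)` with levels
#'   `train`, `test`, `validation`; the seed is stored as an attribute.
#' @export
stratified_split <- function(pairs, ratios = c(3, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  lab <- pairs$label
  if (sum(lab == 1) < 5 || sum(lab == 0) < 5) {
    stop("need at least 5 pairs of each label to split 3:1:1", call. = FALSE)
  }
  total <- sum(ratios)
  out <- character(nrow(pairs))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(lab == cls)
      idx <- sample(idx)
      k <- length(idx)
      n_test <- floor(k * ratios[2] / total)
      n_val <- floor(k * ratios[3] / total)
      out[idx[seq_len(n_test)]] <- "test"
      out[idx[n_test + seq_len(n_val)]] <- "validation"
      out[idx[(n_test + n_val + 1):k]] <- "train"
    }
  })
  structure(factor(out, levels = c("train", "test", "validation")),
            seed = as.integer(seed))
}

#' Assemble a pair dataset ready for training
#'
#' Computes the per-gene feature matrices once and attaches them to the pair
#' table. The pair table gains `tf_series` / `gene_series` columns naming
#' the gene whose series feeds each branch; robustness transforms such as
#' [inject_noise()] redirect these without touching the labels.
#'
#' @param profile An `expression_profile`.
#' @param pairs A `pair_labels` table over the profile's genes.
#' @param tl Time lag of the feature encoding.
#' @param normalize Series normalization mode (see [normalize_series()]).
#' @return A list of class `pair_dataset` with elements `pairs`, `features`,
#'   `tl`, `normalize`.
#' @export
prepare_dataset <- function(profile, pairs, tl = 32, normalize = "zscore") {
  feats <- featurize_profile(profile, tl = tl, normalize = normalize)
  p <- as.data.frame(pairs)
  if (is.null(p$tf_series)) p$tf_series <- p$tf
  if (is.null(p$gene_series)) p$gene_series <- p$gene
  structure(list(pairs = p, features = feats, tl = tl, normalize = normalize),
            class = "pair_dataset")
}

# stack the features of the requested genes into a (B, steps, tl) array
stack_features <- function(features, ids) {
  ft <- features[ids]
  d <- dim(ft[[1L]])
  arr <- array(0, c(length(ft), d[1L], d[2L]))
  for (i in seq_along(ft)) arr[i, , ] <- ft[[i]]
  arr
}

#' Train the pair classifier
#'
#' Minimises the binary cross-entropy on the training pairs with the Adam
#' optimiser, evaluates AUPR on the validation pairs after every epoch, and
#' returns the parameters of the epoch with the best validation AUPR (early
#' stopping with the given patience). Fully seed-reproducible on one device:
#' the same `seed` yields identical shuffles, initial weights and history.
#'
#' @param config A `psgrn_config`.
#' @param dataset A `pair_dataset` from [prepare_dataset()].
#' @param split Factor from [stratified_split()] (or any factor with levels
#'   train/test/validation over `dataset$pairs`).
#' @param epochs Maximum number of epochs (default 100).
#' @param batch_size Minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay Decoupled L2 weight decay applied to weight matrices
#'   (default 1e-4).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_epochs Burn-in: epochs trained before checkpoint selection and
#'   patience counting begin (default 8). With very few validation
#'   positives the per-epoch AUPR is noisy, and a nearly untrained model can
#'   score high by luck at epoch 1; selecting checkpoints only after a
#'   burn-in avoids freezing such a model.
#' @param pos_weight Loss weight of positive pairs relative to negatives
#'   (default 1, i.e. no reweighting of the unbalanced labels). `"balanced"`
#'   uses the negative:positive ratio of the training split.
#' @param restarts Number of random restarts allowed when validation AUPR
#'   shows no lift over the label prevalence after 6 epochs (default 1).
#'   A restart re-initialises the weights from a derived seed; the epoch
#'   budget is shared across restarts and the best-validation checkpoint is
#'   kept across them.
#' @param seed Integer seed for weight initialisation and shuffling;
#'   defaults to `config$seed`.
#' @param verbose Print per-epoch progress.
#' @return A list of class `psgrn_fit`: `model` (with the best-validation
#'   parameters), `history` (data frame epoch / train_loss / val_aupr), and
#'   `best_epoch`.
#' @export
psgrn_train <- function(config, dataset, split, epochs = 100, batch_size = 64,
                        lr = 1e-3, weight_decay = 1e-4, patience = 10,
                        min_epochs = 8L, pos_weight = 1, restarts = 1L,
                        seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(config, "psgrn_config"), inherits(dataset, "pair_dataset"))
  pairs <- dataset$pairs
  steps <- nrow(dataset$features[[1L]])
  cfg <- config
  cfg$seed <- as.integer(seed)
  model <- psgrn_model(cfg, input_steps = steps)
  tr_idx <- which(split == "train")
  va_idx <- which(split == "validation")
  if (!length(tr_idx) || !length(va_idx)) {
    stop("split must contain train and validation pairs", call. = FALSE)
  }
  y_tr <- pairs$label[tr_idx]
  # start the output bias at the log-odds of the training prevalence so the
  # first epochs are not spent calibrating the base rate
  prev <- min(max(mean(y_tr), 1e-4), 1 - 1e-4)
  b0 <- log(prev / (1 - prev))
  if (identical(pos_weight, "balanced")) pos_weight <- (1 - prev) / prev
  model$params$fc2_b <- if (cfg$head == "sigmoid") b0 else c(0, b0)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_aupr = numeric())
  best <- list(aupr = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  burn_in <- min(min_epochs, epochs)
  restarts_left <- restarts
  restart_check <- burn_in + 2L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      sh <- sample(seq_along(tr_idx))
      idx <- tr_idx[sh]
      yy <- y_tr[sh]
      n_batches <- ceiling(length(idx) / batch_size)
      ep_loss <- 0
      for (bi in seq_len(n_batches)) {
        take <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(idx))
        rows <- idx[take]
        fw <- model_forward_grouped(model, dataset$features,
                                    pairs$tf_series[rows],
                                    pairs$gene_series[rows],
                                    keep_cache = TRUE)
        w <- ifelse(yy[take] == 1, pos_weight, 1)
        loss <- weighted_bce(yy[take], fw$prob, w)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d", ep, bi),
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(take)
        grads <- model_backward_grouped(model, fw$cache, yy[take], w)
        upd <- adam_step(model$params, grads, state, lr = lr,
                         weight_decay = weight_decay)
        model$params <- upd$params
        state <- upd$state
      }
      ep_loss <- ep_loss / length(idx)
      val_scores <- predict_scores(model, dataset, va_idx,
                                   batch_size = batch_size)
      val_aupr <- aupr(pairs$label[va_idx], val_scores)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss,
                                  val_aupr = val_aupr))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUPR %.4f",
                        ep, ep_loss, val_aupr))
      }
      if (ep >= burn_in) {
        if (val_aupr > best$aupr) {
          best <- list(aupr = val_aupr, params = model$params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
      if (restarts_left > 0L && ep >= restart_check &&
          best$aupr < 1.2 * prev) {
        # no lift over the base rate: re-initialise once and train on
        restarts_left <- restarts_left - 1L
        cfg_r <- cfg
        cfg_r$seed <- cfg$seed + 101L
        model <- psgrn_model(cfg_r, input_steps = steps)
        model$params$fc2_b <- if (cfg$head == "sigmoid") b0 else c(0, b0)
        state <- adam_init(model$params)
        wait <- 0L
        if (verbose) message(sprintf("epoch %3d  restart (no lift)", ep))
      }
    }
  })
  if (best$epoch > 0L) model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch),
            class = "psgrn_fit")
}

# batched scoring of pair rows (by index) of a dataset
predict_scores <- function(model, dataset, idx, batch_size = 128L) {
  pairs <- dataset$pairs
  out <- numeric(length(idx))
  n_batches <- ceiling(length(idx) / batch_size)
  for (bi in seq_len(n_batches)) {
    take <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(idx))
    rows <- idx[take]
    out[take] <- model_forward_grouped(model, dataset$features,
                                       pairs$tf_series[rows],
                                       pairs$gene_series[rows],
                                       keep_cache = FALSE)$prob
  }
  out
}

#' Score every pair of a dataset (or one split of it)
#'
#' @param fit A `psgrn_fit` from [psgrn_train()] (or a bare `psgrn_model`).
#' @param dataset A `pair_dataset`.
#' @param split Optional factor from [stratified_split()].
#' @param subset Which split level to score; `"all"` scores every pair.
#' @param batch_size Scoring batch size.
#' @return Data frame `tf`, `gene`, `label`, `score`, sorted by descending
#'   score.
#' @export
predict_pairs <- function(fit, dataset, split = NULL, subset = "all",
                          batch_size = 128L) {
  model <- if (inherits(fit, "psgrn_fit")) fit$model else fit
  idx <- if (identical(subset, "all") || is.null(split)) {
    seq_len(nrow(dataset$pairs))
  } else {
    which(split == subset)
  }
  sc <- predict_scores(model, dataset, idx, batch_size = batch_size)
  out <- dataset$pairs[idx, c("tf", "gene", "label")]
  out$score <- sc
  out <- out[order(-out$score, out$tf, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Evaluate a trained model on one split
#'
#' Computes AUPR, AUROC, and — when `top_k` is given — the threshold at the
#' k-th largest score together with the confusion counts under the rule
#' `score >= mu`.
#'
#' @inheritParams predict_pairs
#' @param top_k Optional rank for network extraction.
#' @return A list of class `prediction_result`: `scores` (the scored pair
#'   table), `aupr`, `auroc`, and optionally `threshold` and `confusion`.
#' @export
evaluate_pairs <- function(fit, dataset, split = NULL, subset = "test",
                           top_k = NULL, batch_size = 128L) {
  scored <- predict_pairs(fit, dataset, split = split, subset = subset,
                          batch_size = batch_size)
  out <- list(scores = scored,
              aupr = aupr(scored$label, scored$score),
              auroc = auroc(scored$label, scored$score))
  if (!is.null(top_k)) {
    mu <- top_k_threshold(scored$score, top_k)
    out$threshold <- mu
    out$confusion <- confusion_counts(scored$label, scored$score, mu)
  }
  structure(out, class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d pairs  AUPR %.4f  AUROC %.4f\n",
              nrow(x$scores), x$aupr, x$auroc))
  if (!is.null(x$confusion)) {
    cat(sprintf("  threshold %.4g  TP %d  FP %d  TN %d  FN %d\n",
                x$threshold, x$confusion["TP"], x$confusion["FP"],
                x$confusion["TN"], x$confusion["FN"]))
  }
  invisible(x)
}
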