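#' Inject input-label noise into a pair dataset
#'
#' Selects `round(fraction * N)` pairs uniformly without replacement and, for
#' each, replaces the expression series feeding the TF branch with the
#' series of a uniformly chosen random gene while keeping the target series
#' and the original label — corrupting the association between input and
#' label. The original dataset is untouched.
#'
#' @param dataset A `pair_dataset` from [prepare_dataset()].
#' @param fraction Fraction of pairs to corrupt (default 0.05).
#' @param seed Integer seed.
#' @return A new `pair_dataset` with redirected `tf_series` entries.
#' @export
inject_noise <- function(dataset, fraction = 0.05, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"), fraction > 0, fraction < 1)
  n <- nrow(dataset$pairs)
  k <- round(fraction * n)
  if (k < 1) {
    stop("fraction rounds to zero corrupted pairs", call. = FALSE)
  }
  genes <- names(dataset$features)
  out <- dataset
  with_seed(seed, {
    hit <- sample.int(n, k)
    out$pairs$tf_series[hit] <- sample(genes, k, replace = TRUE)
  })
  out
}

#' Subsample a pair dataset, stratified by label
#'
#' Retains `round(fraction * N)` pairs drawn uniformly without replacement
#' within each label class, so the positive prevalence is preserved within
#' one pair.
#'
#' @param dataset A `pair_dataset`.
#' @param fraction Fraction of pairs to retain (default 0.7).
#' @param seed Integer seed.
#' @return A new, smaller `pair_dataset`.
#' @export
subsample_pairs <- function(dataset, fraction = 0.70, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(dataset)
  lab <- dataset$pairs$label
  n <- length(lab)
  n_keep <- round(fraction * n)
  n1 <- round(fraction * sum(lab == 1))
  n0 <- n_keep - n1
  if (n1 < 5 || n0 < 5) {
    stop("subsample too small for a stratified 3:1:1 split", call. = FALSE)
  }
  with_seed(seed, {
    keep <- c(sample(which(lab == 1), n1), sample(which(lab == 0), n0))
  })
  keep <- sort(keep)
  out <- dataset
  out$pairs <- dataset$pairs[keep, ]
  rownames(out$pairs) <- NULL
  out
}

#' Repeated train/evaluate experiment under a condition
#'
#' Runs `n_repeats` independent repeats: repeat `i` derives seed
#' `base_seed + i`, applies the condition transform to the dataset
#' (`"original"` = identity, `"noise"` = [inject_noise()],
#' `"incomplete"` = [subsample_pairs()]; applied before splitting), draws a
#' stratified 3:1:1 split, trains the configured model, and records the test
#' AUPR. Reports the per-repeat values, their mean, and the population
#' variance.
#'
#' @param condition `"original"`, `"noise"`, or `"incomplete"`.
#' @param dataset A `pair_dataset`.
#' @param config A `psgrn_config`.
#' @param n_repeats Number of repeats (default 10).
#' @param base_seed Base seed; repeat `i` uses `base_seed + i`.
#' @param fraction Condition strength: corrupted fraction for `"noise"`
#'   (default 0.05), retained fraction for `"incomplete"` (default 0.70).
#' @param ... Further arguments to [psgrn_train()] (epochs, batch_size, lr,
#'   patience).
#' @return A list of class `experiment_report`: `name`, `aupr` (per-repeat),
#'   `mean`, `variance`, `seeds`, `failed`, `config`.
#' @export
repeat_experiment <- function(condition = c("original", "noise", "incomplete"),
                              dataset, config, n_repeats = 10, base_seed = 1L,
                              fraction = NULL, ...) {
  condition <- match.arg(condition)
  if (is.null(fraction)) {
    fraction <- switch(condition, original = 1, noise = 0.05,
                       incomplete = 0.70)
  }
  seeds <- base_seed + seq_len(n_repeats)
  auprs <- rep(NA_real_, n_repeats)
  failed <- logical(n_repeats)
  for (i in seq_len(n_repeats)) {
    res <- tryCatch({
      ds <- switch(condition,
                   original = dataset,
                   noise = inject_noise(dataset, fraction, seed = seeds[i]),
                   incomplete = subsample_pairs(dataset, fraction,
                                                seed = seeds[i]))
      sp <- stratified_split(ds$pairs, seed = seeds[i])
      fit <- psgrn_train(config, ds, sp, seed = seeds[i], ...)
      evaluate_pairs(fit, ds, sp, subset = "test")$aupr
    }, error = function(e) {
      warning(sprintf("repeat %d (%s) failed: %s", i, condition,
                      conditionMessage(e)))
      NA_real_
    })
    auprs[i] <- res
    failed[i] <- is.na(res)
  }
  ok <- auprs[!failed]
  structure(list(name = condition, aupr = auprs,
                 mean = mean(ok),
                 variance = mean((ok - mean(ok))^2),
                 seeds = seeds, failed = failed,
                 config = unclass(config)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: mean AUPR %.4f (variance %.3g, %d/%d ok)\n",
              x$name, x$mean, x$variance, sum(!x$failed), length(x$aupr)))
  invisible(x)
}

#' Paired-seed comparison of architecture variants
#'
#' Runs [repeat_experiment()] on the unmodified dataset once per variant,
#' with every variant sharing the same repeat seeds — hence identical split
#' assignments — so the comparison is paired. Returns one report per variant
#' plus a ranking table sorted by mean AUPR.
#'
#' @param dataset A `pair_dataset`.
#' @param variants Character vector of variant names for [build_variant()].
#' @param base A `psgrn_config` used as the base of every variant.
#' @param n_repeats Repeats per variant (default 10).
#' @param base_seed Shared base seed.
#' @param ... Further arguments to [psgrn_train()].
#' @return A list of class `ablation_result`: `reports` (named list of
#'   `experiment_report`) and `ranking` (data frame).
#' @export
ablation_suite <- function(dataset, variants, base = psgrn_config(),
                           n_repeats = 10, base_seed = 1L, ...) {
  reports <- lapply(variants, function(v) {
    cfg <- build_variant(v, base)
    rep <- repeat_experiment("original", dataset, cfg, n_repeats = n_repeats,
                             base_seed = base_seed, ...)
    rep$name <- v
    rep
  })
  names(reports) <- variants
  ranking <- data.frame(
    variant = variants,
    mean_aupr = vapply(reports, function(r) r$mean, numeric(1)),
    variance = vapply(reports, function(r) r$variance, numeric(1)),
    row.names = NULL
  )
  ranking <- ranking[order(-ranking$mean_aupr), ]
  rownames(ranking) <- NULL
  structure(list(reports = reports, ranking = ranking),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(x$ranking)
  invisible(x)
}
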