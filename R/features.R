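#' Lagged difference feature matrix of an expression series
#'
#' Encodes a single gene's expression series of length `n` as a matrix of
#' forward differences: row `j` (for `j = 1 .. n - tl - 1`) holds
#' `series[j + d] - series[j]` for offsets `d = 1 .. tl`. The encoding
#' captures how expression changes after each time point over a window of
#' `tl` future points, and is the input representation of both branches of
#' the pair classifier. With `n = 107` and `tl = 32` a series becomes a
#' 74 x 32 matrix.
#'
#' @param series Numeric vector of expression values at ordered time points.
#' @param tl Time-lag: number of forward offsets per row. Must satisfy
#'   `1 <= tl <= length(series) - 2` so that at least one row exists.
#' @return Numeric matrix of dimension `(n - tl - 1) x tl`.
#' @export
difference_matrix <- function(series, tl) {
  n <- length(series)
  if (tl < 1 || tl > n - 2) {
    stop(sprintf("time lag tl = %d out of range [1, %d] for n = %d",
                 tl, n - 2L, n), call. = FALSE)
  }
  n_rows <- n - tl - 1L
  j <- seq_len(n_rows)
  out <- vapply(seq_len(tl), function(d) series[j + d] - series[j],
                numeric(n_rows))
  matrix(out, nrow = n_rows, ncol = tl)
}

#' Normalize an expression series before feature extraction
#'
#' @param series Numeric vector, length at least 2.
#' @param mode One of `"none"` (identity), `"zscore"` (center and scale to
#'   unit variance; a constant series maps to all zeros), or
#'   `"log1p_zscore"` (z-score of `log(1 + x)`; requires non-negative input).
#' @return The normalized series.
#' @export
normalize_series <- function(series, mode = c("zscore", "none", "log1p_zscore")) {
  mode <- match.arg(mode)
  if (length(series) < 2L) stop("series must have length >= 2", call. = FALSE)
  if (mode == "none") return(series)
  if (mode == "log1p_zscore") {
    if (any(series < 0)) {
      stop("log1p_zscore requires non-negative values", call. = FALSE)
    }
    series <- log1p(series)
  }
  s <- stats::sd(series)
  if (s == 0) return(rep(0, length(series)))
  (series - mean(series)) / s
}

#' Feature matrices for every gene of a profile
#'
#' Applies [normalize_series()] then [difference_matrix()] to each gene row.
#'
#' @param profile An `expression_profile`.
#' @param tl Time-lag parameter; default 32.
#' @param normalize Normalization mode passed to [normalize_series()].
#' @return Named list of `(n - tl - 1) x tl` matrices, one per gene.
#' @export
featurize_profile <- function(profile, tl = 32, normalize = "zscore") {
  out <- lapply(seq_len(nrow(profile)), function(i) {
    difference_matrix(normalize_series(profile[i, ], mode = normalize), tl)
  })
  names(out) <- gene_ids(profile)
  out
}
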