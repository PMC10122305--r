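#' Configuration of the synthetic benchmark generator
#'
#' Describes a maize-like study: a sparse directed TF -> gene network over a
#' gene universe and a staged time course in which regulated targets track
#' their regulators with a time lag plus observation noise, while
#' unregulated genes evolve independently. The defaults give the compact
#' benchmark used throughout the test suite: 60 genes (12 of them TFs),
#' density 0.15 and 107 time points, echoing the shape (not the scale) of
#' the real maize sub-datasets.
#'
#' @param n_genes Number of genes in the universe (TFs included).
#' @param n_tfs Number of TFs; the first `n_tfs` gene ids act as regulators.
#' @param density Fraction of the `n_tfs * n_genes` ordered pairs that are
#'   true regulations.
#' @param n_timepoints Length of the time course (default 107).
#' @param signal_lag Delay, in time steps, between a change in the regulator
#'   and its effect on the target (default 8; keep it within `[1, tl]` so
#'   the difference encoding can see it).
#' @param effect_size Weight of the lagged regulator signal in the target
#'   (default 1.0).
#' @param noise_sd Standard deviation of the Gaussian observation noise
#'   added to regulated targets (default 0.1, i.e. effect >> noise).
#' @param baseline_process Stochastic baseline each gene follows:
#'   `"random_walk"` or `"sinusoid_mixture"`.
#' @param baseline_scale Amplitude multiplier of the baseline process; 0
#'   switches the baseline off (useful to isolate the regulatory signal).
#' @param target_baseline_scale Multiplier applied to the *own* baseline of
#'   regulated genes only (default 1). At 0 a regulated target reduces to
#'   the lagged regulator signal plus noise, which isolates the regulatory
#'   term in closed form while TFs keep their stochastic course.
#' @param stages If `TRUE`, adds a piecewise drift over 4 equal segments of
#'   the time course, mimicking developmental stages. Off by default.
#' @param seed Integer seed; the whole benchmark is a deterministic function
#'   of the configuration.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 60, n_tfs = 12, density = 0.15,
                              n_timepoints = 107, signal_lag = 8,
                              effect_size = 1.0, noise_sd = 0.1,
                              baseline_process = c("random_walk",
                                                   "sinusoid_mixture"),
                              baseline_scale = 1.0,
                              target_baseline_scale = 1.0, stages = FALSE,
                              seed = 1L) {
  baseline_process <- match.arg(baseline_process)
  if (n_tfs > n_genes) stop("n_tfs must not exceed n_genes", call. = FALSE)
  if (density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  if (n_timepoints < signal_lag + 3) {
    stop("n_timepoints must be at least signal_lag + 3", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 density = density, n_timepoints = as.integer(n_timepoints),
                 signal_lag = as.integer(signal_lag),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_process = baseline_process,
                 baseline_scale = baseline_scale,
                 target_baseline_scale = target_baseline_scale,
                 stages = stages, seed = as.integer(seed)),
            class = "simulation_config")
}

sim_gene_ids <- function(config) {
  sprintf("g%03d", seq_len(config$n_genes))
}

#' Sample a sparse directed TF -> gene network
#'
#' Draws exactly `round(density * n_tfs * n_genes)` distinct ordered
#' TF -> gene edges uniformly without replacement and assigns each a
#' synthetic p-value below 0.01, so every simulated edge passes the
#' credibility filter and recomputing [network_density()] from the counts
#' returns the configured density up to rounding.
#'
#' @param config A `simulation_config`.
#' @return A `candidate_edges` table.
#' @export
simulate_grn <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- sim_gene_ids(config)
  tfs <- genes[seq_len(config$n_tfs)]
  n_pairs <- config$n_tfs * config$n_genes
  n_edges <- round(config$density * n_pairs)
  if (n_edges < 1) {
    stop("configured density rounds to zero edges", call. = FALSE)
  }
  if (n_edges > n_pairs) {
    stop("requested edges exceed the number of ordered pairs", call. = FALSE)
  }
  with_seed(config$seed, {
    picked <- sample.int(n_pairs, n_edges)
    tf_idx <- ((picked - 1L) %% config$n_tfs) + 1L
    gene_idx <- ((picked - 1L) %/% config$n_tfs) + 1L
    p_vals <- stats::runif(n_edges, min = 1e-6, max = 0.0099)
    candidate_edges(tfs[tf_idx], genes[gene_idx], p_vals)
  })
}

baseline_course <- function(config) {
  n <- config$n_timepoints
  s <- config$baseline_scale
  if (s == 0) return(rep(0, n))
  raw <- if (config$baseline_process == "random_walk") {
    # start well above zero so the non-negativity floor rarely saturates
    stats::runif(1, 2, 5) + cumsum(stats::rnorm(n, 0, 0.25 * s))
  } else {
    a0 <- stats::runif(1, 2, 4) * s
    out <- rep(a0, n)
    for (k in 1:3) {
      amp <- stats::runif(1, 0.3, 1) * s
      freq <- stats::runif(1, 0.5, 4)
      phase <- stats::runif(1, 0, 2 * pi)
      out <- out + amp * sin(2 * pi * freq * seq_len(n) / n + phase)
    }
    out
  }
  if (config$stages) {
    seg <- ceiling(seq_len(n) / (n / 4))
    drift <- stats::rnorm(4, 0, s)
    raw <- raw + drift[pmin(seg, 4)] * (seq_len(n) / n)
  }
  raw
}

# sharp softplus floor: smooth non-negativity with negligible distortion for
# values well above zero (error < s * exp(-x/s))
softplus_floor <- function(x, s = 0.05) {
  ifelse(x > 20 * s, x, s * log1p(exp(pmin(x / s, 50))))
}

#' Simulate a time-course expression profile over a known network
#'
#' Every gene follows its own baseline process, floored to non-negative
#' values with a sharp softplus (smooth, so differences stay smooth). A
#' regulated target additionally receives `effect_size` times each of its
#' regulators' baseline signal delayed by `signal_lag` steps, plus Gaussian
#' noise; the regulator contribution starts at time `signal_lag + 1`.
#' Regulator signals are the TFs' own baselines, so a TF that is itself
#' regulated still transmits its unregulated course (no cascading).
#' Finally, if the smallest per-gene mean is positive but below 1, the whole
#' matrix is rescaled so every gene passes the default expression filter;
#' the rescaling is linear and preserves the lagged-signal structure.
#'
#' @param grn A `candidate_edges` table from [simulate_grn()].
#' @param config The matching `simulation_config`.
#' @return An `expression_profile` of `n_genes x n_timepoints`.
#' @export
simulate_expression <- function(grn, config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- sim_gene_ids(config)
  n <- config$n_timepoints
  lag <- config$signal_lag
  with_seed(config$seed + 1L, {
    base <- t(vapply(genes, function(g) softplus_floor(baseline_course(config)),
                     numeric(n)))
    rownames(base) <- genes
    values <- base
    reg_of <- split(grn$tf, grn$target)
    for (g in names(reg_of)) {
      contrib <- rep(0, n)
      for (tf in reg_of[[g]]) {
        shifted <- c(rep(0, lag), base[tf, seq_len(n - lag)])
        contrib <- contrib + config$effect_size * shifted
      }
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(n, 0, config$noise_sd)
      } else 0
      values[g, ] <- config$target_baseline_scale * base[g, ] + contrib + noise
    }
    values <- softplus_floor(values)
    mn <- min(rowMeans(values))
    if (mn > 0 && mn < 1) values <- values / mn
    colnames(values) <- sprintf("t%03d", seq_len(n))
    expression_profile(values)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Composes [simulate_grn()], [simulate_expression()] and
#' [label_all_pairs()]. When `dir` is given, the three artifacts are written
#' as delimited text (`expression.tsv`, `edges.tsv`, `labels.tsv`) together
#' with a JSON manifest of the exact configuration, so two calls with the
#' same config produce byte-identical files.
#'
#' @param config A `simulation_config`.
#' @param dir Optional output directory (created if missing).
#' @return A list with `profile`, `edges`, `pairs`, and `config`.
#' @export
make_benchmark <- function(config = simulation_config(), dir = NULL) {
  grn <- simulate_grn(config)
  profile <- simulate_expression(grn, config)
  pairs <- label_all_pairs(profile, grn)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_expression(profile, file.path(dir, "expression.tsv"))
    write_edges(grn, file.path(dir, "edges.tsv"))
    utils::write.table(pairs, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profile = profile, edges = grn, pairs = pairs, config = config)
}
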