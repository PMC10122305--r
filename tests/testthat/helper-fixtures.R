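# Shared fixtures: everything is generated in code at test time.

tiny_profile <- function() {
  m <- rbind(
    ga = c(1, 2, 3, 4),
    gb = c(0.5, 0.5, 0.5, 0.5),
    gc = c(2, 4, 2, 4)
  )
  colnames(m) <- paste0("t", 1:4)
  expression_profile(m)
}

tiny_edges <- function() {
  candidate_edges(tf = c("ga", "ga", "gc"),
                  target = c("gb", "gc", "gb"),
                  p_value = c(0.005, 0.02, 0.01))
}

# small but trainable synthetic study for smoke tests
tiny_benchmark <- function(seed = 1L) {
  make_benchmark(simulation_config(
    n_genes = 16, n_tfs = 4, density = 0.2, n_timepoints = 24,
    signal_lag = 3, seed = seed))
}

tiny_config <- function(seed = 1L, ...) {
  psgrn_config(tl = 6, hidden_dim = 8, dense_blocks = 2, block_layers = 2,
               growth_rate = 4, stem_channels = 4, stem_pool = FALSE,
               head_units = 8, seed = seed, ...)
}

# independent O(n^2) average-precision oracle: walk every unique threshold,
# recount the confusion from scratch, accumulate precision x recall steps
ap_oracle <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_tp <- 0
  ap <- 0
  for (mu in thr) {
    tp <- sum(labels == 1 & scores >= mu)
    fp <- sum(labels == 0 & scores >= mu)
    ap <- ap + (tp - prev_tp) / P * (tp / (tp + fp))
    prev_tp <- tp
  }
  ap
}

# independent AUROC oracle: concordance over all positive x negative pairs,
# ties counted half
auroc_oracle <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
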