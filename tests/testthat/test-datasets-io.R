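test_that("expression round-trips through delimited text", {
  p <- tiny_profile()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(p, tsv)
  back <- read_expression(tsv)
  expect_equal(unclass(back), unclass(p))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_expression(p, csv)
  expect_equal(unclass(read_expression(csv)), unclass(p))
})

test_that("expression loading validates its input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt1\tt2", "ga\t1\t2", "ga\t3\t4"), tsv)
  expect_error(read_expression(tsv), "duplicate")
  writeLines(c("gene\tt1\tt2", "ga\t1\toops"), tsv)
  expect_error(read_expression(tsv), "gene 'ga'.*column 't2'")
  m <- rbind(ga = c(1, NA)); colnames(m) <- c("t1", "t2")
  expect_error(expression_profile(m), "missing")
})

test_that("a generated maize-scale file reads back with the right shape", {
  cfg <- simulation_config(n_genes = 150, n_tfs = 20, density = 0.05,
                           n_timepoints = 107, seed = 4)
  dir <- withr::local_tempdir()
  make_benchmark(cfg, dir = dir)
  prof <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(n_genes(prof), 150L)
  expect_equal(n_timepoints(prof), 107L)
})

test_that("mean-expression filter keeps genes at or above the threshold", {
  m <- rbind(lo = rep(0.5, 4), at = rep(1, 4), hi = c(2, 3, 4, 3.8))
  colnames(m) <- paste0("t", 1:4)
  p <- expression_profile(m)
  kept <- filter_expressed(p)
  expect_equal(gene_ids(kept), c("at", "hi"))  # inclusive at exactly 1.0
  expect_equal(gene_ids(filter_expressed(kept)), gene_ids(kept)) # idempotent
  zero <- expression_profile(rbind(z = c(0, 0, 0, 0)))
  expect_warning(out <- filter_expressed(zero), "no gene")
  expect_equal(n_genes(out), 0L)
})

test_that("credibility filter keeps p <= alpha sorted ascending with stable ties", {
  e <- tiny_edges()
  f <- filter_credible_edges(e)
  expect_equal(nrow(f), 2L)
  expect_equal(f$p_value, c(0.005, 0.01))  # 0.01 kept (inclusive), 0.02 dropped
  tied <- candidate_edges(c("b", "a"), c("x", "x"), c(0.003, 0.003))
  expect_equal(filter_credible_edges(tied)$tf, c("a", "b"))
  none <- filter_credible_edges(candidate_edges("a", "b", 0.5))
  expect_equal(nrow(none), 0L)
})

test_that("edge tables reject invalid rows and round-trip through text", {
  expect_error(candidate_edges("a", "b", 1.2), "\\[0, 1\\]")
  expect_error(candidate_edges(c("a", "a"), c("b", "b"), c(0.1, 0.2)),
               "duplicate")
  e <- tiny_edges()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edges(e, tsv)
  expect_equal(as.data.frame(read_edges(tsv)), as.data.frame(e))
})

test_that("induced sub-dataset keeps all credible edges among selected genes", {
  # 4 sorted edges over {a,b,c,d}; top-2 touch {a,b,c}; the a->c edge ranked
  # 4th also lies inside the gene set and must be retained
  e <- candidate_edges(tf = c("a", "b", "a", "a"),
                       target = c("b", "c", "d", "c"),
                       p_value = c(0.001, 0.002, 0.003, 0.004))
  m <- matrix(rep(1:4, 4), nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), paste0("t", 1:4)))
  p <- expression_profile(m)
  sub <- build_subdataset(e, p, k = 2)
  expect_setequal(gene_ids(sub$profile), c("a", "b", "c"))
  expect_equal(nrow(sub$edges), 3L)  # a->b, b->c, a->c
  # k = all edges restricted to expressed genes is the identity
  all_ <- build_subdataset(e, p, k = 4)
  expect_equal(nrow(all_$edges), 4L)
  expect_warning(build_subdataset(e, p, k = 10), "using all")
})

test_that("top-k sub-dataset of a synthetic network induces at least k edges", {
  cfg <- simulation_config(n_genes = 80, n_tfs = 16, density = 0.15, seed = 9)
  grn <- simulate_grn(cfg)
  prof <- simulate_expression(grn, cfg)
  sorted <- filter_credible_edges(grn)
  sub <- build_subdataset(sorted, prof, k = 50)
  expect_gte(nrow(sub$edges), 50L)
})

test_that("pair labelling enumerates the full TF x gene product", {
  p <- tiny_profile()
  e <- candidate_edges("ga", "gb", 0.001)
  pl <- label_all_pairs(p, e)
  expect_equal(nrow(pl), 3L)  # 1 TF x 3 genes, self pair included
  expect_equal(sum(pl$label), 1L)
  expect_equal(pl$label[pl$tf == "ga" & pl$gene == "gb"], 1L)
  # conservation: positives + negatives = |tf_set| x |genes|
  bench <- tiny_benchmark()
  pl2 <- bench$pairs
  expect_equal(nrow(pl2), attr(pl2, "n_tfs") * attr(pl2, "n_genes"))
  expect_equal(sum(pl2$label == 1) + sum(pl2$label == 0), nrow(pl2))
  # an edge endpoint missing from the profile is an error
  bad <- candidate_edges("ga", "zz", 0.001)
  expect_error(label_all_pairs(p, bad), "absent")
})

test_that("network density follows regulations / (TFs * genes)", {
  expect_equal(round(network_density(9690, 101, 506), 3), 0.190)
  expect_equal(round(network_density(16367, 148, 876), 3), 0.126)
  expect_equal(network_density(0, 10, 10), 0)
  expect_equal(network_density(50, 5, 10), 1)  # complete network
  expect_error(network_density(51, 5, 10), "must lie")
  expect_error(network_density(-1, 5, 10), "must lie")
  expect_error(network_density(1, 0, 10), "at least 1")
})
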