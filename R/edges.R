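#' Construct a candidate edge table
#'
#' Directed TF -> target regulations with an associated p-value, as produced
#' by an upstream network-construction experiment (e.g. ChIP-seq based GRNs).
#' Edges with small p-values become the positive labels of the supervised
#' pair classifier.
#'
#' @param tf Character vector of regulator (TF) gene ids.
#' @param target Character vector of target gene ids.
#' @param p_value Numeric vector of p-values in `[0, 1]`.
#' @return A data frame of class `candidate_edges` with columns
#'   `tf`, `target`, `p_value`.
#' @export
candidate_edges <- function(tf, target, p_value) {
  tf <- as.character(tf); target <- as.character(target)
  p_value <- as.numeric(p_value)
  if (length(tf) != length(target) || length(tf) != length(p_value)) {
    stop("tf, target and p_value must have equal length", call. = FALSE)
  }
  if (length(p_value) && (anyNA(p_value) || any(p_value < 0 | p_value > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(paste(tf, target, sep = "\r"))) {
    stop("duplicate (tf, target) pairs in edge table", call. = FALSE)
  }
  structure(
    data.frame(tf = tf, target = target, p_value = p_value,
               stringsAsFactors = FALSE),
    class = c("candidate_edges", "data.frame")
  )
}

#' Set of TF identifiers appearing as edge sources
#' @param edges A `candidate_edges` table.
#' @return Character vector of distinct TF ids.
#' @export
tf_set <- function(edges) unique(edges$tf)

#' Read / write a candidate edge table
#'
#' Three delimited columns: tf, target, p_value. A header row is detected by
#' a non-numeric third field on the first line.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator; `NULL` to infer from the extension.
#' @return A `candidate_edges` table.
#' @export
read_edges <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- infer_delimiter(path, delimiter)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = c("character", "character", "numeric"),
                           quote = "", comment.char = "")
  candidate_edges(raw[[1L]], raw[[2L]], raw[[3L]])
}

#' @rdname read_edges
#' @param edges A `candidate_edges` table to write.
#' @export
write_edges <- function(edges, path, delimiter = NULL) {
  sep <- infer_delimiter(path, delimiter)
  utils::write.table(edges, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep credible edges and sort by significance
#'
#' Retains edges with `p_value <= alpha` (inclusive) and sorts them in
#' ascending p-value; ties are broken by (tf, target) lexicographic order so
#' the result is reproducible.
#'
#' @param edges A `candidate_edges` table.
#' @param alpha Significance threshold; default 0.01.
#' @return The filtered, sorted `candidate_edges` table.
#' @export
filter_credible_edges <- function(edges, alpha = 0.01) {
  keep <- edges$p_value <= alpha
  out <- edges[keep, , drop = FALSE]
  ord <- order(out$p_value, out$tf, out$target, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_edges", "data.frame"))
}

#' Build an induced sub-dataset from the top-k most credible edges
#'
#' Takes the gene set touched by the `k` most significant edges (the edge
#' table must already be credibility-filtered and sorted) and returns the
#' expression profile restricted to those genes together with *all* credible
#' edges whose both endpoints fall inside the gene set — the induced
#' sub-network, not merely the top-k edges.
#'
#' @param edges Sorted, credibility-filtered `candidate_edges`.
#' @param profile An `expression_profile` (already expression-filtered).
#' @param k Number of leading edges whose genes seed the sub-dataset.
#' @return A list with elements `profile` and `edges`.
#' @export
build_subdataset <- function(edges, profile, k) {
  stopifnot(k >= 1)
  if (k > nrow(edges)) {
    warning(sprintf("k = %d exceeds the %d available edges; using all edges",
                    k, nrow(edges)))
    k <- nrow(edges)
  }
  top <- edges[seq_len(k), , drop = FALSE]
  genes <- intersect(gene_ids(profile), unique(c(top$tf, top$target)))
  sub_profile <- expression_profile(
    unclass(profile)[gene_ids(profile) %in% genes, , drop = FALSE]
  )
  inside <- edges$tf %in% genes & edges$target %in% genes
  sub_edges <- edges[inside, , drop = FALSE]
  rownames(sub_edges) <- NULL
  list(profile = sub_profile,
       edges = structure(sub_edges, class = c("candidate_edges", "data.frame")))
}

#' Enumerate and label every ordered TF x gene pair
#'
#' Lists the full Cartesian product of the edge table's TF set with all genes
#' of the profile (self pairs tf -> tf included) and labels a pair 1 when it
#' appears in the edge table, 0 otherwise. This is the gold-standard pair set
#' the classifier is trained and evaluated on.
#'
#' @param sub_profile An `expression_profile` restricted to the sub-dataset.
#' @param sub_edges The matching `candidate_edges`.
#' @return A data frame of class `pair_labels` with columns `tf`, `gene`,
#'   `label`, and attributes `n_tfs`, `n_genes`, `n_positive`.
#' @export
label_all_pairs <- function(sub_profile, sub_edges) {
  genes <- gene_ids(sub_profile)
  tfs <- sort(tf_set(sub_edges))
  missing <- setdiff(unique(c(sub_edges$tf, sub_edges$target)), genes)
  if (length(missing)) {
    stop("edge endpoints absent from the profile: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pairs <- expand.grid(gene = genes, tf = tfs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[, c("tf", "gene")]
  key <- paste(pairs$tf, pairs$gene, sep = "\r")
  pos <- paste(sub_edges$tf, sub_edges$target, sep = "\r")
  pairs$label <- as.integer(key %in% pos)
  rownames(pairs) <- NULL
  structure(pairs,
            class = c("pair_labels", "data.frame"),
            n_tfs = length(tfs), n_genes = length(genes),
            n_positive = sum(pairs$label))
}

#' Density of a directed TF -> gene network
#'
#' The prevalence of regulations among all ordered TF x gene pairs:
#' `regulations / (TFs * genes)`.
#'
#' @param n_regulations Number of regulatory edges.
#' @param n_tfs Number of transcription factors.
#' @param n_genes Number of genes (TFs included).
#' @return The density, a fraction in `[0, 1]`.
#' @export
network_density <- function(n_regulations, n_tfs, n_genes) {
  if (n_tfs < 1 || n_genes < 1) {
    stop("n_tfs and n_genes must be at least 1", call. = FALSE)
  }
  if (n_regulations < 0 || n_regulations > n_tfs * n_genes) {
    stop("n_regulations must lie in [0, n_tfs * n_genes]", call. = FALSE)
  }
  n_regulations / (n_tfs * n_genes)
}
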