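#' Construct an expression profile
#'
#' An expression profile holds one row per gene and one column per ordered
#' time point. It is the container every downstream step (filtering, feature
#' extraction, simulation) operates on.
#'
#' @param values Numeric matrix, genes in rows, time points in columns.
#'   Row names are the gene identifiers and must be unique; column names, if
#'   present, are kept as time-point labels.
#' @return An object of class `expression_profile`: the validated matrix.
#' @export
expression_profile <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("`values` must have gene identifiers as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("an expression profile needs at least 2 time points", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries", call. = FALSE)
  }
  structure(values, class = c("expression_profile", class(values)))
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes x %d time points\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Number of genes / time points in a profile
#'
#' @param profile An `expression_profile`.
#' @return Integer count.
#' @export
n_genes <- function(profile) nrow(profile)

#' @rdname n_genes
#' @export
n_timepoints <- function(profile) ncol(profile)

#' Gene identifiers of a profile
#' @param profile An `expression_profile`.
#' @return Character vector of gene ids in row order.
#' @export
gene_ids <- function(profile) rownames(profile)

infer_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression profile from delimited text
#'
#' Expects a header row of time-point labels and gene identifiers in the
#' first column. The delimiter is inferred from the file extension
#' (`.csv` is comma, anything else tab) unless given explicitly.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator; `NULL` to infer from the extension.
#' @return An [expression_profile()].
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- infer_delimiter(path, delimiter)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 3L) {
    stop("expression file needs a gene-id column and at least 2 time points",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  num <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !is.na(raw[-1L]), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("malformed numeric value at gene '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(raw)[-1L][bad[1L, 2L]]),
         call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(raw)[-1L]
  expression_profile(num)
}

#' Write an expression profile to delimited text
#'
#' @param profile An `expression_profile`.
#' @param path Output path.
#' @param delimiter Field separator; `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(profile, path, delimiter = NULL) {
  sep <- infer_delimiter(path, delimiter)
  df <- data.frame(gene_id = rownames(profile), unclass(profile),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep genes expressed above a mean level
#'
#' A gene is retained when its mean expression over all time points is at
#' least `min_mean` (inclusive, so a constant series at exactly the
#' threshold is kept). Gene order is preserved.
#'
#' @param profile An `expression_profile`.
#' @param min_mean Minimum mean expression level; default 1.0.
#' @return The filtered `expression_profile`.
#' @export
filter_expressed <- function(profile, min_mean = 1.0) {
  stopifnot(min_mean >= 0)
  keep <- rowMeans(profile) >= min_mean
  if (!any(keep)) warning("no gene passes the mean-expression filter")
  expression_profile(unclass(profile)[keep, , drop = FALSE])
}
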