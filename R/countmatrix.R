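#' Gene-by-sample count matrix with platform tag and sample metadata
#'
#' The unit every pipeline stage consumes: a nonnegative integer matrix with
#' gene IDs as rownames and sample IDs as colnames, a platform tag, and a
#' per-sample metadata table (group label and RNA-quality fields).
#'
#' @param counts Numeric matrix of nonnegative integer counts, genes in rows
#'   (rownames required) and samples in columns (colnames required).
#' @param platform Character tag naming the measurement platform.
#' @param sample_meta Optional data.frame with one row per sample; must contain
#'   a `sample_id` column matching `colnames(counts)` in order. A minimal table
#'   is built when omitted.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, platform = "generic", sample_meta = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene IDs as rownames and sample IDs as colnames")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) {
    stop("duplicate gene ID(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite values")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(
      "counts must be nonnegative integers; first offender: gene '",
      rownames(counts)[bad[1, 1]], "', sample '", colnames(counts)[bad[1, 2]],
      "' (value ", counts[bad[1, , drop = FALSE]], ")"
    )
  }
  storage.mode(counts) <- "double" # integral values, double storage avoids overflow
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(counts), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sample_meta) || !"sample_id" %in% names(sample_meta)) {
    stop("`sample_meta` must be a data.frame with a `sample_id` column")
  }
  if (!identical(as.character(sample_meta$sample_id), colnames(counts))) {
    stop("`sample_meta$sample_id` must match colnames(counts) in order")
  }
  rownames(sample_meta) <- NULL
  structure(
    list(counts = counts, platform = platform, sample_meta = sample_meta),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(
    "count_matrix [", x$platform, "]: ", nrow(x$counts), " genes x ",
    ncol(x$counts), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene identifiers of a counts container
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector of gene IDs.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.count_matrix <- function(x) rownames(x$counts)

#' Sample identifiers of a counts container
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.count_matrix <- function(x) colnames(x$counts)

#' Numeric value matrix of a counts container
#'
#' Extracts the gene-by-sample numeric matrix from a `count_matrix` (raw
#' counts), a `normalized_matrix` (normalized values) or a plain matrix.
#'
#' @param x Object to extract from.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
values <- function(x) UseMethod("values")

#' @export
values.count_matrix <- function(x) x$counts

#' @export
values.matrix <- function(x) x

#' @export
values.normalized_matrix <- function(x) x$values

#' @export
gene_ids.normalized_matrix <- function(x) rownames(x$values)

#' @export
sample_ids.normalized_matrix <- function(x) colnames(x$values)
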