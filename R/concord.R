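# Cross-platform concordance layer: annotation overlap, log2FC correlation,
# per-gene direction classes, Venn counts, Jaccard index, combined report.

DIRECTION_LEVELS <- c(
  "both_down", "both_up", "a_only_down", "a_only_up",
  "b_only_down", "b_only_up", "opposite", "not_significant"
)

#' Panel-versus-annotation overlap accounting
#'
#' How many panel genes are present in the sequencing annotation, with the
#' missing IDs listed. Full-precision percentage is stored; use
#' [format_percent()] for display.
#'
#' @param panel_gene_ids Panel gene IDs (no duplicates).
#' @param annotation_gene_ids Annotated gene IDs (no duplicates).
#' @return An object of class `overlap_report`: `n_panel`, `n_found`,
#'   `n_missing`, `pct_found`, `missing_ids` (sorted).
#' @export
annotation_overlap <- function(panel_gene_ids, annotation_gene_ids) {
  if (!length(panel_gene_ids)) stop("empty panel gene list")
  if (anyDuplicated(panel_gene_ids)) stop("duplicate IDs in panel list")
  if (anyDuplicated(annotation_gene_ids)) stop("duplicate IDs in annotation list")
  found <- panel_gene_ids %in% annotation_gene_ids
  structure(
    list(
      n_panel = length(panel_gene_ids),
      n_found = sum(found),
      n_missing = sum(!found),
      pct_found = 100 * sum(found) / length(panel_gene_ids),
      missing_ids = sort(panel_gene_ids[!found])
    ),
    class = "overlap_report"
  )
}

#' Format a percentage the way overlap figures are reported
#'
#' One decimal by default; two decimals are kept when the exact value is
#' representable at two decimals but not at one (e.g. 98.75 stays "98.75"
#' while 98.9156... becomes "98.9").
#'
#' @param x Percentage value.
#' @return Character scalar, without the percent sign.
#' @export
format_percent <- function(x) {
  if (isTRUE(all.equal(round(x, 2), x)) && round(x, 1) != round(x, 2)) {
    format(round(x, 2), nsmall = 2)
  } else {
    format(round(x, 1), nsmall = 1)
  }
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(
    "overlap_report: ", x$n_found, "/", x$n_panel, " panel genes found (",
    format_percent(x$pct_found), "%), ", x$n_missing, " missing\n",
    sep = ""
  )
  invisible(x)
}

shared_defined_genes <- function(res_a, res_b, use_shrunk) {
  col <- if (use_shrunk) "lfc_shrunk" else "lfc_raw"
  ga <- res_a$gene_id[!is.na(res_a[[col]])]
  gb <- res_b$gene_id[!is.na(res_b[[col]])]
  intersect(ga, gb)
}

#' Correlation of log2 fold changes between two platforms
#'
#' Pearson and Spearman correlation of the per-gene log2 fold changes over the
#' genes shared by both results with defined estimates.
#'
#' @param res_a,res_b `dge_result` objects for the two platforms.
#' @param use_shrunk Correlate shrunken (`TRUE`) or raw (`FALSE`, default —
#'   the convention for fold-change concordance) estimates.
#' @return List with `pearson`, `spearman`, `n_genes`, `gene_ids`.
#' @export
lfc_concordance <- function(res_a, res_b, use_shrunk = FALSE) {
  stopifnot(inherits(res_a, "dge_result"), inherits(res_b, "dge_result"))
  col <- if (use_shrunk) "lfc_shrunk" else "lfc_raw"
  genes <- shared_defined_genes(res_a, res_b, use_shrunk)
  if (length(genes) < 3) stop("fewer than 3 shared genes with defined fold changes")
  la <- stats::setNames(res_a[[col]], res_a$gene_id)[genes]
  lb <- stats::setNames(res_b[[col]], res_b$gene_id)[genes]
  list(
    pearson = pearson_cor(la, lb),
    spearman = spearman_cor(la, lb),
    n_genes = length(genes),
    gene_ids = genes
  )
}

#' Classify per-gene differential-expression direction agreement
#'
#' Every shared gene with defined statistics on both platforms gets exactly
#' one label: significant in both with the same sign (`both_down`/`both_up`),
#' significant in exactly one platform (`a_only_*`/`b_only_*`, direction from
#' that platform's sign), significant in both with opposite signs
#' (`opposite`), or `not_significant`. Significance uses [call_degs()]
#' semantics (inclusive fold-change and adjusted-p gates).
#'
#' @param res_a,res_b `dge_result` objects (shrunken fold changes filled if
#'   `use_shrunk`).
#' @param thresholds A [dge_thresholds()].
#' @param use_shrunk Gate and sign on shrunken estimates (default TRUE).
#' @return An object of class `direction_class`: list with `labels` (named
#'   per-gene character vector) and `tally` (named integer vector over all
#'   eight labels).
#' @export
classify_directions <- function(res_a, res_b, thresholds = dge_thresholds(),
                                use_shrunk = TRUE) {
  stopifnot(inherits(res_a, "dge_result"), inherits(res_b, "dge_result"))
  col <- if (use_shrunk) "lfc_shrunk" else "lfc_raw"
  genes <- shared_defined_genes(res_a, res_b, use_shrunk)
  la <- stats::setNames(res_a[[col]], res_a$gene_id)[genes]
  lb <- stats::setNames(res_b[[col]], res_b$gene_id)[genes]
  deg_a <- call_degs(res_a, thresholds, use_shrunk)
  deg_b <- call_degs(res_b, thresholds, use_shrunk)
  sig_a <- genes %in% deg_a$gene_id
  sig_b <- genes %in% deg_b$gene_id

  lab <- rep("not_significant", length(genes))
  both <- sig_a & sig_b
  same <- sign(la) == sign(lb)
  lab[both & same & la < 0] <- "both_down"
  lab[both & same & la >= 0] <- "both_up"
  lab[both & !same] <- "opposite"
  lab[sig_a & !sig_b & la < 0] <- "a_only_down"
  lab[sig_a & !sig_b & la >= 0] <- "a_only_up"
  lab[!sig_a & sig_b & lb < 0] <- "b_only_down"
  lab[!sig_a & sig_b & lb >= 0] <- "b_only_up"
  names(lab) <- genes

  tally <- vapply(DIRECTION_LEVELS, function(l) sum(lab == l), integer(1))
  structure(list(labels = lab, tally = tally), class = "direction_class")
}

#' @export
print.direction_class <- function(x, ...) {
  cat("direction_class over", length(x$labels), "genes:\n")
  print(x$tally)
  invisible(x)
}

#' Jaccard index of two identifier sets
#'
#' `|A intersect B| / |A union B|`; 0 by convention when both sets are empty.
#'
#' @param set_a,set_b Character vectors (duplicates collapse).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- union(a, b)
  if (!length(u)) {
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Assemble the full cross-platform concordance report
#'
#' Runs the concordance stages in order: annotation overlap of the panel's
#' endogenous + housekeeping genes against the annotation, restriction to
#' shared genes, fold-change correlations (raw and shrunken), direction
#' classification, DEG Venn counts and the Jaccard index. Platform "a" is the
#' panel side, "b" the sequencing side.
#'
#' @param res_a,res_b `dge_result` objects for the panel and sequencing
#'   platforms (with shrunken fold changes filled).
#' @param panel A `panel_definition`.
#' @param annotation Character vector of annotated (sequencing) gene IDs.
#' @param thresholds A [dge_thresholds()].
#' @return An object of class `concordance_report`: `overlap`, `lfc_raw` and
#'   `lfc_shrunk` correlation lists, `classes`, `venn` (`a_only`, `b_only`,
#'   `both`), `jaccard`, `n_deg_a`, `n_deg_b`.
#' @export
build_report <- function(res_a, res_b, panel, annotation,
                         thresholds = dge_thresholds()) {
  stopifnot(inherits(panel, "panel_definition"))
  pg <- panel_genes(panel, c("endogenous", "housekeeping"))
  overlap <- annotation_overlap(pg, annotation)
  shared <- intersect(pg, annotation)

  sub <- function(res) {
    out <- res[res$gene_id %in% shared, , drop = FALSE]
    class(out) <- class(res)
    out
  }
  ra <- sub(res_a)
  rb <- sub(res_b)

  lfc_raw <- lfc_concordance(ra, rb, use_shrunk = FALSE)
  lfc_shrunk <- lfc_concordance(ra, rb, use_shrunk = TRUE)
  classes <- classify_directions(ra, rb, thresholds, use_shrunk = TRUE)

  deg_a <- call_degs(ra, thresholds, use_shrunk = TRUE)$gene_id
  deg_b <- call_degs(rb, thresholds, use_shrunk = TRUE)$gene_id
  n_both <- length(intersect(deg_a, deg_b))
  venn <- c(
    a_only = length(deg_a) - n_both,
    b_only = length(deg_b) - n_both,
    both = n_both
  )
  structure(
    list(
      overlap = overlap,
      lfc_raw = lfc_raw[c("pearson", "spearman", "n_genes")],
      lfc_shrunk = lfc_shrunk[c("pearson", "spearman", "n_genes")],
      classes = classes,
      venn = venn,
      jaccard = jaccard_index(deg_a, deg_b),
      n_deg_a = length(deg_a),
      n_deg_b = length(deg_b)
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report\n")
  cat(
    "  overlap: ", x$overlap$n_found, "/", x$overlap$n_panel, " (",
    format_percent(x$overlap$pct_found), "%)\n",
    sep = ""
  )
  cat(
    "  log2FC correlation (raw): Pearson ", round(x$lfc_raw$pearson, 2),
    ", Spearman ", round(x$lfc_raw$spearman, 2), " over ",
    x$lfc_raw$n_genes, " genes\n",
    sep = ""
  )
  cat(
    "  DEGs: panel ", x$n_deg_a, ", sequencing ", x$n_deg_b, ", shared ",
    x$venn[["both"]], "; Jaccard ", round(x$jaccard, 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Serialize a concordance report to JSON
#'
#' @param report A `concordance_report`.
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "concordance_report"))
  x <- list(
    overlap = report$overlap[c("n_panel", "n_found", "n_missing", "pct_found")],
    missing_ids = report$overlap$missing_ids,
    lfc_raw = report$lfc_raw,
    lfc_shrunk = report$lfc_shrunk,
    direction_tally = as.list(report$classes$tally),
    venn = as.list(report$venn),
    jaccard = report$jaccard,
    n_deg_a = report$n_deg_a,
    n_deg_b = report$n_deg_b
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
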