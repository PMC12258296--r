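# Sample-wise and gene-wise cross-platform correlation profiles, expression
# strata, box summaries, and the correlation-strength interpretation bins.

#' Pearson correlation of log-transformed counts
#'
#' Product-moment correlation of `log2(x + pseudocount)` and
#' `log2(y + pseudocount)`; the log transform damps the influence of a few
#' very highly expressed genes. Returns `NA` when either transformed vector
#' has zero variance.
#'
#' @param x,y Nonnegative numeric vectors of equal length >= 3.
#' @param pseudocount Nonnegative value added before the log (default 1).
#' @return A correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_log <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(x < 0) || any(y < 0)) stop("inputs must be nonnegative")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    return(NA_real_)
  }
  stats::cor(lx, ly)
}

#' Pearson correlation with zero-variance guard
#' @inheritParams pearson_log
#' @return Coefficient or `NA` when either vector is constant.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Spearman rank correlation with mid-ranks for ties
#' @inheritParams pearson_log
#' @return Coefficient or `NA` when either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

.coef_fun <- function(coefficient, pseudocount) {
  switch(coefficient,
    pearson = pearson_cor,
    pearson_log = function(x, y) pearson_log(x, y, pseudocount),
    spearman = spearman_cor
  )
}

#' Cross-platform correlation profile
#'
#' Computes one correlation coefficient per matched sample (`axis = "sample"`,
#' correlating the two platforms' values across the shared genes within each
#' sample) or per shared gene (`axis = "gene"`, correlating across the matched
#' samples). The gene universe is the intersection of the two matrices' genes
#' — panel genes missing from the sequencing annotation drop out here. Units
#' with zero variance on either platform yield `NA` coefficients, which are
#' counted and excluded from summaries downstream.
#'
#' @param a,b `count_matrix` or `normalized_matrix` for the two platforms,
#'   sharing sample IDs.
#' @param axis `"sample"` or `"gene"`.
#' @param coefficient `"pearson"`, `"pearson_log"` or `"spearman"`.
#' @param pseudocount Pseudocount for `"pearson_log"`.
#' @return An object of class `correlation_set`: list with `axis`,
#'   `coefficient`, `normalization` (tags of `a` and `b`), `ids`, `r` (named,
#'   may contain `NA`), `n_undefined` and `pseudocount`.
#' @export
correlation_profile <- function(a, b, axis = c("sample", "gene"),
                                coefficient = c("pearson", "pearson_log", "spearman"),
                                pseudocount = 1) {
  axis <- match.arg(axis)
  coefficient <- match.arg(coefficient)
  ma <- values(a)
  mb <- values(b)
  genes <- intersect(rownames(ma), rownames(mb))
  samples <- intersect(colnames(ma), colnames(mb))
  n_obs <- if (axis == "sample") length(genes) else length(samples)
  if (n_obs < 3) {
    stop("fewer than 3 shared ", if (axis == "sample") "genes" else "samples")
  }
  if (length(samples) < 1 || length(genes) < 1) stop("no shared samples/genes")
  ma <- ma[genes, samples, drop = FALSE]
  mb <- mb[genes, samples, drop = FALSE]
  f <- .coef_fun(coefficient, pseudocount)
  if (axis == "sample") {
    r <- vapply(samples, function(s) f(ma[, s], mb[, s]), numeric(1))
    ids <- samples
  } else {
    r <- vapply(genes, function(g) f(ma[g, ], mb[g, ]), numeric(1))
    ids <- genes
  }
  norm_tag <- function(x) if (inherits(x, "normalized_matrix")) x$method else "raw"
  structure(
    list(
      axis = axis, coefficient = coefficient,
      normalization = c(a = norm_tag(a), b = norm_tag(b)),
      ids = ids, r = r, n_undefined = sum(is.na(r)),
      pseudocount = if (coefficient == "pearson_log") pseudocount else NA_real_
    ),
    class = "correlation_set"
  )
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(
    "correlation_set: ", x$axis, "-wise ", x$coefficient,
    " (", paste(x$normalization, collapse = " vs "), "), ",
    length(x$r), " ids, ", x$n_undefined, " undefined; median r = ",
    round(stats::median(x$r, na.rm = TRUE), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Correlation-strength interpretation bins
#'
#' Medical-field convention: `|r| >= 0.8` very strong, `0.6 <= |r| < 0.8`
#' moderately strong, `0.3 <= |r| < 0.6` fair, `|r| < 0.3` poor. The bin is
#' assigned on the magnitude; retrieve the sign separately when labelling
#' negative correlations. `NA` propagates.
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
classify_strength <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("coefficients must lie in [-1, 1]")
  a <- abs(r)
  out <- rep(NA_character_, length(r))
  out[a < 0.3] <- "poor"
  out[a >= 0.3 & a < 0.6] <- "fair"
  out[a >= 0.6 & a < 0.8] <- "moderately strong"
  out[a >= 0.8] <- "very strong"
  out
}

#' Five-number box summary with 1.5 IQR whiskers
#'
#' Quartiles use linear interpolation (R quantile type 7), whiskers extend to
#' the most extreme points within 1.5 IQR of the quartiles, points beyond are
#' outliers. `NA` values are dropped and counted.
#'
#' @param x Numeric vector with at least one defined value.
#' @return An object of class `box_summary`: list with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`, `n_undefined`.
#' @export
summarize_box <- function(x) {
  n_na <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) stop("no defined values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(
    list(
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(x[inside]), whisker_high = max(x[inside]),
      outliers = sort(x[!inside]), n = length(x), n_undefined = n_na
    ),
    class = "box_summary"
  )
}

#' @export
print.box_summary <- function(x, ...) {
  cat(
    "box_summary: median ", round(x$median, 3), " [q1 ", round(x$q1, 3),
    ", q3 ", round(x$q3, 3), "], ", length(x$outliers), " outlier(s), n = ",
    x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' Expression-strata correlation summaries (all / top 90% / top 50%)
#'
#' Groups the gene-wise coefficients into nested expression strata — all
#' genes, genes above the 10th percentile of mean log expression (top 90%),
#' and genes above the 50th percentile (top 50%) — and box-summarizes the
#' defined coefficients of each stratum. Thresholds are quantiles (type 7) of
#' `mean_expr`; membership is inclusive (`>=`), so with distinct values the
#' top-50% stratum holds `ceiling(n/2)` genes.
#'
#' @param gene_set A gene-axis `correlation_set`.
#' @param mean_expr Named per-gene mean log expression covering
#'   `gene_set$ids`; which platform it comes from is the caller's choice.
#' @param probs Quantile cutpoints defining the strata below `all`
#'   (default `c(0.10, 0.50)`).
#' @return Named list (`all`, `top90`, `top50`), each with `genes`,
#'   `threshold` and `box` (a [summarize_box()] result).
#' @export
strata_correlations <- function(gene_set, mean_expr, probs = c(0.10, 0.50)) {
  stopifnot(inherits(gene_set, "correlation_set"))
  if (gene_set$axis != "gene") stop("strata require a gene-axis correlation set")
  if (is.null(names(mean_expr))) stop("`mean_expr` must be named by gene")
  missing <- setdiff(gene_set$ids, names(mean_expr))
  if (length(missing)) {
    stop("mean_expr missing gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  if (any(diff(probs) <= 0)) stop("`probs` must be strictly increasing")
  me <- mean_expr[gene_set$ids]
  thr <- stats::quantile(me, probs, names = FALSE, type = 7)
  sets <- c(
    list(all = gene_set$ids),
    stats::setNames(
      lapply(thr, function(t) gene_set$ids[me >= t]),
      c("top90", "top50")[seq_along(thr)]
    )
  )
  thresholds <- c(-Inf, thr)
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (i in seq_along(sets)) {
    genes <- sets[[i]]
    r <- gene_set$r[genes]
    if (!length(r) || all(is.na(r))) stop("empty stratum: ", names(sets)[i])
    out[[i]] <- list(genes = genes, threshold = thresholds[i], box = summarize_box(r))
  }
  out
}
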