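# The four normalization schemes compared across platforms, implemented from
# first principles: CPM, TMM (trimmed mean of M-values), RLE (median of
# ratios), and the two-step positive-control/housekeeping panel normalization.
# All four are per-sample rescalings of the raw counts.

new_scale_factors <- function(method, factors, flags = NULL) {
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("scale factors must be positive and finite")
  }
  if (is.null(flags)) {
    flags <- data.frame(
      sample_id = names(factors), flagged = FALSE, reason = "",
      stringsAsFactors = FALSE
    )
  }
  structure(list(method = method, factors = factors, flags = flags),
    class = "scale_factors"
  )
}

#' @export
print.scale_factors <- function(x, ...) {
  cat("scale_factors [", x$method, "]\n", sep = "")
  print(round(x$factors, 4))
  if (any(x$flags$flagged)) {
    cat("flagged:", paste(x$flags$sample_id[x$flags$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

new_normalized_matrix <- function(values, method, factors_used, template) {
  structure(
    list(
      values = values, method = method, factors_used = factors_used,
      platform = template$platform, sample_meta = template$sample_meta
    ),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix [", x$method, "]: ", nrow(x$values), " genes x ",
    ncol(x$values), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' Counts-per-million normalization
#'
#' Scales each sample to a library size of one million:
#' `value_gs = count_gs / libsize_s * 1e6`, so every column sums to 1e6.
#'
#' @param counts A `count_matrix`.
#' @return A `normalized_matrix` with method `"cpm"`.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  }
  vals <- sweep(counts$counts, 2, lib, "/") * 1e6
  sf <- new_scale_factors("CPM", lib / 1e6)
  new_normalized_matrix(vals, "cpm", sf, counts)
}

# 75th-percentile of library-size-scaled counts, used for reference selection
.upper_quartile <- function(counts, lib) {
  apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75, names = FALSE)
}

tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  use <- obs > 0 & ref > 0 # zeros in either member of the pair are excluded
  if (!any(use)) {
    return(NA_real_)
  }
  o <- obs[use] / lib_obs
  r <- ref[use] / lib_ref
  m <- log2(o / r)
  a <- 0.5 * log2(o * r)
  # delta-method asymptotic variance of M
  v <- (lib_obs - obs[use]) / (lib_obs * obs[use]) +
    (lib_ref - ref[use]) / (lib_ref * ref[use])
  if (max(abs(m)) < 1e-6) {
    return(1)
  }
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) {
    return(NA_real_)
  }
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' TMM scale factors (trimmed mean of M-values)
#'
#' The reference sample is the one whose upper-quartile of library-size-scaled
#' counts is closest to the mean upper-quartile. For every sample, gene-wise
#' log ratios (M) and average log abundances (A) against the reference are
#' computed on genes nonzero in both members of the pair, the stated M and A
#' fractions are trimmed from both tails, and the factor is `2^` the
#' inverse-variance weighted mean of the surviving M-values. Factors are
#' divided by their geometric mean, so their product is 1.
#'
#' @param counts A `count_matrix` with >= 2 samples.
#' @param trim_m Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A-values trimmed from each tail (default 0.05).
#' @param ref_sample Optional sample ID to force as reference.
#' @return A `scale_factors` with method `"TMM"`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref_sample = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- counts$counts
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with zero library size")
  if (is.null(ref_sample)) {
    uq <- .upper_quartile(x, lib)
    ref_i <- which.min(abs(uq - mean(uq)))
  } else {
    ref_i <- match(ref_sample, colnames(x))
    if (is.na(ref_i)) stop("unknown reference sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(x)), function(s) {
    if (s == ref_i) {
      return(1)
    }
    tmm_pair_factor(x[, s], x[, ref_i], lib[s], lib[ref_i], trim_m, trim_a)
  }, numeric(1))
  bad <- colnames(x)[is.na(f)]
  if (length(bad)) {
    stop(
      "sample(s) share no co-expressed genes with the reference: ",
      paste(bad, collapse = ", ")
    )
  }
  f <- f / exp(mean(log(f))) # geometric-mean centering: product = 1
  new_scale_factors("TMM", stats::setNames(f, colnames(x)))
}

#' RLE scale factors (median of ratios)
#'
#' Builds a pseudo-reference as the per-gene geometric mean across samples
#' (genes with any zero excluded) and takes each sample's factor as the median
#' ratio of its counts to the reference.
#'
#' @param counts A `count_matrix`.
#' @return A `scale_factors` with method `"RLE"`.
#' @export
rle_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  x <- counts$counts
  usable <- rowSums(x == 0) == 0
  if (!any(usable)) stop("no gene with nonzero counts in every sample")
  xs <- x[usable, , drop = FALSE]
  ref <- exp(rowMeans(log(xs)))
  f <- apply(xs / ref, 2, stats::median)
  new_scale_factors("RLE", stats::setNames(f, colnames(x)))
}

geometric_mean <- function(x) exp(mean(log(x)))

panel_step_factors <- function(mat, ref_ids, what) {
  sub <- mat[ref_ids, , drop = FALSE]
  # geometric mean over the nonzero reference counts; a probe at zero would
  # otherwise annihilate the mean, and only an all-zero sample is an error
  gm <- apply(sub, 2, function(col) {
    if (all(col == 0)) {
      return(0)
    }
    geometric_mean(col[col > 0])
  })
  zero <- colnames(mat)[gm == 0]
  if (length(zero)) {
    stop(
      "all-zero ", what, " counts for sample(s): ",
      paste(zero, collapse = ", ")
    )
  }
  mean(gm) / gm
}

#' Two-step panel normalization (positive controls, then housekeepers)
#'
#' Step 1 scales each sample by (arithmetic mean over samples of the geometric
#' mean of positive-control counts) / (that sample's positive-control
#' geometric mean); step 2 repeats the computation with housekeeping genes on
#' the step-1 output. Samples whose step factor falls outside the flag range
#' are flagged, not dropped.
#'
#' @param counts A `count_matrix` containing control probes and housekeepers.
#' @param panel A `panel_definition` declaring gene classes.
#' @param pos_flag_range,hk_flag_range Acceptable factor intervals for the two
#'   steps; defaults `[0.3, 3]` and `[0.1, 10]`.
#' @return A `normalized_matrix` with method `"panel"`; `factors_used$factors`
#'   holds the combined (step1 * step2) per-sample factor and
#'   `factors_used$flags` the per-step flags.
#' @export
panel_two_step_normalize <- function(counts, panel,
                                     pos_flag_range = c(0.3, 3),
                                     hk_flag_range = c(0.1, 10)) {
  stopifnot(inherits(counts, "count_matrix"), inherits(panel, "panel_definition"))
  pos <- intersect(panel_genes(panel, "positive"), gene_ids(counts))
  hk <- intersect(panel_genes(panel, "housekeeping"), gene_ids(counts))
  if (!length(pos)) stop("no positive-control probe present in the counts")
  if (!length(hk)) stop("no housekeeping gene present in the counts")

  f1 <- panel_step_factors(counts$counts, pos, "positive-control")
  step1 <- sweep(counts$counts, 2, f1, "*")
  f2 <- panel_step_factors(step1, hk, "housekeeping")
  vals <- sweep(step1, 2, f2, "*")

  flag1 <- f1 < pos_flag_range[1] | f1 > pos_flag_range[2]
  flag2 <- f2 < hk_flag_range[1] | f2 > hk_flag_range[2]
  reason <- character(length(f1))
  reason[flag1] <- sprintf("positive-control factor %.3g outside [%g, %g]",
    f1[flag1], pos_flag_range[1], pos_flag_range[2]
  )
  reason[flag2] <- trimws(paste(
    reason[flag2],
    sprintf(
      "housekeeping factor %.3g outside [%g, %g]",
      f2[flag2], hk_flag_range[1], hk_flag_range[2]
    )
  ))
  flags <- data.frame(
    sample_id = colnames(counts$counts),
    flagged = flag1 | flag2, reason = reason,
    step1_factor = unname(f1), step2_factor = unname(f2),
    stringsAsFactors = FALSE
  )
  sf <- new_scale_factors("PANEL", f1 * f2, flags)
  new_normalized_matrix(vals, "panel", sf, counts)
}

#' Normalize a count matrix by a named method
#'
#' Dispatcher used by the pipeline: `"cpm"` scales columns to one million;
#' `"tmm"` computes CPM on TMM-effective library sizes
#' (`libsize_s * factor_s`); `"rle"` divides each column by its median-of-
#' ratios size factor; `"none"` returns the raw counts as values. `"panel"`
#' requires a `panel` definition and applies the two-step scheme.
#'
#' @param counts A `count_matrix`.
#' @param method One of `"cpm"`, `"tmm"`, `"rle"`, `"panel"`, `"none"`.
#' @param panel `panel_definition`, required for `method = "panel"`.
#' @return A `normalized_matrix`.
#' @export
normalize_counts <- function(counts, method = c("cpm", "tmm", "rle", "panel", "none"),
                             panel = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_matrix"))
  switch(method,
    cpm = cpm_normalize(counts),
    tmm = {
      sf <- tmm_factors(counts)
      eff <- colSums(counts$counts) * sf$factors
      vals <- sweep(counts$counts, 2, eff, "/") * 1e6
      new_normalized_matrix(vals, "tmm", sf, counts)
    },
    rle = {
      sf <- rle_factors(counts)
      vals <- sweep(counts$counts, 2, sf$factors, "/")
      new_normalized_matrix(vals, "rle", sf, counts)
    },
    panel = {
      if (is.null(panel)) stop("`panel` is required for panel normalization")
      panel_two_step_normalize(counts, panel)
    },
    none = {
      sf <- new_scale_factors("NONE", stats::setNames(
        rep(1, ncol(counts$counts)), colnames(counts$counts)
      ))
      new_normalized_matrix(counts$counts, "none", sf, counts)
    }
  )
}

#' Subset a normalized matrix to a gene set
#'
#' Keeps factors and metadata; used to restrict sequencing-side matrices
#' (normalized on the full gene set) to the panel genes for comparison.
#'
#' @param x A `normalized_matrix`.
#' @param genes Gene IDs to keep (order preserved; must all be present).
#' @return A `normalized_matrix`.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "normalized_matrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) {
    stop("gene(s) not present: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  x$values <- x$values[genes, , drop = FALSE]
  x
}
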