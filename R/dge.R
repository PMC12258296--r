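# Self-contained two-group differential-expression engine: per-gene NB
# log-link GLM fit by IRLS at a moment-based dispersion estimate, Wald test,
# normal-prior log2FC shrinkage, and BH/BY step-up adjustment. An explicit,
# documented approximation of the DESeq2/nSolver stages it stands in for: no
# empirical-Bayes dispersion shrinkage, no apeglm prior.

DISP_FLOOR <- 1e-8
IRLS_TOL <- 1e-8
IRLS_MAXIT <- 100L
ETA_CLAMP <- 30 # natural-log scale; keeps exp(eta) finite at boundary fits

#' Significance thresholds for DEG calling
#'
#' @param lfc_cut Absolute log2 fold-change cutoff (inclusive), default 1.
#' @param alpha Adjusted-p cutoff (inclusive), default 0.05.
#' @param adjust Which adjusted p-value to gate on: `"BY"` (default, the more
#'   conservative) or `"BH"`.
#' @return An object of class `dge_thresholds`.
#' @export
dge_thresholds <- function(lfc_cut = 1, alpha = 0.05, adjust = c("BY", "BH")) {
  adjust <- match.arg(adjust)
  if (lfc_cut <= 0) stop("`lfc_cut` must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(lfc_cut = lfc_cut, alpha = alpha, adjust = adjust),
    class = "dge_thresholds"
  )
}

# Per-gene moment estimate of NB dispersion phi (variance = mu + phi mu^2),
# pooled across groups on size-factor-normalized counts, floored.
moment_dispersion <- function(z, group_b) {
  est_one <- function(zz) {
    m <- rowMeans(zz)
    v <- apply(zz, 1, stats::var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  pa <- est_one(z[, !group_b, drop = FALSE])
  pb <- est_one(z[, group_b, drop = FALSE])
  na <- sum(!group_b) - 1
  nb <- sum(group_b) - 1
  w <- cbind(ifelse(is.na(pa), 0, na), ifelse(is.na(pb), 0, nb))
  p <- cbind(ifelse(is.na(pa), 0, pa), ifelse(is.na(pb), 0, pb))
  phi <- rowSums(p * w) / pmax(rowSums(w), 1)
  pmax(phi, DISP_FLOOR)
}

#' Two-group negative-binomial Wald differential expression test
#'
#' For every gene, fits the log-link NB GLM
#' `log mu_gi = log sf_i + beta0_g + beta1_g * [group_i == B]` by iteratively
#' reweighted least squares at a per-gene moment dispersion estimate (floored
#' at 1e-8), and tests `beta1 = 0` with a two-sided Wald test. The Wald
#' statistic is referred to a t distribution with `N - 2` degrees of freedom
#' rather than the normal: with per-gene dispersions estimated from a handful
#' of samples, the normal reference is markedly anticonservative at n = 5 per
#' group, while the t reference keeps the null type-I error near nominal.
#' `lfc_raw = beta1 / ln 2`. Genes with all-zero counts get `NA` statistics
#' and are excluded from the adjustment denominators. Both BH- and BY-adjusted
#' p-values are reported.
#'
#' @param counts A `count_matrix`.
#' @param groups Per-sample labels (exactly two levels, each with >= 2
#'   samples); defaults to the `group` column of the sample metadata. The
#'   second level in sort order (or factor order) is the "B" group whose fold
#'   change is reported.
#' @param size_factors A `scale_factors` (e.g. from [rle_factors()]) or a
#'   named positive vector; defaults to RLE factors computed on `counts`.
#' @return An object of class `dge_result` (also a data.frame): columns
#'   `gene_id`, `base_mean`, `lfc_raw`, `lfc_shrunk` (NA until
#'   [shrink_lfc()]), `se`, `stat`, `p`, `padj_bh`, `padj_by`, `dispersion`.
#' @export
nb_wald_dge <- function(counts, groups = NULL, size_factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  if (is.null(groups)) {
    if (!"group" %in% names(counts$sample_meta)) {
      stop("`groups` not given and sample_meta has no `group` column")
    }
    groups <- counts$sample_meta$group
  }
  if (length(groups) != ncol(y)) stop("`groups` length must match sample count")
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(groups))
  if (length(lev) != 2) stop("exactly two group labels required")
  group_b <- as.character(groups) == lev[2]
  if (sum(group_b) < 2 || sum(!group_b) < 2) {
    stop("each group needs at least 2 samples")
  }

  if (is.null(size_factors)) size_factors <- rle_factors(counts)
  sf <- if (inherits(size_factors, "scale_factors")) size_factors$factors else size_factors
  if (length(sf) != ncol(y)) stop("size factors not conformable with samples")
  if (!is.null(names(sf))) {
    if (!setequal(names(sf), colnames(y))) stop("size factor names do not match samples")
    sf <- sf[colnames(y)]
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be positive")

  z <- sweep(y, 2, sf, "/") # normalized counts
  base_mean <- rowMeans(z)
  defined <- rowSums(y) > 0
  phi <- moment_dispersion(z, group_b)

  n_g <- nrow(y)
  m_a <- rowMeans(z[, !group_b, drop = FALSE])
  m_b <- rowMeans(z[, group_b, drop = FALSE])
  b0 <- log(pmax(m_a, 1e-8))
  b1 <- log(pmax(m_b, 1e-8)) - b0
  off <- matrix(log(sf), n_g, ncol(y), byrow = TRUE)
  xb <- matrix(as.numeric(group_b), n_g, ncol(y), byrow = TRUE)

  for (it in seq_len(IRLS_MAXIT)) {
    eta <- b0 + outer(b1, as.numeric(group_b))
    eta <- pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)
    mu <- exp(eta + off)
    w <- mu / (1 + phi * mu)
    zz <- (eta + off) + (y - mu) / mu # working response incl. offset
    zz_off <- zz - off
    sw_a <- rowSums(w * (1 - xb))
    sw_b <- rowSums(w * xb)
    swz_a <- rowSums(w * zz_off * (1 - xb))
    swz_b <- rowSums(w * zz_off * xb)
    b0_new <- swz_a / sw_a
    b1_new <- swz_b / sw_b - b0_new
    delta <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    delta[!defined] <- 0
    b0 <- ifelse(defined, b0_new, NA_real_)
    b1 <- ifelse(defined, b1_new, NA_real_)
    if (all(delta[defined & is.finite(delta)] < IRLS_TOL)) break
  }

  eta <- pmin(pmax(b0 + outer(b1, as.numeric(group_b)), -ETA_CLAMP), ETA_CLAMP)
  mu <- exp(eta + off)
  w <- mu / (1 + phi * mu)
  se_b1 <- sqrt(1 / rowSums(w * (1 - xb)) + 1 / rowSums(w * xb))
  stat <- b1 / se_b1
  df <- ncol(y) - 2L
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[!defined] <- NA_real_
  stat[!defined] <- NA_real_

  res <- data.frame(
    gene_id = rownames(y),
    base_mean = base_mean,
    lfc_raw = b1 / log(2),
    lfc_shrunk = NA_real_,
    se = se_b1 / log(2),
    stat = stat,
    p = p,
    padj_bh = adjust_pvalues(p, "BH"),
    padj_by = adjust_pvalues(p, "BY"),
    dispersion = ifelse(defined, phi, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$se[!defined] <- NA_real_
  res$lfc_raw[!defined] <- NA_real_
  class(res) <- c("dge_result", "data.frame")
  attr(res, "groups") <- stats::setNames(lev, c("A", "B"))
  attr(res, "df") <- df
  res
}

#' Normal-prior shrinkage of log2 fold changes
#'
#' Posterior mean under a zero-centred normal prior:
#' `lfc_shrunk = lfc_raw * prior_sd^2 / (prior_sd^2 + se^2)`. Genes with large
#' standard errors — typically low-count genes whose raw estimates can be
#' artificially extreme — are pulled hardest toward zero. With
#' `prior_sd = "auto"` the prior sd is the 0.90 quantile of `|lfc_raw|` over
#' genes with defined estimates.
#'
#' @param result A `dge_result`.
#' @param prior_sd Positive number, or `"auto"`.
#' @param auto_quantile Quantile of `|lfc_raw|` used when `prior_sd = "auto"`.
#' @return The `dge_result` with `lfc_shrunk` filled in.
#' @export
shrink_lfc <- function(result, prior_sd = "auto", auto_quantile = 0.90) {
  stopifnot(inherits(result, "dge_result"))
  if (identical(prior_sd, "auto")) {
    ok <- !is.na(result$lfc_raw)
    if (!any(ok)) stop("no defined fold changes to set the prior from")
    prior_sd <- stats::quantile(abs(result$lfc_raw[ok]), auto_quantile, names = FALSE)
    prior_sd <- max(prior_sd, 1e-3) # guard: all-null data still gives a proper prior
  }
  if (!is.numeric(prior_sd) || prior_sd <= 0) stop("`prior_sd` must be > 0")
  shrink <- prior_sd^2 / (prior_sd^2 + result$se^2)
  result$lfc_shrunk <- result$lfc_raw * shrink
  attr(result, "prior_sd") <- prior_sd
  result
}

#' Benjamini-Hochberg / Benjamini-Yekutieli step-up adjustment
#'
#' Step-up FDR adjustment: sorted `p_(i)` become `min over j >= i of
#' m * p_(j) / j`, capped at 1. BY multiplies by the harmonic sum
#' `c(m) = sum(1/i)`, making it valid under arbitrary dependence and always at
#' least as conservative as BH. `NA` entries pass through and do not count
#' toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param method `"BH"` or `"BY"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) {
    return(out)
  }
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  adj <- cummin(cm * m / (m:1) * pp[o])
  adj <- pmin(adj, 1)
  out[ok][o] <- adj
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its adjusted p-value is at most `alpha` AND its log2
#' fold change is at most `-lfc_cut` or at least `lfc_cut` (both gates
#' inclusive). Direction is the fold-change sign.
#'
#' @param result A `dge_result`.
#' @param thresholds A [dge_thresholds()].
#' @param use_shrunk Gate on `lfc_shrunk` (default) or `lfc_raw`.
#' @return data.frame of DEGs: `gene_id`, `lfc`, `padj`,
#'   `direction` (`"up"`/`"down"`).
#' @export
call_degs <- function(result, thresholds = dge_thresholds(), use_shrunk = TRUE) {
  stopifnot(inherits(result, "dge_result"), inherits(thresholds, "dge_thresholds"))
  lfc <- if (use_shrunk) result$lfc_shrunk else result$lfc_raw
  if (use_shrunk && all(is.na(lfc)) && !all(is.na(result$lfc_raw))) {
    stop("`lfc_shrunk` is empty; run shrink_lfc() first or set use_shrunk = FALSE")
  }
  padj <- if (thresholds$adjust == "BY") result$padj_by else result$padj_bh
  hit <- !is.na(padj) & !is.na(lfc) &
    padj <= thresholds$alpha & abs(lfc) >= thresholds$lfc_cut
  data.frame(
    gene_id = result$gene_id[hit],
    lfc = lfc[hit],
    padj = padj[hit],
    direction = ifelse(lfc[hit] >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
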