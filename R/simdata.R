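# Paired-platform study simulator: shared latent expression, platform-specific
# capture/depth/noise, negative-binomial counts. Ground truth travels with the
# simulated study so every downstream stage is testable without external data.

child_seed <- function(seed, k) {
  # deterministic per-component seeds below 2^31 from one master seed
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Simulate ground-truth expression for a two-group design
#'
#' Draws per-gene baseline log2 means and, for a fixed fraction of genes,
#' nonzero true log2 fold changes (group B versus group A) from a zero-mean
#' normal. Non-DE genes have a true fold change of exactly zero.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_per_group Integer vector of length 2: samples in groups A and B
#'   (each >= 2).
#' @param de_fraction Fraction of genes that are truly differentially
#'   expressed, in `[0, 1]`. The DE gene count is `round(de_fraction * n_genes)`.
#' @param lfc_sd Standard deviation of true log2 fold changes for DE genes.
#' @param baseline_mean_log2,baseline_sd_log2 Mean and sd of per-gene baseline
#'   log2 expression.
#' @param seed Integer seed; equal seeds give identical output.
#' @return An object of class `true_expression` with fields `gene_ids`,
#'   `baseline_log2`, `lfc_true`, `is_de`, `group_of_sample` and `n_per_group`.
#' @export
simulate_truth <- function(n_genes, n_per_group, de_fraction, lfc_sd,
                           baseline_mean_log2 = 4, baseline_sd_log2 = 2,
                           seed = 1L) {
  stopifnot(length(n_per_group) == 2)
  args <- c(n_genes, n_per_group, de_fraction, lfc_sd, baseline_mean_log2,
            baseline_sd_log2, seed)
  if (anyNA(args) || any(!is.finite(args))) {
    stop("all simulate_truth() arguments must be finite")
  }
  if (n_genes < 1) stop("`n_genes` must be >= 1")
  if (any(n_per_group < 2)) stop("both group sizes must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` must be in [0, 1]")
  if (lfc_sd <= 0) stop("`lfc_sd` must be > 0")
  if (baseline_sd_log2 <= 0) stop("`baseline_sd_log2` must be > 0")

  set.seed(child_seed(seed, 1L))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, baseline_mean_log2, baseline_sd_log2)
  n_de <- round(de_fraction * n_genes)
  is_de <- rep(FALSE, n_genes)
  if (n_de > 0) is_de[sample.int(n_genes, n_de)] <- TRUE
  lfc <- numeric(n_genes)
  lfc[is_de] <- stats::rnorm(n_de, 0, lfc_sd)

  groups <- rep(c("A", "B"), times = n_per_group)
  names(groups) <- sprintf("S%02d", seq_along(groups))
  structure(
    list(
      gene_ids = gene_ids,
      baseline_log2 = stats::setNames(baseline, gene_ids),
      lfc_true = stats::setNames(lfc, gene_ids),
      is_de = stats::setNames(is_de, gene_ids),
      group_of_sample = groups,
      n_per_group = as.integer(n_per_group)
    ),
    class = "true_expression"
  )
}

#' Platform measurement parameters
#'
#' Describes one platform's count-generating process on top of the shared
#' truth: negative-binomial dispersion `phi` (variance `mu + phi * mu^2`),
#' per-sample sequencing-depth spread, a per-gene capture/probe efficiency
#' drawn once per platform (systematic 3'-bias or probe effects), optional
#' restriction to a panel gene subset, per-observation extra log-normal noise,
#' and a global depth offset in log2 units.
#'
#' @param dispersion NB dispersion `phi >= 0`; 0 gives Poisson counts.
#' @param library_size_log2_sd Per-sample depth spread (log2 sd), >= 0.
#' @param capture_log2_sd Per-gene platform efficiency spread (log2 sd), >= 0.
#' @param panel_subset Optional character vector of gene IDs to restrict to.
#' @param noise_log2_sd Per-observation log-normal noise (log2 sd), >= 0.
#' @param depth_log2_offset Added to every log2 mean; shifts overall depth.
#' @return An object of class `platform_params`.
#' @export
platform_params <- function(dispersion = 0.1, library_size_log2_sd = 0.25,
                            capture_log2_sd = 0.5, panel_subset = NULL,
                            noise_log2_sd = 0.1, depth_log2_offset = 0) {
  sds <- c(library_size_log2_sd, capture_log2_sd, noise_log2_sd)
  if (anyNA(c(dispersion, sds, depth_log2_offset))) stop("parameters must not be NA")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (any(sds < 0)) stop("sd parameters must be >= 0")
  structure(
    list(
      dispersion = dispersion,
      library_size_log2_sd = library_size_log2_sd,
      capture_log2_sd = capture_log2_sd,
      panel_subset = panel_subset,
      noise_log2_sd = noise_log2_sd,
      depth_log2_offset = depth_log2_offset
    ),
    class = "platform_params"
  )
}

#' Draw one platform's count matrix from the shared truth
#'
#' Each count is negative binomial with mean
#' `mu_gs = 2^(baseline_g + lfc_g * [group_s == B] + capture_g + depth_s +
#' eps_gs + offset)` and variance `mu + phi * mu^2`. Capture effects are drawn
#' once per gene (per call, i.e. per platform), depth once per sample, `eps`
#' per observation.
#'
#' @param truth A `true_expression` object.
#' @param params A `platform_params` object.
#' @param seed Integer seed.
#' @param platform Platform tag stored on the result.
#' @param latent_log2 Optional gene-by-sample matrix of shared latent log2
#'   deviations (biological sample-to-sample variation measured by both
#'   platforms); rownames must cover the simulated genes. Default none.
#' @return A `count_matrix`; the drawn per-sample depth (log2) is attached as
#'   attribute `depth_log2`.
#' @export
simulate_platform <- function(truth, params, seed = 1L, platform = "platform",
                              latent_log2 = NULL) {
  stopifnot(inherits(truth, "true_expression"), inherits(params, "platform_params"))
  genes <- truth$gene_ids
  if (!is.null(params$panel_subset)) {
    missing <- setdiff(params$panel_subset, genes)
    if (length(missing)) {
      stop("panel_subset gene(s) not in truth: ", paste(missing, collapse = ", "))
    }
    genes <- params$panel_subset # order of the subset is preserved
  }
  n_g <- length(genes)
  samples <- names(truth$group_of_sample)
  n_s <- length(samples)
  is_b <- as.numeric(truth$group_of_sample == "B")

  set.seed(child_seed(seed, 2L))
  capture <- stats::rnorm(n_g, 0, params$capture_log2_sd)
  depth <- stats::rnorm(n_s, 0, params$library_size_log2_sd)
  eps <- matrix(stats::rnorm(n_g * n_s, 0, params$noise_log2_sd), n_g, n_s)

  log2_mu <- outer(
    truth$baseline_log2[genes] + capture,
    depth + params$depth_log2_offset, "+"
  ) +
    outer(truth$lfc_true[genes], is_b) + eps
  if (!is.null(latent_log2)) {
    if (!all(genes %in% rownames(latent_log2))) {
      stop("`latent_log2` must cover all simulated genes")
    }
    log2_mu <- log2_mu + latent_log2[genes, names(truth$group_of_sample), drop = FALSE]
  }
  mu <- 2^log2_mu
  counts <- if (params$dispersion > 0) {
    stats::rnbinom(n_g * n_s, mu = mu, size = 1 / params$dispersion)
  } else {
    stats::rpois(n_g * n_s, lambda = mu)
  }
  counts <- matrix(counts, n_g, n_s, dimnames = list(genes, samples))
  meta <- data.frame(
    sample_id = samples,
    group = unname(truth$group_of_sample),
    stringsAsFactors = FALSE
  )
  out <- count_matrix(counts, platform = platform, sample_meta = meta)
  attr(out, "depth_log2") <- stats::setNames(depth, samples)
  out
}

#' Build a hybridization-panel definition over the simulated truth
#'
#' Samples endogenous panel genes from the truth, housekeeping genes from the
#' non-DE genes only, adds synthetic positive/negative control probes (IDs not
#' present in the truth), and marks a subset of endogenous genes as missing
#' from the sequencing annotation.
#'
#' @param truth A `true_expression`.
#' @param n_endogenous,n_housekeeping Panel content sizes;
#'   `n_endogenous + n_housekeeping` must not exceed the number of genes and
#'   housekeeping genes must fit in the non-DE pool.
#' @param n_pos_controls,n_neg_controls Control probe counts.
#' @param n_missing Number of endogenous genes absent from the sequencing
#'   annotation (`<= n_endogenous`).
#' @param seed Integer seed.
#' @return An object of class `panel_definition`: a list with `genes` (a
#'   data.frame of `gene_id`, `class` in endogenous/housekeeping/positive/
#'   negative) and `missing_from_annotation` (character).
#' @export
build_panel <- function(truth, n_endogenous = 780, n_housekeeping = 20,
                        n_pos_controls = 6, n_neg_controls = 8,
                        n_missing = 9, seed = 1L) {
  stopifnot(inherits(truth, "true_expression"))
  n_genes <- length(truth$gene_ids)
  if (n_endogenous + n_housekeeping > n_genes) {
    stop("panel larger than the gene universe")
  }
  if (n_missing > n_endogenous) stop("`n_missing` must be <= `n_endogenous`")
  if (n_endogenous < 1 || n_housekeeping < 0) stop("invalid panel sizes")

  set.seed(child_seed(seed, 3L))
  endo <- sample(truth$gene_ids, n_endogenous)
  hk_pool <- setdiff(truth$gene_ids[!truth$is_de], endo)
  if (length(hk_pool) < n_housekeeping) {
    stop("not enough non-DE genes outside the endogenous set for housekeeping")
  }
  hk <- sample(hk_pool, n_housekeeping)
  pos <- if (n_pos_controls > 0) sprintf("POS_%s", LETTERS[seq_len(n_pos_controls)]) else character()
  neg <- if (n_neg_controls > 0) sprintf("NEG_%s", LETTERS[seq_len(n_neg_controls)]) else character()
  missing <- if (n_missing > 0) sort(sample(endo, n_missing)) else character()

  genes <- data.frame(
    gene_id = c(endo, hk, pos, neg),
    class = rep(
      c("endogenous", "housekeeping", "positive", "negative"),
      c(n_endogenous, n_housekeeping, length(pos), length(neg))
    ),
    stringsAsFactors = FALSE
  )
  structure(
    list(genes = genes, missing_from_annotation = missing),
    class = "panel_definition"
  )
}

#' Panel gene IDs by class
#' @param panel A `panel_definition`.
#' @param classes Classes to include.
#' @return Character vector of gene IDs.
#' @export
panel_genes <- function(panel, classes = c("endogenous", "housekeeping")) {
  stopifnot(inherits(panel, "panel_definition"))
  panel$genes$gene_id[panel$genes$class %in% classes]
}

#' Simulation configuration for one paired-platform study
#'
#' Defaults emulate the entity-contrasting tumor design: 10 vs 11 samples,
#' 20,000 annotated genes, 10% truly DE genes with log2FC sd 1.5, a panel of
#' 780 endogenous plus 20 housekeeping genes with 6 positive and 8 negative
#' control probes, and 9 panel genes (~1%) missing from the sequencing
#' annotation. The sequencing platform is deeper and noisier per gene; the
#' panel is shallower with tighter dispersion, mirroring digital counting.
#'
#' @param n_genes,n_per_group,de_fraction,lfc_sd,baseline_mean_log2,baseline_sd_log2
#'   Passed to [simulate_truth()].
#' @param seq_params,panel_params `platform_params` for the two platforms.
#' @param n_endogenous,n_housekeeping,n_pos_controls,n_neg_controls,n_missing
#'   Passed to [build_panel()].
#' @param bio_log2_sd Shared biological sample-to-sample variation (log2 sd):
#'   latent per-gene-per-sample deviations measured by BOTH platforms, on top
#'   of the group effect. This is what gene-wise correlations recover.
#' @param pos_control_means Fixed positive-control probe means spanning four
#'   orders of magnitude (scaled by each sample's depth).
#' @param neg_control_mean Negative-control (background) Poisson mean.
#' @param panel_background_mean Poisson background added to every panel probe
#'   (hybridization background, the floor the negative controls measure).
#' @param seed Master seed; all component seeds derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000, n_per_group = c(10, 11),
                       de_fraction = 0.1, lfc_sd = 1.5,
                       baseline_mean_log2 = 4, baseline_sd_log2 = 2,
                       seq_params = platform_params(
                         dispersion = 0.15, library_size_log2_sd = 0.3,
                         capture_log2_sd = 0.5, noise_log2_sd = 0.15,
                         depth_log2_offset = 4
                       ),
                       panel_params = platform_params(
                         dispersion = 0.05, library_size_log2_sd = 0.25,
                         capture_log2_sd = 0.5, noise_log2_sd = 0.1,
                         depth_log2_offset = 2
                       ),
                       n_endogenous = 780, n_housekeeping = 20,
                       n_pos_controls = 6, n_neg_controls = 8, n_missing = 9,
                       bio_log2_sd = 0.7,
                       pos_control_means = 10^seq(5, 1, length.out = n_pos_controls),
                       neg_control_mean = 2,
                       panel_background_mean = neg_control_mean,
                       seed = 1L) {
  stopifnot(inherits(seq_params, "platform_params"),
            inherits(panel_params, "platform_params"))
  cfg <- list(
    n_genes = n_genes, n_per_group = n_per_group, de_fraction = de_fraction,
    lfc_sd = lfc_sd, baseline_mean_log2 = baseline_mean_log2,
    baseline_sd_log2 = baseline_sd_log2, seq_params = seq_params,
    panel_params = panel_params, n_endogenous = n_endogenous,
    n_housekeeping = n_housekeeping, n_pos_controls = n_pos_controls,
    n_neg_controls = n_neg_controls, n_missing = n_missing,
    bio_log2_sd = bio_log2_sd,
    pos_control_means = pos_control_means, neg_control_mean = neg_control_mean,
    panel_background_mean = panel_background_mean,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate one complete paired-platform study
#'
#' One shared truth, two platform draws with independent platform noise. The
#' sequencing matrix covers the annotated genes and therefore EXCLUDES the
#' panel genes missing from the annotation; the panel matrix contains all
#' panel genes (including the missing ones) plus control probes, since the
#' panel measures its probes regardless of the sequencing annotation.
#' Positive-control probe counts scale with the panel draw's per-sample depth;
#' negative controls are background Poisson counts. Sample metadata carries
#' simulated RQN and DV200 quality values drawn in the passing range.
#'
#' @param config A `sim_config`.
#' @return An object of class `paired_study`: list with `seq_counts`,
#'   `panel_counts` (both `count_matrix` with identical samples in identical
#'   order), `panel` (`panel_definition`), `truth`, `seed` and `config`.
#' @export
simulate_paired_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  truth <- simulate_truth(
    config$n_genes, config$n_per_group, config$de_fraction, config$lfc_sd,
    config$baseline_mean_log2, config$baseline_sd_log2,
    seed = child_seed(seed, 11L)
  )
  panel <- build_panel(
    truth, config$n_endogenous, config$n_housekeeping,
    config$n_pos_controls, config$n_neg_controls, config$n_missing,
    seed = child_seed(seed, 12L)
  )

  # shared biological sample-to-sample variation, seen by both platforms
  set.seed(child_seed(seed, 16L))
  samples <- names(truth$group_of_sample)
  latent <- matrix(
    stats::rnorm(length(truth$gene_ids) * length(samples), 0, config$bio_log2_sd),
    length(truth$gene_ids), length(samples),
    dimnames = list(truth$gene_ids, samples)
  )

  seq_cm <- simulate_platform(truth, config$seq_params,
    seed = child_seed(seed, 13L), platform = "sequencing",
    latent_log2 = latent
  )
  if (length(panel$missing_from_annotation)) {
    keep <- setdiff(gene_ids(seq_cm), panel$missing_from_annotation)
    depth <- attr(seq_cm, "depth_log2")
    seq_cm <- count_matrix(seq_cm$counts[keep, , drop = FALSE],
      platform = seq_cm$platform, sample_meta = seq_cm$sample_meta
    )
    attr(seq_cm, "depth_log2") <- depth
  }

  pp <- config$panel_params
  pp$panel_subset <- panel_genes(panel, c("endogenous", "housekeeping"))
  panel_cm <- simulate_platform(truth, pp,
    seed = child_seed(seed, 14L), platform = "panel",
    latent_log2 = latent
  )
  depth <- attr(panel_cm, "depth_log2")

  set.seed(child_seed(seed, 15L))
  n_s <- ncol(panel_cm$counts)
  if (config$panel_background_mean > 0) {
    # hybridization background: the count floor the negative controls measure
    bg <- matrix(
      stats::rpois(length(panel_cm$counts), config$panel_background_mean),
      nrow(panel_cm$counts), n_s
    )
    panel_cm$counts <- panel_cm$counts + bg
  }
  pos_ids <- panel_genes(panel, "positive")
  neg_ids <- panel_genes(panel, "negative")
  pos <- matrix(0, length(pos_ids), n_s, dimnames = list(pos_ids, colnames(panel_cm$counts)))
  for (i in seq_along(pos_ids)) {
    pos[i, ] <- stats::rpois(n_s, config$pos_control_means[i] * 2^depth)
  }
  neg <- matrix(
    stats::rpois(length(neg_ids) * n_s, config$neg_control_mean),
    length(neg_ids), n_s, dimnames = list(neg_ids, colnames(panel_cm$counts))
  )
  panel_counts <- rbind(panel_cm$counts, pos, neg)

  # shared per-sample RNA-quality fields, within the QC-passing range
  meta <- panel_cm$sample_meta
  meta$rqn <- round(stats::runif(n_s, 5, 9), 1)
  meta$dv200 <- round(stats::runif(n_s, 66, 92), 1)
  seq_cm$sample_meta <- meta
  panel_out <- count_matrix(panel_counts, platform = "panel", sample_meta = meta)

  structure(
    list(
      seq_counts = seq_cm, panel_counts = panel_out,
      panel = panel, truth = truth, seed = seed, config = config
    ),
    class = "paired_study"
  )
}

#' @export
print.paired_study <- function(x, ...) {
  cat("paired_study (seed ", x$seed, ")\n  sequencing: ",
    nrow(x$seq_counts$counts), " genes\n  panel: ",
    nrow(x$panel_counts$counts), " probes (",
    length(x$panel$missing_from_annotation), " missing from annotation)\n  ",
    ncol(x$seq_counts$counts), " samples (",
    paste(x$truth$n_per_group, collapse = " vs "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Write a paired study to plain-text files
#'
#' Emits two TSV count matrices, the panel definition table (with a
#' `missing_from_annotation` flag column) and the per-gene truth table.
#'
#' @param study A `paired_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_paired_study <- function(study, dir) {
  stopifnot(inherits(study, "paired_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    seq = file.path(dir, "seq_counts.tsv"),
    panel = file.path(dir, "panel_counts.tsv"),
    panel_def = file.path(dir, "panel_definition.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(study$seq_counts, paths[["seq"]])
  write_counts(study$panel_counts, paths[["panel"]])
  pd <- study$panel$genes
  pd$missing_from_annotation <- pd$gene_id %in% study$panel$missing_from_annotation
  utils::write.table(pd, paths[["panel_def"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  tr <- data.frame(
    gene_id = study$truth$gene_ids,
    baseline_log2 = unname(study$truth$baseline_log2),
    lfc_true = unname(study$truth$lfc_true),
    is_de = unname(study$truth$is_de),
    stringsAsFactors = FALSE
  )
  utils::write.table(tr, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
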