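# Shared fixtures: tiny deterministic matrices and a small paired-study
# configuration that keeps the full pipeline fast.

tiny_counts <- function(mat, platform = "test", groups = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  meta <- NULL
  if (!is.null(groups)) {
    meta <- data.frame(sample_id = colnames(mat), group = groups,
      stringsAsFactors = FALSE)
  }
  count_matrix(mat, platform = platform, sample_meta = meta)
}

random_counts <- function(n_genes, n_samples, seed, mu_range = c(5, 500)) {
  set.seed(seed)
  mu <- exp(runif(n_genes, log(mu_range[1]), log(mu_range[2])))
  mat <- matrix(
    rnbinom(n_genes * n_samples, mu = rep(mu, n_samples), size = 10),
    n_genes, n_samples
  )
  tiny_counts(mat)
}

small_study_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_genes = 1500, n_per_group = c(6, 6), de_fraction = 0.1, lfc_sd = 1.5,
      n_endogenous = 120, n_housekeeping = 10, n_missing = 2, seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# A constructed dge_result with chosen lfc / padj values; se defaults keep
# shrinkage well-defined.
make_dge <- function(gene_id, lfc, padj, se = 0.3) {
  res <- data.frame(
    gene_id = gene_id,
    base_mean = 100,
    lfc_raw = lfc,
    lfc_shrunk = lfc,
    se = se,
    stat = lfc / se,
    p = padj,
    padj_bh = padj,
    padj_by = padj,
    dispersion = 0.1,
    stringsAsFactors = FALSE
  )
  class(res) <- c("dge_result", "data.frame")
  res
}
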