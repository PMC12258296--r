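test_that("simulate_truth honours the DE fraction and determinism contract", {
  t0 <- simulate_truth(1000, c(5, 5), de_fraction = 0, lfc_sd = 1, seed = 11)
  expect_true(all(t0$lfc_true == 0))
  expect_false(any(t0$is_de))

  t1 <- simulate_truth(1000, c(5, 5), de_fraction = 0.1, lfc_sd = 1, seed = 11)
  expect_identical(sum(t1$is_de), 100L)
  expect_true(all(t1$lfc_true[!t1$is_de] == 0))
  expect_true(all(t1$lfc_true[t1$is_de] != 0))

  t2 <- simulate_truth(1000, c(5, 5), de_fraction = 0.1, lfc_sd = 1, seed = 11)
  expect_identical(t1, t2)

  expect_error(simulate_truth(100, c(1, 5), 0.1, 1, seed = 1), "group sizes")
  expect_error(simulate_truth(100, c(5, 5), 1.5, 1, seed = 1), "de_fraction")
  expect_error(simulate_truth(100, c(5, 5), NA, 1, seed = 1), "finite")
})

test_that("simulate_platform reproduces NB moments and respects subsets", {
  # fixed mu = 100, phi = 0.1: mean 100, variance 100 + 0.1 * 100^2 = 1100,
  # checked against direct replicate sampling within 3 Monte-Carlo SEs
  truth <- simulate_truth(1, c(5000, 5000), 0, 1, seed = 1)
  truth$baseline_log2[] <- log2(100)
  pp <- platform_params(
    dispersion = 0.1, library_size_log2_sd = 0,
    capture_log2_sd = 0, noise_log2_sd = 0
  )
  cm <- simulate_platform(truth, pp, seed = 5)
  x <- as.numeric(cm$counts)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 100), 3 * se_mean)
  dev2 <- (x - mean(x))^2
  se_var <- sd(dev2) / sqrt(length(x))
  expect_lt(abs(var(x) - 1100), 3 * se_var)

  # determinism and subset restriction
  truth2 <- simulate_truth(50, c(3, 3), 0.2, 1, seed = 2)
  a <- simulate_platform(truth2, platform_params(), seed = 9)
  b <- simulate_platform(truth2, platform_params(), seed = 9)
  expect_identical(a$counts, b$counts)
  subset <- truth2$gene_ids[c(10, 3, 27)]
  pp2 <- platform_params(panel_subset = subset)
  cm2 <- simulate_platform(truth2, pp2, seed = 9)
  expect_identical(rownames(cm2$counts), subset)
  expect_true(all(cm2$counts >= 0))
  expect_true(all(cm2$counts == round(cm2$counts)))
})

test_that("build_panel draws housekeepers from non-DE genes and controls off-truth", {
  truth <- simulate_truth(500, c(5, 5), 0.3, 1.5, seed = 4)
  panel <- build_panel(truth,
    n_endogenous = 100, n_housekeeping = 15,
    n_pos_controls = 6, n_neg_controls = 8, n_missing = 5, seed = 4
  )
  hk <- panel_genes(panel, "housekeeping")
  expect_length(hk, 15)
  expect_false(any(truth$is_de[hk]))
  ctrl <- panel_genes(panel, c("positive", "negative"))
  expect_length(intersect(ctrl, truth$gene_ids), 0)
  expect_true(all(panel$missing_from_annotation %in% panel_genes(panel, "endogenous")))
  expect_length(panel$missing_from_annotation, 5)

  p0 <- build_panel(truth, 100, 15, 6, 8, n_missing = 0, seed = 4)
  expect_length(p0$missing_from_annotation, 0)
  ov <- annotation_overlap(panel_genes(p0), truth$gene_ids)
  expect_equal(ov$pct_found, 100)

  expect_error(build_panel(truth, 600, 15, 6, 8, 0, seed = 1), "larger")
  expect_error(build_panel(truth, 100, 15, 6, 8, 200, seed = 1), "n_missing")
})

test_that("simulate_paired_study shares samples and excludes missing genes from annotation", {
  cfg <- small_study_config(seed = 21)
  s1 <- simulate_paired_study(cfg)
  s2 <- simulate_paired_study(cfg)
  expect_identical(s1$seq_counts$counts, s2$seq_counts$counts)
  expect_identical(s1$panel_counts$counts, s2$panel_counts$counts)

  expect_identical(sample_ids(s1$seq_counts), sample_ids(s1$panel_counts))
  expect_false(any(is.na(s1$seq_counts$counts)))
  expect_false(any(is.na(s1$panel_counts$counts)))

  # missing genes are on the panel but absent from the sequencing annotation
  miss <- s1$panel$missing_from_annotation
  expect_length(miss, 2)
  expect_true(all(miss %in% gene_ids(s1$panel_counts)))
  expect_length(intersect(miss, gene_ids(s1$seq_counts)), 0)
  expect_identical(
    sort(gene_ids(s1$panel_counts)),
    sort(panel_genes(s1$panel, c("endogenous", "housekeeping", "positive", "negative")))
  )
})

test_that("shared-signal limit gives correlations near 1; more noise lowers gene-wise r", {
  quiet <- function(noise_sd, seed) {
    sim_config(
      n_genes = 400, n_per_group = c(5, 5), de_fraction = 0.1, lfc_sd = 1.5,
      baseline_mean_log2 = 8, baseline_sd_log2 = 1.5,
      seq_params = platform_params(
        dispersion = 1e-8, library_size_log2_sd = 0, capture_log2_sd = 0,
        noise_log2_sd = noise_sd, depth_log2_offset = 6
      ),
      panel_params = platform_params(
        dispersion = 1e-8, library_size_log2_sd = 0, capture_log2_sd = 0,
        noise_log2_sd = noise_sd, depth_log2_offset = 6
      ),
      n_endogenous = 100, n_housekeeping = 10, n_missing = 0,
      bio_log2_sd = 0.7, panel_background_mean = 0, seed = seed
    )
  }
  median_gene_r <- function(noise_sd, seed) {
    s <- simulate_paired_study(quiet(noise_sd, seed))
    cs <- correlation_profile(s$panel_counts, s$seq_counts, "gene", "spearman")
    median(cs$r, na.rm = TRUE)
  }
  # noise-free shared-signal limit
  expect_gt(median_gene_r(0, 31), 0.99)
  # median gene-wise correlation strictly decreasing in platform noise
  rs <- vapply(c(0, 0.5, 1.0), median_gene_r, numeric(1), seed = 31)
  expect_true(all(diff(rs) < 0))
})

test_that("paired studies round-trip through their TSV files", {
  s <- simulate_paired_study(small_study_config(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_paired_study(s, dir)
  back <- read_counts(paths[["seq"]], platform = "sequencing")
  expect_identical(back$counts, s$seq_counts$counts)
  pd <- read.delim(paths[["panel_def"]])
  expect_identical(
    sort(pd$gene_id[pd$missing_from_annotation]),
    s$panel$missing_from_annotation
  )
})
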