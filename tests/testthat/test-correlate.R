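# Direct product-moment evaluation, independent of stats::cor, used as the
# oracle for the coefficient primitives.
brute_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

test_that("pearson_log matches direct evaluation on log2(x + pseudocount)", {
  # exactly affine after the transform
  expect_equal(pearson_log(c(0, 1, 3, 7), c(1, 3, 7, 15)), 1.0)
  expect_equal(pearson_log(c(2, 9, 40, 7), c(2, 9, 40, 7)), 1.0)

  x <- c(0, 1, 3, 7)
  y <- c(0, 2, 6, 14)
  expect_equal(
    pearson_log(x, y),
    brute_pearson(log2(x + 1), log2(y + 1))
  )
  x2 <- c(3, 0, 250, 17, 88)
  y2 <- c(5, 2, 90, 30, 41)
  expect_equal(pearson_log(x2, y2), brute_pearson(log2(x2 + 1), log2(y2 + 1)))

  # pseudocount 0 on all-positive data reduces to Pearson of log counts
  expect_equal(
    pearson_log(x2 + 1, y2 + 1, pseudocount = 0),
    brute_pearson(log2(x2 + 1), log2(y2 + 1))
  )

  expect_true(is.na(pearson_log(c(4, 4, 4), c(1, 2, 3))))
  expect_error(pearson_log(1:4, 1:5), "equal length")
  expect_error(pearson_log(c(-1, 2, 3), c(1, 2, 3)), "nonnegative")
})

test_that("spearman_cor uses mid-ranks and handles monotone transforms", {
  x <- c(1, 2, 2, 3)
  y <- c(10, 20, 30, 40)
  expect_equal(spearman_cor(x, y), brute_pearson(c(1, 2.5, 2.5, 4), 1:4))
  expect_equal(spearman_cor(x, y), 0.9486833, tolerance = 1e-7)

  z <- c(3, 17, 44, 180, 201)
  expect_equal(spearman_cor(z, log1p(z)), 1.0)
  expect_equal(spearman_cor(z, rev(sort(z))), -1.0)
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))))
})

test_that("correlation_profile: identity, axes, and undefined handling", {
  cm <- random_counts(40, 6, seed = 9)
  cs <- correlation_profile(cm, cm, "sample", "pearson_log")
  expect_equal(unname(cs$r), rep(1, 6))
  cg <- correlation_profile(cm, cm, "gene", "spearman")
  expect_equal(length(cg$r), 40)
  expect_true(all(abs(cg$r - 1) < 1e-12, na.rm = TRUE))

  # a constant gene on one side yields an undefined entry, counted not imputed
  m2 <- cm$counts
  m2[3, ] <- 7
  cm2 <- tiny_counts(m2)
  cg2 <- correlation_profile(cm, cm2, "gene", "pearson")
  expect_true(is.na(cg2$r[[3]]))
  expect_equal(cg2$n_undefined, sum(is.na(cg2$r)))

  expect_error(
    correlation_profile(
      tiny_counts(matrix(1:4, 2, 2)), tiny_counts(matrix(1:4, 2, 2)), "sample"
    ),
    "fewer than 3"
  )
})

test_that("sample-wise Spearman is exactly invariant under the four normalizations", {
  s <- simulate_paired_study(small_study_config(seed = 77))
  panel_norm <- panel_two_step_normalize(s$panel_counts, s$panel)
  shared <- intersect(
    panel_genes(s$panel, c("endogenous", "housekeeping")),
    gene_ids(s$seq_counts)
  )
  p <- subset_genes(panel_norm, shared)
  rs <- lapply(c("none", "cpm", "tmm", "rle"), function(m) {
    q <- subset_genes(normalize_counts(s$seq_counts, m), shared)
    correlation_profile(p, q, "sample", "spearman")$r
  })
  for (i in 2:4) expect_identical(rs[[1]], rs[[i]])
})

test_that("strength bins follow the medical-field convention", {
  expect_identical(classify_strength(0.87), "very strong")
  expect_identical(classify_strength(0.80), "very strong") # boundary inclusive
  expect_identical(classify_strength(0.45), "fair")
  expect_identical(
    classify_strength(c(0.79, 0.6, 0.3, 0.29, -0.85, NA)),
    c("moderately strong", "moderately strong", "fair", "poor", "very strong", NA)
  )
  expect_error(classify_strength(1.2), "\\[-1, 1\\]")
})

test_that("box summaries flag outliers beyond 1.5 IQR with interpolated quartiles", {
  b <- summarize_box(c(1, 2, 3))
  expect_equal(b$median, 2)
  expect_length(b$outliers, 0)
  expect_equal(summarize_box(0.4)$median, 0.4)

  # hand evaluation with type-7 quartiles: q1 = 2, q3 = 4, fence = 4 + 1.5*2 = 7
  b2 <- summarize_box(c(1, 2, 3, 4, 100))
  expect_equal(b2$q1, 2)
  expect_equal(b2$q3, 4)
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 4)

  b3 <- summarize_box(c(0.2, NA, 0.4, 0.9))
  expect_equal(b3$n, 3)
  expect_equal(b3$n_undefined, 1)
  expect_error(summarize_box(c(NA_real_, NA_real_)), "no defined")
})

test_that("strata are nested and obey the tie rule", {
  ids <- sprintf("g%03d", 1:20)
  cs <- structure(
    list(
      axis = "gene", coefficient = "pearson", normalization = c(a = "x", b = "y"),
      ids = ids, r = seq(0.1, 0.9, length.out = 20), n_undefined = 0,
      pseudocount = NA_real_
    ),
    class = "correlation_set"
  )
  names(cs$r) <- ids
  me <- setNames(seq_len(20), ids) # distinct uniform mean expression
  st <- strata_correlations(cs, me)
  expect_length(st$top50$genes, 10) # ceiling(20/2)
  expect_true(all(st$top50$genes %in% st$top90$genes))
  expect_true(all(st$top90$genes %in% st$all$genes))

  st21 <- strata_correlations(
    within_cs <- local({
      cs2 <- cs
      cs2$ids <- c(ids, "g021")
      cs2$r <- setNames(c(unname(cs$r), 0.5), cs2$ids)
      cs2
    }),
    setNames(1:21, c(ids, "g021"))
  )
  expect_length(st21$top50$genes, 11) # ceiling(21/2)
})

test_that("stratified medians increase with expression under NB noise", {
  # constant dispersion makes low-count genes relatively noisier, so the
  # correlation of lowly expressed genes is weakest
  cfg <- small_study_config(
    seed = 5,
    baseline_mean_log2 = 3, baseline_sd_log2 = 2.5
  )
  s <- simulate_paired_study(cfg)
  shared <- intersect(
    panel_genes(s$panel, c("endogenous", "housekeeping")),
    gene_ids(s$seq_counts)
  )
  p <- subset_genes(panel_two_step_normalize(s$panel_counts, s$panel), shared)
  q <- subset_genes(normalize_counts(s$seq_counts, "tmm"), shared)
  cg <- correlation_profile(p, q, "gene", "pearson")
  me <- rowMeans(log2(values(p) + 1))
  st <- strata_correlations(cg, me)
  meds <- c(st$all$box$median, st$top90$box$median, st$top50$box$median)
  expect_true(all(diff(meds) >= 0))
})
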