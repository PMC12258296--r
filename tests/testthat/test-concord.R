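test_that("annotation overlap accounting and percentage formatting", {
  panel <- sprintf("P%03d", 1:830)
  annot <- c(sprintf("P%03d", 1:821), sprintf("X%03d", 1:50))
  ov <- annotation_overlap(panel, annot)
  expect_equal(ov$n_found, 821)
  expect_equal(ov$n_missing, 9)
  expect_identical(format_percent(ov$pct_found), "98.9")
  expect_identical(format_percent(100 * ov$n_missing / ov$n_panel), "1.1")
  expect_identical(ov$missing_ids, sort(sprintf("P%03d", 822:830)))

  ov2 <- annotation_overlap(sprintf("P%03d", 1:800), sprintf("P%03d", 1:790))
  expect_identical(format_percent(ov2$pct_found), "98.75")

  ov3 <- annotation_overlap(c("a", "b"), c("a", "b", "c"))
  expect_equal(ov3$pct_found, 100)
  expect_length(ov3$missing_ids, 0)

  expect_error(annotation_overlap(character(), "a"), "empty panel")
  expect_error(annotation_overlap(c("a", "a"), "a"), "duplicate")
})

test_that("jaccard index: arithmetic, symmetry, and conventions", {
  a <- sprintf("A%03d", 1:182)
  b <- c(a[1:120], sprintf("B%03d", 1:50))
  expect_equal(jaccard_index(a, b), 120 / 232)
  expect_equal(round(jaccard_index(a, b), 2), 0.52)
  expect_equal(jaccard_index(b, a), jaccard_index(a, b))
  expect_equal(jaccard_index(character(), sprintf("C%02d", 1:89)), 0)
  expect_equal(jaccard_index(character(), character()), 0)
  expect_equal(jaccard_index(a, a), 1)
})

test_that("direction classification covers the Fig-4-style contingencies", {
  da <- make_dge(
    c("g1", "g2", "g3", "g4", "g5"),
    lfc = c(-1.5, 1.4, 0.2, 1.2, -1.1),
    padj = c(0.01, 0.02, 0.9, 0.01, 0.03)
  )
  db <- make_dge(
    c("g1", "g2", "g3", "g4", "g5"),
    lfc = c(-2.0, 0.3, -0.4, -1.6, -1.4),
    padj = c(0.001, 0.40, 0.7, 0.04, 0.01)
  )
  cl <- classify_directions(da, db)
  expect_identical(unname(cl$labels[c("g1", "g2", "g3", "g4", "g5")]),
    c("both_down", "a_only_up", "not_significant", "opposite", "both_down"))
  expect_equal(sum(cl$tally), 5)
  expect_equal(unname(cl$tally["opposite"]), 1)

  # platform-role swap maps a_only_* <-> b_only_*
  cl_sw <- classify_directions(db, da)
  expect_equal(unname(cl_sw$tally["b_only_up"]), unname(cl$tally["a_only_up"]))
})

test_that("direction tallies partition and reconcile with call_degs", {
  s <- simulate_paired_study(small_study_config(seed = 14))
  dge_b <- shrink_lfc(nb_wald_dge(s$seq_counts))
  pn <- panel_two_step_normalize(s$panel_counts, s$panel)
  dge_a <- shrink_lfc(nb_wald_dge(s$panel_counts,
    size_factors = 1 / pn$factors_used$factors))
  shared <- intersect(dge_a$gene_id[!is.na(dge_a$lfc_shrunk)],
    dge_b$gene_id[!is.na(dge_b$lfc_shrunk)])
  cl <- classify_directions(dge_a, dge_b)
  expect_equal(sum(cl$tally), length(shared))
  expect_setequal(names(cl$labels), shared)

  th <- dge_thresholds()
  deg_a <- call_degs(dge_a, th)$gene_id
  deg_b <- call_degs(dge_b, th)$gene_id
  sig_a_lab <- sum(cl$tally[c("both_down", "both_up", "opposite",
    "a_only_down", "a_only_up")])
  expect_equal(sig_a_lab, length(intersect(deg_a, shared)))
})

test_that("lfc concordance degenerate and oracle cases", {
  d <- make_dge(sprintf("g%d", 1:6),
    lfc = c(-2.1, -0.4, 0.1, 0.9, 1.7, 3.0), padj = 0.5)
  same <- lfc_concordance(d, d)
  expect_equal(same$pearson, 1)
  expect_equal(same$spearman, 1)

  neg <- d
  neg$lfc_raw <- -neg$lfc_raw
  opp <- lfc_concordance(d, neg)
  expect_equal(opp$pearson, -1)
  expect_equal(opp$spearman, -1)

  d2 <- make_dge(sprintf("g%d", 1:6),
    lfc = c(-1.8, -0.1, 0.3, 0.4, 2.2, 2.4), padj = 0.5)
  got <- lfc_concordance(d, d2)
  px <- d$lfc_raw - mean(d$lfc_raw)
  py <- d2$lfc_raw - mean(d2$lfc_raw)
  expect_equal(got$pearson, sum(px * py) / sqrt(sum(px^2) * sum(py^2)))
  expect_equal(got$spearman, cor(rank(d$lfc_raw), rank(d2$lfc_raw)))

  expect_error(lfc_concordance(make_dge("g1", 1, 0.5), make_dge("g1", 1, 0.5)),
    "fewer than 3")
})

test_that("build_report assembles a consistent record", {
  # strong shared DE signal: 10 vs 10 samples, 15% DE genes with sd-2 effects
  s <- simulate_paired_study(small_study_config(
    seed = 23,
    n_per_group = c(10, 10), de_fraction = 0.15, lfc_sd = 2
  ))
  dge_b <- shrink_lfc(nb_wald_dge(s$seq_counts))
  pn <- panel_two_step_normalize(s$panel_counts, s$panel)
  dge_a <- shrink_lfc(nb_wald_dge(s$panel_counts,
    size_factors = 1 / pn$factors_used$factors))
  rep <- build_report(dge_a, dge_b, s$panel, gene_ids(s$seq_counts))

  # Venn identities against the DEG sets
  expect_equal(rep$venn[["a_only"]] + rep$venn[["both"]], rep$n_deg_a)
  expect_equal(rep$venn[["b_only"]] + rep$venn[["both"]], rep$n_deg_b)
  expect_equal(
    rep$jaccard,
    rep$venn[["both"]] / sum(rep$venn)
  )
  expect_true(rep$jaccard >= 0 && rep$jaccard <= 1)
  expect_equal(rep$overlap$n_found + rep$overlap$n_missing, rep$overlap$n_panel)

  # strong shared DE signal beats a pure-noise study
  noise_cfg <- small_study_config(
    seed = 23,
    n_per_group = c(10, 10), de_fraction = 0, lfc_sd = 2
  )
  s0 <- simulate_paired_study(noise_cfg)
  d0b <- shrink_lfc(nb_wald_dge(s0$seq_counts))
  pn0 <- panel_two_step_normalize(s0$panel_counts, s0$panel)
  d0a <- shrink_lfc(nb_wald_dge(s0$panel_counts,
    size_factors = 1 / pn0$factors_used$factors))
  rep0 <- build_report(d0a, d0b, s0$panel, gene_ids(s0$seq_counts))
  expect_gt(rep$jaccard, rep0$jaccard)

  # identical results on both sides: jaccard 1, every DEG in a both_* class
  rep_id <- build_report(dge_a, dge_a, s$panel, gene_ids(s$panel_counts))
  expect_equal(rep_id$jaccard, 1)
  expect_equal(sum(rep_id$classes$tally[c("a_only_down", "a_only_up",
    "b_only_down", "b_only_up", "opposite")]), 0)

  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$jaccard, rep$jaccard)
  expect_equal(js$venn$both, unname(rep$venn[["both"]]))
})
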