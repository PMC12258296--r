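# Readers/writers, RNA-quality gates, JSON configuration, and the end-to-end
# pipeline driver.

#' RNA-quality gate for FFPE samples
#'
#' Keeps a sample iff RQN > 4 AND DV200 > 64.5% (strict inequalities), and
#' assigns the DV200 quality class: > 70 high, 50-70 medium (both boundaries
#' medium), < 50 low. Samples failing the gate are labelled, not removed.
#'
#' @param records data.frame with columns `sample_id`, `rqn`, `dv200`.
#' @param rqn_min,dv200_min Exclusive gate thresholds (defaults 4 and 64.5).
#' @return The input with added logical `keep` and character `dv200_class`.
#' @export
sample_qc <- function(records, rqn_min = 4, dv200_min = 64.5) {
  need <- c("sample_id", "rqn", "dv200")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- records$sample_id[!is.finite(records$rqn) | !is.finite(records$dv200)]
  if (length(bad)) {
    stop("non-numeric QC fields for sample(s): ", paste(bad, collapse = ", "))
  }
  if (any(records$dv200 < 0 | records$dv200 > 100)) {
    stop("dv200 must lie in [0, 100]")
  }
  records$keep <- records$rqn > rqn_min & records$dv200 > dv200_min
  records$dv200_class <- ifelse(records$dv200 > 70, "high",
    ifelse(records$dv200 >= 50, "medium", "low")
  )
  records
}

#' Read / write a TSV count matrix
#'
#' The canonical interchange format: tab-separated, gene IDs in the first
#' column (`gene_id`), sample IDs in the header. Readers reject rather than
#' coerce: duplicate IDs, negative, fractional or missing counts are errors
#' with row/column context.
#'
#' @param path File path.
#' @param platform Platform tag for the resulting object.
#' @param sample_meta Optional metadata data.frame passed through.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, platform = "generic", sample_meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed count file (need gene_id + >= 1 sample): ", path)
  gene <- as.character(df[[1]])
  dup <- unique(gene[duplicated(gene)])
  if (length(dup)) stop("duplicate gene ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric count column(s) in ", path, ": ", paste(badcol, collapse = ", "))
  }
  rownames(m) <- gene
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(
      "invalid count in ", path, " at gene '", gene[bad[1, 1]], "', sample '",
      colnames(m)[bad[1, 2]], "': ", m[bad[1, , drop = FALSE]]
    )
  }
  count_matrix(m, platform = platform, sample_meta = sample_meta)
}

#' @rdname read_counts
#' @param x A `count_matrix` to write.
#' @return `write_counts` returns `path` invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

rcc_sections <- c("Header", "Sample_Attributes", "Lane_Attributes", "Code_Summary")

#' Read a reporter-code-count (RCC) panel export
#'
#' Parses the line-oriented RCC dialect: sections delimited by
#' `<Name>`...`</Name>` with CSV content; the `Code_Summary` section holds
#' `CodeClass,Name,Accession,Count` rows. Code classes map onto panel classes
#' (Endogenous, Housekeeping, Positive, Negative).
#'
#' @param path RCC file path.
#' @return List with `sample_id`, `counts` (named integer vector), `classes`
#'   (data.frame `gene_id`, `class`), and `attributes` (header/sample/lane
#'   key-value lists).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sections <- list()
  current <- NULL
  buf <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^<[A-Za-z_]+>$", ln)) {
      current <- sub("^<([A-Za-z_]+)>$", "\\1", ln)
      buf <- character()
    } else if (grepl("^</[A-Za-z_]+>$", ln)) {
      closing <- sub("^</([A-Za-z_]+)>$", "\\1", ln)
      if (is.null(current) || closing != current) {
        stop("mismatched section tag </", closing, "> in ", path)
      }
      sections[[current]] <- buf
      current <- NULL
    } else if (!is.null(current) && nzchar(ln)) {
      buf <- c(buf, ln)
    }
  }
  if (!is.null(current)) {
    stop("truncated RCC file: section <", current, "> never closed in ", path)
  }
  if (is.null(sections[["Code_Summary"]])) {
    stop("missing Code_Summary section in ", path)
  }

  kv <- function(sec) {
    if (is.null(sections[[sec]])) {
      return(list())
    }
    parts <- strsplit(sections[[sec]], ",")
    stats::setNames(
      lapply(parts, function(p) paste(p[-1], collapse = ",")),
      vapply(parts, `[`, character(1), 1)
    )
  }
  cs <- utils::read.csv(
    text = paste(sections[["Code_Summary"]], collapse = "\n"),
    stringsAsFactors = FALSE
  )
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% names(cs))) {
    stop("Code_Summary must have columns ", paste(need, collapse = ","), " in ", path)
  }
  if (anyNA(suppressWarnings(as.numeric(cs$Count))) ||
    any(as.numeric(cs$Count) != round(as.numeric(cs$Count)))) {
    stop("non-integer Count in Code_Summary of ", path)
  }
  class_map <- c(
    Endogenous = "endogenous", Housekeeping = "housekeeping",
    Positive = "positive", Negative = "negative"
  )
  cls <- class_map[cs$CodeClass]
  if (anyNA(cls)) {
    stop("unknown CodeClass in ", path, ": ",
      paste(unique(cs$CodeClass[is.na(cls)]), collapse = ", "))
  }
  attrs <- list(
    header = kv("Header"),
    sample = kv("Sample_Attributes"),
    lane = kv("Lane_Attributes")
  )
  sample_id <- attrs$sample[["ID"]] %||% basename(path)
  list(
    sample_id = sample_id,
    counts = stats::setNames(as.integer(cs$Count), cs$Name),
    classes = data.frame(gene_id = cs$Name, class = unname(cls),
      stringsAsFactors = FALSE),
    attributes = attrs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an RCC fixture file
#'
#' Emits a file in the dialect [read_rcc()] parses; intended for tests and
#' demonstrations of panel-export ingestion.
#'
#' @param path Output path.
#' @param sample_id Sample identifier (Sample_Attributes ID).
#' @param code_summary data.frame with `CodeClass`, `Name`, `Accession`,
#'   `Count`.
#' @param lane_id Lane identifier.
#' @return `path`, invisibly.
#' @export
write_rcc_fixture <- function(path, sample_id, code_summary, lane_id = "1") {
  need <- c("CodeClass", "Name", "Accession", "Count")
  stopifnot(all(need %in% names(code_summary)))
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,4.0.0.3",
    "</Header>",
    "",
    "<Sample_Attributes>",
    paste0("ID,", sample_id),
    "Owner,",
    "Comments,",
    "Date,20240101",
    "</Sample_Attributes>",
    "",
    "<Lane_Attributes>",
    paste0("ID,", lane_id),
    "FovCount,555",
    "FovCounted,550",
    "BindingDensity,0.5",
    "</Lane_Attributes>",
    "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf(
      "%s,%s,%s,%d",
      code_summary$CodeClass, code_summary$Name,
      code_summary$Accession, as.integer(code_summary$Count)
    ),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a pipeline configuration (JSON)
#'
#' Serializes a [sim_config()] (plus any pipeline options) to JSON and back.
#'
#' @param path JSON file path.
#' @return `read_config` returns a `sim_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), c(known, "seq_params", "panel_params"))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  for (p in c("seq_params", "panel_params")) {
    if (!is.null(raw[[p]])) {
      bad <- setdiff(names(raw[[p]]), names(formals(platform_params)))
      if (length(bad)) {
        stop("unknown ", p, " field(s): ", paste(bad, collapse = ", "))
      }
      raw[[p]] <- do.call(platform_params, raw[[p]])
    }
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @param config A `sim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$seq_params <- unclass(x$seq_params)
  x$panel_params <- unclass(x$panel_params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

write_tsv_num <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full cross-platform concordance pipeline
#'
#' Simulates a paired study from `config` (or takes one supplied as `study`),
#' applies the RNA-quality gate, normalizes the sequencing counts with the
#' none/CPM/TMM/RLE schemes on the full gene set and the panel counts with the
#' two-step scheme, computes sample-wise (Pearson-log, Spearman) and gene-wise
#' (Pearson, Spearman) correlation profiles for each sequencing normalization,
#' expression strata on the TMM gene-wise profiles, runs the NB Wald test with
#' shrinkage on both platforms, and assembles the concordance report. All
#' artifacts are written under `out_dir` together with a manifest recording
#' the package version, seed and configuration hash.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param study Optional pre-built `paired_study`; `config` is then ignored
#'   for simulation but still recorded.
#' @param thresholds DEG thresholds, default [dge_thresholds()] (BY, |lfc|>=1,
#'   alpha 0.05).
#' @return Invisibly, a list with the in-memory results (`study`, `qc`,
#'   `correlations`, `strata`, `dge_panel`, `dge_seq`, `report`, `paths`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         study = NULL, thresholds = dge_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(study)) study <- simulate_paired_study(config)
  stopifnot(inherits(study, "paired_study"))

  paths <- write_paired_study(study, out_dir)
  config_path <- file.path(out_dir, "config.json")
  write_config(config, config_path)

  qc <- sample_qc(study$seq_counts$sample_meta)
  write_tsv_num(qc, file.path(out_dir, "sample_qc.tsv"))

  panel_norm <- panel_two_step_normalize(study$panel_counts, study$panel)
  shared <- intersect(
    panel_genes(study$panel, c("endogenous", "housekeeping")),
    gene_ids(study$seq_counts)
  )
  panel_shared <- subset_genes(panel_norm, shared)

  seq_norms <- lapply(
    stats::setNames(nm = c("none", "cpm", "tmm", "rle")),
    function(m) normalize_counts(study$seq_counts, m)
  )

  correlations <- list()
  for (nm in names(seq_norms)) {
    seq_shared <- subset_genes(seq_norms[[nm]], shared)
    correlations[[nm]] <- list(
      sample_pearson_log = correlation_profile(panel_shared, seq_shared,
        "sample", "pearson_log"),
      sample_spearman = correlation_profile(panel_shared, seq_shared,
        "sample", "spearman"),
      gene_pearson = correlation_profile(panel_shared, seq_shared,
        "gene", "pearson"),
      gene_spearman = correlation_profile(panel_shared, seq_shared,
        "gene", "spearman")
    )
  }

  corr_rows <- do.call(rbind, lapply(names(correlations), function(nm) {
    do.call(rbind, lapply(correlations[[nm]], function(cs) {
      data.frame(
        normalization = nm, axis = cs$axis, coefficient = cs$coefficient,
        id = cs$ids, r = unname(cs$r), stringsAsFactors = FALSE
      )
    }))
  }))
  write_tsv_num(corr_rows, file.path(out_dir, "correlations.tsv"))

  mean_expr_panel <- rowMeans(log2(values(panel_shared) + 1))
  strata <- list(
    pearson = strata_correlations(correlations$tmm$gene_pearson, mean_expr_panel),
    spearman = strata_correlations(correlations$tmm$gene_spearman, mean_expr_panel)
  )

  dge_panel <- shrink_lfc(nb_wald_dge(study$panel_counts,
    size_factors = panel_norm$factors_used$factors^-1
  ))
  dge_seq <- shrink_lfc(nb_wald_dge(study$seq_counts))
  write_tsv_num(as.data.frame(dge_panel), file.path(out_dir, "dge_panel.tsv"))
  write_tsv_num(as.data.frame(dge_seq), file.path(out_dir, "dge_seq.tsv"))

  report <- build_report(
    dge_panel, dge_seq, study$panel, gene_ids(study$seq_counts), thresholds
  )
  report_path <- file.path(out_dir, "report.json")
  report_to_json(report, report_path)

  summary_json <- list(
    sample_wise_medians = lapply(correlations, function(l) list(
      pearson_log = stats::median(l$sample_pearson_log$r, na.rm = TRUE),
      spearman = stats::median(l$sample_spearman$r, na.rm = TRUE)
    )),
    gene_wise_medians = lapply(correlations, function(l) list(
      pearson = stats::median(l$gene_pearson$r, na.rm = TRUE),
      spearman = stats::median(l$gene_spearman$r, na.rm = TRUE)
    )),
    strata_medians = lapply(strata, function(s) lapply(s, function(x) x$box$median))
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "correlation_summary.json"),
    auto_unbox = TRUE, digits = NA
  )

  manifest <- list(
    package = "xconcord",
    version = as.character(utils::packageVersion("xconcord")),
    seed = config$seed,
    config_file = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    outputs = basename(c(
      unname(paths), file.path(out_dir, c(
        "sample_qc.tsv", "correlations.tsv", "dge_panel.tsv", "dge_seq.tsv",
        "report.json", "correlation_summary.json"
      ))
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    study = study, qc = qc, correlations = correlations, strata = strata,
    dge_panel = dge_panel, dge_seq = dge_seq, report = report,
    paths = c(paths,
      config = config_path, report = report_path,
      manifest = file.path(out_dir, "manifest.json")
    )
  ))
}
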