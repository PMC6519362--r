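#' Pipeline run configuration
#'
#' Collects everything a full simulate -> tabulate -> train -> score run
#' needs. Every numeric setting is echoed into the output provenance headers
#' so reports are self-describing.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; all stage seeds derive from it.
#' @param sim a [sim_config()].
#' @param read a [read_config()].
#' @param n_train_controls frequency-table controls used for model training.
#' @param n_controls,n_cmmrd read-level (FASTQ) test samples per group.
#' @param fit_method passed to [fit_control_model()].
#' @param threshold_5pct,threshold_1pct classification thresholds.
#' @return list of class `msi_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       sim = sim_config(),
                       read = read_config(),
                       n_train_controls = 40L,
                       n_controls = 3L, n_cmmrd = 1L,
                       fit_method = "moments",
                       threshold_5pct = 1.30, threshold_1pct = 2.00) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 read = read, n_train_controls = as.integer(n_train_controls),
                 n_controls = as.integer(n_controls),
                 n_cmmrd = as.integer(n_cmmrd), fit_method = fit_method,
                 threshold_5pct = threshold_5pct,
                 threshold_1pct = threshold_1pct),
            class = "msi_run_config")
}

# provenance header lines ("#key<TAB>value") prepended to an artifact
.provenance_header <- function(config, inputs = character(0)) {
  cfg <- list(seed = config$seed,
              n_train_controls = config$n_train_controls,
              n_controls = config$n_controls, n_cmmrd = config$n_cmmrd,
              fit_method = config$fit_method,
              threshold_5pct = config$threshold_5pct,
              threshold_1pct = config$threshold_1pct,
              umi_scheme = config$read$umi_scheme,
              min_family_size = config$read$min_family_size,
              min_consensus_fraction = config$read$min_consensus_fraction,
              min_marker_families = config$read$min_marker_families,
              per_read_length_error = config$sim$per_read_length_error,
              mean_depth = config$sim$mean_depth)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(js, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  lines <- c(sprintf("#msiscope\t%s", as.character(packageVersion("msiscope"))),
             sprintf("#config\t%s", js),
             sprintf("#config_md5\t%s", hash))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("#input\t%s\t%s", basename(inputs), sums))
  }
  lines
}

.prepend_lines <- function(path, lines) {
  body <- readLines(path)
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages, in order: (1) simulate a training control cohort (count tables)
#' and read-level test samples (FASTQ); (2) tabulate the FASTQ samples into
#' counts with QC; (3) train the per-marker Beta control model; (4) score the
#' test samples and write the report. All artifacts land under `out_dir` with
#' provenance headers (tool version, configuration JSON + md5, input file
#' checksums). Stages never mutate their inputs.
#'
#' @param config an [run_config()].
#' @return list with paths of all artifacts and the in-memory `report`
#'   data frame.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance_header(config)
  panel <- config$sim$panel
  # -- stage 1: simulate ----------------------------------------------------
  train_counts <- simulate_frequency_cohort(
    config$sim, "control", config$n_train_controls,
    seed = config$seed + 1L, sample_prefix = "train",
    min_marker_families = config$read$min_marker_families)
  train_path <- file.path(out, "train_counts.tsv")
  write_counts_table(train_counts, train_path)
  .prepend_lines(train_path, prov)
  groups <- rep(c("control", "cmmrd"), c(config$n_controls, config$n_cmmrd))
  fastqs <- character(length(groups))
  for (i in seq_along(groups)) {
    set.seed(config$seed + 100L + i)
    tr <- .draw_truth(config$sim, groups[i])
    fastqs[i] <- file.path(out, sprintf("%s_%02d.fastq.gz", groups[i], i))
    simulate_fastq(config$sim, tr, fastq = fastqs[i],
                   sample_id = sprintf("%s_%02d", groups[i], i))
  }
  # -- stage 2: tabulate ----------------------------------------------------
  tabs <- lapply(seq_along(fastqs), function(i)
    tabulate_fastq(fastqs[i], panel,
                   sample_id = sub("\\.fastq\\.gz$", "", basename(fastqs[i])),
                   config = config$read))
  test_counts <- do.call(rbind, lapply(tabs, `[[`, "counts"))
  counts_path <- file.path(out, "test_counts.tsv")
  write_counts_table(test_counts, counts_path)
  .prepend_lines(counts_path, .provenance_header(config, fastqs))
  qc_path <- file.path(out, "qc.json")
  jsonlite::write_json(lapply(tabs, `[[`, "qc"), qc_path,
                       auto_unbox = TRUE, pretty = TRUE)
  # -- stage 3: train -------------------------------------------------------
  model <- withCallingHandlers(
    fit_control_model(train_counts, fit_method = config$fit_method,
                      on_degenerate = "drop"),
    warning = function(w) { message(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  model_path <- file.path(out, "model.tsv")
  write_control_model(model, model_path)
  # -- stage 4: score -------------------------------------------------------
  check_panel_compatibility(model, test_counts)
  scored <- score_cohort(model, test_counts,
                         threshold_5pct = config$threshold_5pct,
                         threshold_1pct = config$threshold_1pct)
  report_path <- file.path(out, "report.tsv")
  write_score_report(scored$report, report_path)
  .prepend_lines(report_path,
                 .provenance_header(config, c(model_path, counts_path)))
  detail_path <- file.path(out, "report_markers.tsv")
  write.table(scored$detail, detail_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  md_path <- file.path(out, "report.md")
  render_report(scored$report, md_path, format = "markdown",
                panel_size = nrow(panel),
                thresholds = c(config$threshold_5pct, config$threshold_1pct))
  list(train_counts = train_path, fastq = fastqs, counts = counts_path,
       qc = qc_path, model = model_path, report = report_path,
       detail = detail_path, markdown = md_path, report_df = scored$report)
}

#' Check that a model and a counts table come from the same panel
#'
#' @param model fitted control model.
#' @param counts counts table to score.
#' @return invisibly `TRUE`; raises a panel-mismatch error otherwise.
#' @export
check_panel_compatibility <- function(model, counts) {
  missing <- setdiff(unique(counts$marker_id), model$markers$marker_id)
  if (length(missing) == length(unique(counts$marker_id)))
    stop_msi("model and counts share no markers (panel mismatch)",
             class = "msi_panel_mismatch_error")
  invisible(TRUE)
}

#' Render a score report
#'
#' @param report report data frame (see [score_cohort()]).
#' @param path output path.
#' @param format `"tsv"`, `"json"` or `"markdown"`. The markdown variant
#'   lists per-sample score, both threshold calls and the number of markers
#'   `k`, with a caveat line whenever `k` is below the panel size.
#' @param panel_size full panel size used for the caveat (default 24).
#' @param thresholds the two thresholds annotated in the report.
#' @return the path, invisibly.
#' @export
render_report <- function(report, path, format = c("tsv", "json", "markdown"),
                          panel_size = 24L, thresholds = c(1.30, 2.00)) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_score_report(report, path)
  } else if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    lines <- c(
      "# MSI score report",
      "",
      sprintf("Thresholds: score >= %.2f (5%% control probability) = lenient positive; score >= %.2f (1%%) = conservative positive.",
              thresholds[1], thresholds[2]),
      "",
      "| sample | score | k | call @1.30 | call @2.00 |",
      "|---|---|---|---|---|")
    for (i in seq_len(nrow(report))) {
      r <- report[i, ]
      lines <- c(lines, sprintf("| %s | %.2f | %d | %s | %s |",
                                r$sample_id, r$score, r$k,
                                if (r$call_1.30) "POSITIVE" else "negative",
                                if (r$call_2.00) "POSITIVE" else "negative"))
    }
    low <- report$k < panel_size
    if (any(low))
      lines <- c(lines, "",
                 sprintf("Caveat: %s scored on fewer than %d markers (reduced degrees of freedom).",
                         paste(report$sample_id[low], collapse = ", "),
                         panel_size))
    writeLines(lines, path)
  }
  invisible(path)
}
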