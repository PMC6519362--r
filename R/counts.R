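#' Build per-marker count records from length histograms
#'
#' A counts table has one row per sample x marker with the consensus-family
#' repeat-length histogram, the wild-type (WT) family count, the total family
#' count, the WT frequency and a coverage QC flag. Markers with zero coverage
#' are kept (not dropped) with `total_count = 0`, `qc_pass = FALSE` and an
#' undefined (`NA`) `wt_frequency`.
#'
#' @param sample_id sample label (scalar).
#' @param marker_id marker labels, one per histogram.
#' @param histograms list of named integer vectors (names = repeat length).
#' @param wt_length integer WT length per marker.
#' @param min_marker_families minimum family count for `qc_pass` (default 100).
#' @return A `data.frame` with columns `sample_id`, `marker_id`, `histogram`
#'   (serialized `length:count` pairs), `wt_count`, `total_count`,
#'   `wt_frequency`, `qc_pass`.
#' @export
marker_counts <- function(sample_id, marker_id, histograms, wt_length,
                          min_marker_families = 100L) {
  stopifnot(length(marker_id) == length(histograms),
            length(wt_length) == length(marker_id))
  wt_count <- mapply(function(h, wt) {
    v <- h[as.character(wt)]
    if (is.na(v)) 0L else as.integer(v)
  }, histograms, wt_length)
  total <- vapply(histograms, function(h) as.integer(sum(h)), 1L)
  data.frame(
    sample_id = as.character(sample_id),
    marker_id = as.character(marker_id),
    histogram = vapply(histograms, format_hist, ""),
    wt_count = as.integer(wt_count),
    total_count = total,
    wt_frequency = ifelse(total > 0L, wt_count / total, NA_real_),
    qc_pass = total >= min_marker_families,
    stringsAsFactors = FALSE
  )
}

#' Write / read a counts table
#'
#' Tab-delimited UTF-8 with a mandatory header; one row per sample x marker.
#' Round-trips losslessly, including QC flags and undefined frequencies.
#'
#' @param counts a counts `data.frame` (see [marker_counts()]), possibly
#'   spanning several samples.
#' @param path output (input) file path.
#' @return `write_counts_table()`: the path, invisibly.
#'   `read_counts_table()`: the counts `data.frame`.
#' @export
write_counts_table <- function(counts, path) {
  req <- c("sample_id", "marker_id", "histogram", "wt_count",
           "total_count", "wt_frequency", "qc_pass")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop_msi("counts table missing column(s): %s",
             paste(miss, collapse = ", "), class = "msi_validation_error")
  key <- paste(counts$sample_id, counts$marker_id)
  if (anyDuplicated(key))
    stop_msi("duplicate sample x marker row: %s", key[duplicated(key)][1],
             class = "msi_validation_error")
  out <- counts[, req]
  out$wt_frequency <- ifelse(is.na(out$wt_frequency), "NA",
                             sprintf("%.12g", out$wt_frequency))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  df <- tryCatch(suppressWarnings(
                   read.delim(path, stringsAsFactors = FALSE,
                              comment.char = "#",
                              colClasses = c(histogram = "character"))),
                 error = function(e)
                   stop_msi("failed to parse counts table '%s': %s", path,
                            conditionMessage(e), class = "msi_parse_error"))
  req <- c("sample_id", "marker_id", "histogram", "wt_count",
           "total_count", "wt_frequency", "qc_pass")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_msi("counts table '%s' missing column(s): %s", path,
             paste(miss, collapse = ", "), class = "msi_parse_error")
  key <- paste(df$sample_id, df$marker_id)
  if (anyDuplicated(key))
    stop_msi("duplicate sample x marker row in '%s': %s", path,
             key[duplicated(key)][1], class = "msi_validation_error")
  df$sample_id <- as.character(df$sample_id)
  df$marker_id <- as.character(df$marker_id)
  df$histogram[is.na(df$histogram)] <- ""
  df$wt_frequency <- suppressWarnings(as.numeric(df$wt_frequency))
  df$qc_pass <- as.logical(df$qc_pass)
  df
}

# wide matrix (samples x markers) of WT frequencies from a long counts table;
# qc-failing cells become NA
counts_to_freq_matrix <- function(counts, qc_only = TRUE) {
  samples <- unique(counts$sample_id)
  markers <- unique(counts$marker_id)
  m <- matrix(NA_real_, length(samples), length(markers),
              dimnames = list(samples, markers))
  keep <- if (qc_only) counts$qc_pass & !is.na(counts$wt_frequency)
          else !is.na(counts$wt_frequency)
  cc <- counts[keep, ]
  m[cbind(match(cc$sample_id, samples), match(cc$marker_id, markers))] <-
    cc$wt_frequency
  m
}
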