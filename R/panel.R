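#' Construct a marker panel definition
#'
#' A panel is a data frame with one row per mononucleotide-repeat marker.
#' Coordinates follow the BED convention (0-based, half-open), so the repeat
#' tract spans `[start, end)` and `end - start` must equal the wild-type
#' repeat length. Flank sequences are the anchor sequences immediately
#' adjacent to the tract and must terminate the homopolymer run: the base of
#' `left_flank` touching the tract, and the base of `right_flank` touching
#' it, must differ from the repeat unit.
#'
#' @param marker_id character vector of unique marker labels.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open tract coordinates.
#' @param repeat_unit single base A/C/G/T per marker.
#' @param wt_length wild-type repeat length in bases (7-12).
#' @param left_flank,right_flank uppercase DNA anchors adjacent to the tract.
#' @return A `data.frame` of class `msi_panel`.
#' @export
marker_panel <- function(marker_id, chrom, start, end, repeat_unit,
                         wt_length, left_flank, right_flank) {
  panel <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    repeat_unit = toupper(as.character(repeat_unit)),
    wt_length = as.integer(wt_length),
    left_flank = toupper(as.character(left_flank)),
    right_flank = toupper(as.character(right_flank)),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("msi_panel", "data.frame")
  panel
}

#' Validate a marker panel
#'
#' Checks every panel invariant and raises a validation error naming the
#' offending marker.
#'
#' @param panel a panel data frame as built by [marker_panel()] or
#'   [load_panel()].
#' @return The panel, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  req <- c("marker_id", "chrom", "start", "end", "repeat_unit",
           "wt_length", "left_flank", "right_flank")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop_msi("panel is missing column(s): %s", paste(miss, collapse = ", "),
             class = "msi_parse_error")
  dup <- panel$marker_id[duplicated(panel$marker_id)]
  if (length(dup))
    stop_msi("duplicate marker_id: %s", dup[1], class = "msi_validation_error")
  for (i in seq_len(nrow(panel))) {
    m <- panel[i, ]
    fail <- function(msg) stop_msi("marker '%s': %s", m$marker_id, msg,
                                   class = "msi_validation_error")
    if (!m$repeat_unit %in% c("A", "C", "G", "T"))
      fail("repeat_unit must be one of A/C/G/T")
    if (m$end - m$start != m$wt_length)
      fail(sprintf("tract span (%d) != wt_length (%d)",
                   m$end - m$start, m$wt_length))
    if (m$wt_length < 7L || m$wt_length > 12L)
      fail("wt_length must be in 7..12")
    if (!is_dna(m$left_flank) || !is_dna(m$right_flank))
      fail("flanks must be DNA (A/C/G/T/N)")
    if (substr(m$left_flank, nchar(m$left_flank), nchar(m$left_flank)) ==
        m$repeat_unit)
      fail("last base of left_flank equals the repeat unit (anchor does not terminate the run)")
    if (substr(m$right_flank, 1L, 1L) == m$repeat_unit)
      fail("first base of right_flank equals the repeat unit (anchor does not terminate the run)")
  }
  invisible(panel)
}

#' Load a marker panel from BED + metadata TSV
#'
#' The BED file (chrom, start, end, name) gives the tract coordinates; the
#' companion TSV, keyed by `marker_id`, supplies the repeat unit, wild-type
#' length and flank anchors. Every panel invariant is checked on load.
#'
#' @param bed_path path to a 4-column BED file, one record per marker.
#' @param meta_path path to a tab-delimited file with columns `marker_id`,
#'   `repeat_unit`, `wt_length`, `left_flank`, `right_flank`.
#' @return A validated panel (`msi_panel`).
#' @export
load_panel <- function(bed_path, meta_path) {
  gr <- tryCatch(rtracklayer::import(bed_path, format = "BED"),
                 error = function(e)
                   stop_msi("failed to parse BED '%s': %s", bed_path,
                            conditionMessage(e), class = "msi_parse_error"))
  meta <- tryCatch(read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character"),
                   error = function(e)
                     stop_msi("failed to parse meta TSV '%s': %s", meta_path,
                              conditionMessage(e), class = "msi_parse_error"))
  req <- c("marker_id", "repeat_unit", "wt_length", "left_flank", "right_flank")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop_msi("panel meta '%s' missing column(s): %s", meta_path,
             paste(miss, collapse = ", "), class = "msi_parse_error")
  ids <- as.character(GenomicRanges::mcols(gr)$name)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop_msi("BED '%s' has records without a name field", bed_path,
             class = "msi_parse_error")
  idx <- match(ids, meta$marker_id)
  if (anyNA(idx))
    stop_msi("marker '%s' present in BED but absent from meta TSV",
             ids[which(is.na(idx))[1]], class = "msi_validation_error")
  meta <- meta[idx, ]
  marker_panel(
    marker_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # rtracklayer imports BED as 1-based closed ranges; convert back
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    repeat_unit = meta$repeat_unit,
    wt_length = as.integer(meta$wt_length),
    left_flank = meta$left_flank,
    right_flank = meta$right_flank
  )
}

#' Write a panel to BED + metadata TSV
#'
#' @param panel a validated panel.
#' @param bed_path,meta_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, bed_path, meta_path) {
  validate_panel(panel)
  bed <- panel[, c("chrom", "start", "end", "marker_id")]
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- panel[, c("marker_id", "repeat_unit", "wt_length",
                    "left_flank", "right_flank")]
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, meta = meta_path))
}

#' Generate a synthetic stand-in marker panel
#'
#' The published assay targets 24 specific genomic loci whose coordinates and
#' flanks live in supplementary material, not in the main text; this function
#' fabricates a panel with the same stated properties (24 short 7-12 bp
#' monomorphic mononucleotide repeats with known flanks) so the pipeline can
#' be exercised without the real design. Flanks are random but constrained to
#' terminate the repeat run and to avoid containing a long run of the repeat
#' unit themselves. Substitute the real BED/TSV via [load_panel()] to run the
#' published panel.
#'
#' @param n_markers number of markers (default 24).
#' @param flank_length anchor length in bp (default 10).
#' @param seed integer seed; the default yields the panel shipped in
#'   `inst/extdata/`.
#' @return A validated panel (`msi_panel`).
#' @export
synthetic_panel <- function(n_markers = 24L, flank_length = 10L, seed = 2024L) {
  # use a private RNG stream so building a panel never disturbs the caller's
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  # mostly A/T repeats, as in real mononucleotide MSI panels
  units <- sample(c("A", "T", "A", "T", "C", "G"), n_markers, replace = TRUE)
  wt <- 7L + (seq_len(n_markers) - 1L) %% 6L   # cycle 7..12
  rand_flank <- function(unit, terminal_first) {
    other <- setdiff(c("A", "C", "G", "T"), unit)
    repeat {
      fl <- sample(c("A", "C", "G", "T"), flank_length, replace = TRUE)
      # anchor base touching the tract must not extend the run
      if (terminal_first) fl[1L] <- sample(other, 1L) else
        fl[flank_length] <- sample(other, 1L)
      s <- paste(fl, collapse = "")
      # avoid internal runs of the unit that could blur the tract boundary
      if (!grepl(strrep(unit, 3L), s)) return(s)
    }
  }
  start <- cumsum(c(1000L, rep(5000L, n_markers - 1L)))
  marker_panel(
    marker_id = sprintf("M%02d", seq_len(n_markers)),
    chrom = "chrS",
    start = start,
    end = start + wt,
    repeat_unit = units,
    wt_length = wt,
    left_flank = vapply(units, rand_flank, "", terminal_first = FALSE),
    right_flank = vapply(units, rand_flank, "", terminal_first = TRUE)
  )
}
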