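#' Read-processing configuration
#'
#' Bundles the tunables that turn raw reads into per-marker family counts.
#'
#' @param umi_scheme barcode location: `"read5:N"` takes the leading `N`
#'   bases of each read (default `"read5:5"`, matching the 5-nt single-arm
#'   barcode of common smMIP designs); `"name:TAG"` takes the field following
#'   `TAG:` in the read name, leaving the sequence untouched.
#' @param max_anchor_mismatches substitutions tolerated in each flank anchor
#'   (no indels inside anchors; default 1).
#' @param min_family_size smallest UMI family for which a consensus is called
#'   (default 2).
#' @param min_consensus_fraction fraction of a family that must share the
#'   modal length for it to become the consensus; must exceed 0.5
#'   (default 0.66).
#' @param min_marker_families families required at a marker for `qc_pass`
#'   (default 100).
#' @param count_mode `"family"` counts consensus families (default);
#'   `"read"` counts raw anchored reads without barcode error correction,
#'   for comparison.
#' @return A list of class `msi_read_config`.
#' @export
read_config <- function(umi_scheme = "read5:5",
                        max_anchor_mismatches = 1L,
                        min_family_size = 2L,
                        min_consensus_fraction = 0.66,
                        min_marker_families = 100L,
                        count_mode = c("family", "read")) {
  count_mode <- match.arg(count_mode)
  if (min_consensus_fraction <= 0.5)
    stop_msi("min_consensus_fraction must exceed 0.5 (got %g)",
             min_consensus_fraction, class = "msi_config_error")
  structure(list(umi_scheme = umi_scheme,
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 min_family_size = as.integer(min_family_size),
                 min_consensus_fraction = min_consensus_fraction,
                 min_marker_families = as.integer(min_marker_families),
                 count_mode = count_mode),
            class = "msi_read_config")
}

parse_umi_scheme <- function(scheme) {
  if (grepl("^read5:\\d+$", scheme)) {
    list(type = "read5", len = as.integer(sub("^read5:", "", scheme)))
  } else if (grepl("^name:.+$", scheme)) {
    list(type = "name", tag = sub("^name:", "", scheme))
  } else {
    stop_msi("unknown umi scheme '%s' (use 'read5:N' or 'name:TAG')",
             scheme, class = "msi_config_error")
  }
}

#' Extract molecular barcodes from reads
#'
#' Vectorised over reads. Under an in-read scheme the barcode bases are
#' removed from the returned sequence; under a name-tag scheme the sequence
#' is unchanged. Reads too short to contain the barcode (or names lacking the
#' tag) are flagged as no-calls and excluded from downstream counting.
#'
#' @param seqs character vector of read sequences.
#' @param names character vector of read names (needed for name-tag schemes).
#' @param umi_scheme scheme string, see [read_config()].
#' @return A list with `umi` (NA for no-calls), `seq` (trimmed sequences) and
#'   `ok` (logical).
#' @export
extract_umi <- function(seqs, names = NULL, umi_scheme = "read5:5") {
  sc <- parse_umi_scheme(umi_scheme)
  if (sc$type == "read5") {
    ok <- nchar(seqs) >= sc$len
    umi <- ifelse(ok, substr(seqs, 1L, sc$len), NA_character_)
    seq <- ifelse(ok, substr(seqs, sc$len + 1L, nchar(seqs)), seqs)
  } else {
    if (is.null(names))
      stop_msi("name-tag umi scheme needs read names", class = "msi_config_error")
    pat <- paste0(".*", sc$tag, ":([A-Za-z]+).*")
    hit <- grepl(pat, names)
    umi <- ifelse(hit, sub(pat, "\\1", names), NA_character_)
    ok <- hit
    seq <- seqs
  }
  list(umi = umi, seq = seq, ok = ok)
}

# one orientation of flank anchoring; returns candidate assignments
.anchor_pass <- function(seqs, panel, max_mm) {
  dss <- Biostrings::DNAStringSet(seqs)
  cand <- list()
  for (i in seq_len(nrow(panel))) {
    lf <- panel$left_flank[i]
    rf <- panel$right_flank[i]
    lm <- Biostrings::vmatchPattern(lf, dss, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
    rm_ <- Biostrings::vmatchPattern(rf, dss, max.mismatch = max_mm,
                                     with.indels = FALSE, fixed = TRUE)
    li <- Biostrings::endIndex(lm)        # plain lists: avoids S4 overhead
    ri <- Biostrings::startIndex(rm_)
    hit <- which(lengths(li) > 0L & lengths(ri) > 0L)
    if (!length(hit)) next
    lend <- vapply(li[hit], min, 1L)      # leftmost left-anchor end
    rstart <- vapply(ri[hit], min, 1L)    # first right-anchor start
    ok <- rstart > lend          # left anchor strictly before right anchor
    if (!any(ok)) next
    hit <- hit[ok]
    tract <- substr(seqs[hit], lend[ok] + 1L, rstart[ok] - 1L)
    unit <- panel$repeat_unit[i]
    obs <- nchar(tract) - nchar(gsub(unit, "", tract, fixed = TRUE))
    cand[[length(cand) + 1L]] <- data.frame(
      read = hit, marker_id = panel$marker_id[i],
      observed_length = as.integer(obs), stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(read = integer(0), marker_id = character(0),
                      observed_length = integer(0)))
  do.call(rbind, cand)
}

# resolve one stage: unique assignments, plus which reads were ambiguous
.anchor_stage <- function(seqs, panel, mm) {
  cand <- .anchor_pass(seqs, panel, mm)
  nhit <- tabulate(cand$read, nbins = length(seqs))
  list(assigned = cand[nhit[cand$read] == 1L, , drop = FALSE],
       ambiguous = which(nhit >= 2L))
}

#' Assign reads to markers by flank anchoring
#'
#' Alignment-free marker assignment: a read is assigned to the unique marker
#' whose left and right flank anchors both occur in it (each with at most
#' `max_mm` substitutions, no indels inside anchors, left before right). The
#' tract is the substring strictly between the anchors and `observed_length`
#' counts the repeat-unit bases in it, so an interrupting substitution
#' shortens the call. Reads matching no marker, matching two or more markers,
#' or with anchors out of order are no-matches. The reverse complement is
#' tried for reads that fail in forward orientation.
#'
#' Matching is staged for speed: an exact pass assigns most reads, and only
#' reads left unassigned enter the mismatch-tolerant pass, then the two
#' passes are repeated on the reverse complement. An exact flank match
#' therefore outranks a mismatched one; with distinct anchor sequences the
#' outcome is the same as a single fuzzy pass.
#'
#' @param seqs character vector of read sequences (A/C/G/T/N).
#' @param panel marker panel.
#' @param max_mm maximum substitutions per anchor.
#' @return data frame with one row per anchored read: `read` (input index),
#'   `marker_id`, `observed_length`, `orientation` (`"+"`/`"-"`).
#' @export
anchor_reads <- function(seqs, panel, max_mm = 1L) {
  bad <- !is_dna(seqs)
  if (any(bad))
    stop_msi("read %d contains non-DNA characters", which(bad)[1],
             class = "msi_input_error")
  out <- list()
  todo <- seq_along(seqs)          # reads still unassigned and unambiguous
  stages <- list(list(orient = "+", mm = 0L))
  if (max_mm > 0L) stages <- c(stages, list(list(orient = "+", mm = max_mm)))
  stages <- c(stages, list(list(orient = "-", mm = 0L)))
  if (max_mm > 0L) stages <- c(stages, list(list(orient = "-", mm = max_mm)))
  rc <- NULL
  for (st in stages) {
    if (!length(todo)) break
    ss <- if (st$orient == "+") seqs[todo] else {
      if (is.null(rc)) rc <- revcomp(seqs)
      rc[todo]
    }
    res <- .anchor_stage(ss, panel, st$mm)
    a <- res$assigned
    if (nrow(a)) {
      a$read <- todo[a$read]
      a$orientation <- st$orient
      out[[length(out) + 1L]] <- a
    }
    todo <- setdiff(todo, c(todo[res$ambiguous], a$read))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read = integer(0), marker_id = character(0),
                      observed_length = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  out[order(out$read), , drop = FALSE]
}

#' Anchor a single read
#'
#' Scalar convenience wrapper around [anchor_reads()].
#'
#' @inheritParams anchor_reads
#' @param read_sequence one read sequence.
#' @return A one-row data frame as in [anchor_reads()], or `NULL` when the
#'   read matches no marker (or matches ambiguously).
#' @export
anchor_read <- function(read_sequence, panel, max_mm = 1L) {
  res <- anchor_reads(read_sequence, panel, max_mm)
  if (nrow(res) == 0L) NULL else res
}

#' Group anchored reads into UMI families
#'
#' Reads are partitioned exactly by the pair (marker, barcode); each family
#' collects the observed repeat lengths of its member reads.
#'
#' @param anchored data frame with columns `marker_id`, `umi`,
#'   `observed_length` (one row per read).
#' @return data frame with one row per family: `marker_id`, `umi`,
#'   `family_size`, and `member_lengths` (list column of integer vectors).
#' @export
build_families <- function(anchored) {
  if (nrow(anchored) == 0L) {
    out <- data.frame(marker_id = character(0), umi = character(0),
                      family_size = integer(0), stringsAsFactors = FALSE)
    out$member_lengths <- list()
    return(out)
  }
  key <- paste(anchored$marker_id, anchored$umi, sep = "\r")
  lens <- split(anchored$observed_length, key)
  parts <- strsplit(names(lens), "\r", fixed = TRUE)
  out <- data.frame(
    marker_id = vapply(parts, `[`, "", 1L),
    umi = vapply(parts, `[`, "", 2L),
    family_size = vapply(lens, length, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  out$member_lengths <- unname(lens)
  out
}

#' Call a family's consensus repeat length
#'
#' Majority vote within a UMI family: families smaller than
#' `min_family_size` are no-calls; otherwise the modal length is the
#' consensus iff its within-family frequency reaches
#' `min_consensus_fraction`. Ties between modes are discarded (no-call).
#'
#' @param lengths integer vector of member observed lengths (one family).
#' @param min_family_size,min_consensus_fraction see [read_config()].
#' @return The consensus length, or `NA_integer_` for a no-call.
#' @export
call_consensus <- function(lengths, min_family_size = 2L,
                           min_consensus_fraction = 0.66) {
  if (min_consensus_fraction <= 0.5)
    stop_msi("min_consensus_fraction must exceed 0.5", class = "msi_config_error")
  n <- length(lengths)
  if (n < min_family_size) return(NA_integer_)
  tab <- table(lengths)
  mx <- max(tab)
  if (sum(tab == mx) != 1L) return(NA_integer_)
  if (mx / n < min_consensus_fraction) return(NA_integer_)
  as.integer(names(tab)[which.max(tab)])
}

#' Tabulate consensus families into per-marker counts
#'
#' Builds, for every marker of the panel, the histogram of called consensus
#' lengths and derives WT count, total count and WT frequency. Markers with
#' no families are emitted with zero counts and `qc_pass = FALSE`.
#'
#' @param families output of [build_families()].
#' @param panel marker panel.
#' @param sample_id label recorded in the table.
#' @param config an [read_config()] object.
#' @return A counts `data.frame` (one row per marker) plus attribute
#'   `consensus_nocall` (number of families without a consensus).
#' @export
tabulate_sample <- function(families, panel, sample_id = "sample",
                            config = read_config()) {
  cons <- vapply(families$member_lengths, call_consensus, 1L,
                 min_family_size = config$min_family_size,
                 min_consensus_fraction = config$min_consensus_fraction)
  called <- !is.na(cons)
  hists <- lapply(seq_len(nrow(panel)), function(i) {
    v <- cons[called & families$marker_id == panel$marker_id[i]]
    if (!length(v)) return(integer(0))
    tab <- table(v)
    h <- as.integer(tab)
    names(h) <- names(tab)
    h
  })
  out <- marker_counts(sample_id, panel$marker_id, hists, panel$wt_length,
                       min_marker_families = config$min_marker_families)
  attr(out, "consensus_nocall") <- sum(!called)
  out
}

# shared back half of the fastq/bam front ends
.process_reads <- function(seqs, names, sample_id, panel, config) {
  n_reads <- length(seqs)
  um <- extract_umi(seqs, names, config$umi_scheme)
  n_umi_nocall <- sum(!um$ok)
  seqs2 <- um$seq[um$ok]
  anch <- anchor_reads(seqs2, panel, config$max_anchor_mismatches)
  anch$umi <- um$umi[um$ok][anch$read]
  n_anchored <- nrow(anch)
  n_no_match <- length(seqs2) - n_anchored
  if (config$count_mode == "read") {
    # raw-read mode: each anchored read is its own "family"
    fam <- anch
    fam$family_size <- 1L
    fam$member_lengths <- as.list(fam$observed_length)
    cfg <- config
    cfg$min_family_size <- 1L
    counts <- tabulate_sample(fam, panel, sample_id, cfg)
    fam_sizes <- rep(1L, nrow(anch))
  } else {
    fam <- build_families(anch)
    counts <- tabulate_sample(fam, panel, sample_id, config)
    fam_sizes <- fam$family_size
  }
  qc <- list(
    sample_id = sample_id,
    n_reads = n_reads,
    n_umi_nocall = n_umi_nocall,
    n_anchored = n_anchored,
    n_no_match = n_no_match,
    conservation_ok = (n_umi_nocall + n_anchored + n_no_match) == n_reads,
    n_families = length(fam_sizes),
    n_consensus_nocall = attr(counts, "consensus_nocall"),
    family_size_histogram = as.list(table(fam_sizes))
  )
  list(counts = counts, qc = qc)
}

#' Tabulate a FASTQ sample into marker counts
#'
#' Reads one or two (paired) FASTQ files, optionally gzipped; mates are
#' processed independently and merged at the family level (same marker +
#' barcode). Returns the counts table and a QC summary whose read-class
#' tallies (umi-no-call, anchored, no-match) sum to the input read count.
#'
#' @param fastq character vector of 1 or 2 FASTQ paths.
#' @param panel marker panel.
#' @param sample_id label for the counts rows.
#' @param config an [read_config()].
#' @return list with `counts` (data frame) and `qc` (list).
#' @export
tabulate_fastq <- function(fastq, panel, sample_id = "sample",
                           config = read_config()) {
  seqs <- character(0)
  nms <- character(0)
  for (fp in fastq) {
    ss <- Biostrings::readDNAStringSet(fp, format = "fastq")
    seqs <- c(seqs, as.character(ss))
    nms <- c(nms, names(ss))
  }
  .process_reads(unname(seqs), nms, sample_id, panel, config)
}

#' Tabulate an aligned BAM sample into marker counts
#'
#' Alignment is used only to retrieve candidate reads overlapping each marker
#' interval; every retrieved read is then re-anchored by the same flank
#' procedure as the FASTQ path, because aligner gap placement inside
#' homopolymers is unreliable. Requires a coordinate-sorted, indexed BAM.
#'
#' @param bam path to an indexed BAM file.
#' @param panel marker panel.
#' @param sample_id label for the counts rows.
#' @param config an [read_config()]; for aligned data the barcode usually
#'   lives in the read name, e.g. `umi_scheme = "name:UMI"`.
#' @param pad bases added on both sides of each marker interval when
#'   collecting candidates (default 50).
#' @return list with `counts` and `qc`, as [tabulate_fastq()].
#' @export
tabulate_bam <- function(bam, panel, sample_id = "sample",
                         config = read_config(umi_scheme = "name:UMI"),
                         pad = 50L) {
  which <- GenomicRanges::GRanges(
    panel$chrom,
    IRanges::IRanges(pmax(1L, panel$start + 1L - pad), panel$end + pad))
  param <- Rsamtools::ScanBamParam(which = which,
                                   what = c("qname", "seq"))
  res <- Rsamtools::scanBam(bam, param = param)
  qname <- unlist(lapply(res, `[[`, "qname"), use.names = FALSE)
  seq <- unlist(lapply(res, function(x) as.character(x$seq)),
                use.names = FALSE)
  dup <- duplicated(qname)     # a read can overlap several query windows
  .process_reads(seq[!dup], qname[!dup], sample_id, panel, config)
}
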