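#' Simulation configuration
#'
#' Describes the generative world the scorer assumes: per-marker control WT
#' frequencies follow marker-specific Beta distributions with means close to
#' 1; mismatch-repair-deficient (CMMRD) samples depress those frequencies
#' multiplicatively; sequencing depth matches the assay's reported
#' 3,642 +/- 1,659 reads/marker/sample; reads carry a molecular barcode and
#' are perturbed by contraction-biased polymerase slippage.
#'
#' Defaults (the stated world of the generator):
#' * control Beta means are spread over 0.95-0.999 with a common
#'   concentration of 62 (so the least stable marker is Beta(58.9, 3.1), the
#'   most stable Beta(61.9, 0.06) -- the Beta(60, 2) family);
#' * `cmmrd_effect` spreads over 0.85-0.98 across markers;
#' * `per_read_length_error = 0.02` with 70% of slips being contractions,
#'   a realistic slippage rate for 7-12 bp homopolymers;
#' * `mean_family_size = 4` reads per captured molecule, so the default
#'   depth corresponds to roughly 900 UMI families per marker.
#'
#' @param n_markers number of markers (default 24).
#' @param panel marker panel; default [synthetic_panel()] with `n_markers`.
#' @param control_mean per-marker mean control WT frequency.
#' @param concentration Beta concentration (alpha + beta) per marker.
#' @param cmmrd_effect per-marker multiplicative depression of the expected
#'   WT frequency in CMMRD samples.
#' @param mean_depth,depth_sd reads per marker per sample (normal, truncated
#'   at `mean_family_size`).
#' @param mean_family_size mean reads per UMI family.
#' @param per_read_length_error probability a read's observed length deviates
#'   from its molecule's true length by +/-1.
#' @param contraction_bias fraction of slippage events that contract the
#'   repeat (both in molecule truth and read noise).
#' @param umi_length barcode length in nt (default 5).
#' @return list of class `msi_sim_config`.
#' @export
sim_config <- function(n_markers = 24L,
                       panel = synthetic_panel(n_markers),
                       control_mean = seq(0.95, 0.999, length.out = n_markers),
                       concentration = rep(62, n_markers),
                       cmmrd_effect = seq(0.85, 0.98, length.out = n_markers),
                       mean_depth = 3642,
                       depth_sd = 1659,
                       mean_family_size = 4,
                       per_read_length_error = 0.02,
                       contraction_bias = 0.7,
                       umi_length = 5L) {
  stopifnot(nrow(panel) == n_markers,
            all(control_mean > 0 & control_mean < 1),
            all(cmmrd_effect > 0 & cmmrd_effect <= 1),
            per_read_length_error >= 0, per_read_length_error <= 1,
            contraction_bias >= 0, contraction_bias <= 1,
            mean_depth > 0, mean_family_size >= 1)
  structure(list(
    n_markers = as.integer(n_markers), panel = panel,
    alpha0 = control_mean * concentration,
    beta0 = (1 - control_mean) * concentration,
    cmmrd_effect = cmmrd_effect,
    mean_depth = mean_depth, depth_sd = depth_sd,
    mean_family_size = mean_family_size,
    per_read_length_error = per_read_length_error,
    contraction_bias = contraction_bias,
    umi_length = as.integer(umi_length)
  ), class = "msi_sim_config")
}

# distribution of non-WT lengths around wt: +/-1 gets 80% of the mass,
# +/-2 the remaining 20%, contractions favoured by `cb`
.variant_length_probs <- function(wt, cb) {
  stats::setNames(c(0.8 * cb, 0.8 * (1 - cb), 0.2 * cb, 0.2 * (1 - cb)),
                  c(wt - 1L, wt + 1L, wt - 2L, wt + 2L))
}

# per-marker true WT fractions for one sample
.draw_truth <- function(config, group) {
  p <- rbeta(config$n_markers, config$alpha0, config$beta0)
  if (group == "cmmrd") p <- p * config$cmmrd_effect
  stats::setNames(p, config$panel$marker_id)
}

# expected families per marker, with depth variability
.draw_n_families <- function(config, n) {
  depth <- pmax(config$mean_family_size,
                rnorm(n, config$mean_depth, config$depth_sd))
  pmax(1L, rpois(n, depth / config$mean_family_size))
}

#' Simulate a cohort of per-marker count tables
#'
#' Draws, per sample and marker, a true WT fraction from the group's
#' generative Beta (control) or the control Beta multiplicatively depressed
#' (`cmmrd`), a family count around the configured depth, and a binomial WT
#' family count; non-WT families are spread over wt_length +/- 1 and +/- 2
#' (80/20, contraction-biased). Output is a standard long counts table.
#'
#' @param config [sim_config()].
#' @param group `"control"` or `"cmmrd"`.
#' @param n_samples cohort size (> 0).
#' @param seed integer seed; same (config, seed) gives identical tables.
#' @param sample_prefix prefix for sample ids.
#' @param min_marker_families QC threshold recorded in the table.
#' @return counts `data.frame` with attribute `truth` (samples x markers
#'   matrix of true WT fractions).
#' @export
simulate_frequency_cohort <- function(config, group = c("control", "cmmrd"),
                                      n_samples, seed = NULL,
                                      sample_prefix = NULL,
                                      min_marker_families = 100L) {
  group <- match.arg(group)
  if (n_samples <= 0)
    stop_msi("n_samples must be positive", class = "msi_config_error")
  if (!is.null(seed)) set.seed(seed)
  sample_prefix <- sample_prefix %||% group
  panel <- config$panel
  truth <- matrix(NA_real_, n_samples, config$n_markers,
                  dimnames = list(NULL, panel$marker_id))
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    p <- .draw_truth(config, group)
    truth[s, ] <- p
    nf <- .draw_n_families(config, config$n_markers)
    wt <- rbinom(config$n_markers, nf, p)
    hists <- lapply(seq_len(config$n_markers), function(i) {
      h <- integer(0)
      wl <- panel$wt_length[i]
      if (wt[i] > 0L) h[as.character(wl)] <- wt[i]
      nv <- nf[i] - wt[i]
      if (nv > 0L) {
        pr <- .variant_length_probs(wl, config$contraction_bias)
        v <- stats::rmultinom(1L, nv, pr)[, 1L]
        for (len in names(v)) if (v[[len]] > 0L)
          h[len] <- (if (len %in% names(h)) h[[len]] else 0L) + v[[len]]
      }
      h
    })
    out[[s]] <- marker_counts(sprintf("%s_%03d", sample_prefix, s),
                              panel$marker_id, hists, panel$wt_length,
                              min_marker_families = min_marker_families)
  }
  res <- do.call(rbind, out)
  rownames(truth) <- unique(res$sample_id)
  attr(res, "truth") <- truth
  res
}

#' Simulate UMI-bearing reads for one sample
#'
#' Per marker, molecules are drawn with true repeat lengths (WT with the
#' sample's true fraction, otherwise a slippage variant), each molecule gets
#' a random barcode (collisions possible) and a family of reads; each read's
#' length is independently perturbed with probability
#' `per_read_length_error`. Reads are `UMI + left_flank + tract +
#' right_flank`.
#'
#' @param config [sim_config()].
#' @param sample_truth named per-marker true WT fractions (names = marker
#'   ids), e.g. one row of a cohort `truth` attribute.
#' @param seed integer seed.
#' @param fastq optional path; when given, reads are written as (gzipped if
#'   the name ends `.gz`) FASTQ.
#' @param sample_id read-name prefix.
#' @return list with `seqs`, `names` (character vectors) and `truth`
#'   (data frame: one row per molecule with `marker_id`, `umi`,
#'   `true_length`, `family_size`).
#' @export
simulate_fastq <- function(config, sample_truth, seed = NULL, fastq = NULL,
                           sample_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  panel <- config$panel
  stopifnot(all(panel$marker_id %in% names(sample_truth)))
  n_mol <- .draw_n_families(config, config$n_markers)
  mol <- vector("list", config$n_markers)
  for (i in seq_len(config$n_markers)) {
    m <- n_mol[i]
    wl <- panel$wt_length[i]
    is_wt <- runif(m) < sample_truth[[panel$marker_id[i]]]
    pr <- .variant_length_probs(wl, config$contraction_bias)
    lens <- ifelse(is_wt, wl,
                   as.integer(sample(names(pr), m, replace = TRUE, prob = pr)))
    umi <- vapply(seq_len(m), function(j)
      paste(sample(c("A", "C", "G", "T"), config$umi_length, replace = TRUE),
            collapse = ""), "")
    fs <- 1L + rpois(m, config$mean_family_size - 1)
    mol[[i]] <- data.frame(marker_id = panel$marker_id[i], umi = umi,
                           true_length = as.integer(lens), family_size = fs,
                           stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, mol)
  # expand molecules to reads and apply per-read slippage
  ridx <- rep(seq_len(nrow(truth)), truth$family_size)
  rlen <- truth$true_length[ridx]
  slip <- runif(length(rlen)) < config$per_read_length_error
  dir <- ifelse(runif(length(rlen)) < config$contraction_bias, -1L, 1L)
  rlen[slip] <- pmax(0L, rlen[slip] + dir[slip])
  mi <- match(truth$marker_id[ridx], panel$marker_id)
  seqs <- paste0(truth$umi[ridx],
                 panel$left_flank[mi],
                 strrep(panel$repeat_unit[mi], rlen),
                 panel$right_flank[mi])
  nms <- sprintf("%s_r%06d", sample_id, seq_along(seqs))
  if (!is.null(fastq)) {
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- nms
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dss, fastq, format = "fastq",
                                qualities = qual,
                                compress = grepl("\\.gz$", fastq))
  }
  list(seqs = seqs, names = nms, truth = truth)
}
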