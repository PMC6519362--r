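# small hand-written 3-marker panel; flanks terminate the repeat run and are
# distinct enough that cross-marker anchoring is impossible
tiny_panel <- function() {
  marker_panel(
    marker_id = c("T1", "T2", "T3"),
    chrom = "chrT",
    start = c(100L, 200L, 300L),
    end = c(108L, 209L, 310L),
    repeat_unit = c("A", "T", "C"),
    wt_length = c(8L, 9L, 10L),
    left_flank = c("GGATCCGTTC", "ACCGATGCAG", "TTGAGCGATA"),
    right_flank = c("GTTCGGATCC", "CAGGCATCGA", "ATAGGTGCTA")
  )
}

# a synthetic read for one panel row: UMI + left flank + tract + right flank
make_read <- function(m, len, umi = "ACGTG") {
  paste0(umi, m$left_flank, strrep(m$repeat_unit, len), m$right_flank)
}

# minimal counts rows carrying just what the scorer needs
freq_counts <- function(sample_id, marker_id, freq, qc = TRUE) {
  data.frame(sample_id = sample_id, marker_id = marker_id,
             wt_frequency = freq, qc_pass = qc, stringsAsFactors = FALSE)
}

# a control cohort of pure Beta frequency draws for the given shape vectors
draw_control_cohort <- function(n, alpha0, beta0, marker_id,
                                prefix = "ctl") {
  do.call(rbind, lapply(seq_len(n), function(s)
    freq_counts(sprintf("%s%04d", prefix, s), marker_id,
                rbeta(length(alpha0), alpha0, beta0))))
}
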