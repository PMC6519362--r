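panel <- tiny_panel()

test_that("flank anchoring measures the tract between the anchors", {
  m <- panel[1, ]   # A8
  r_wt <- paste0(m$left_flank, strrep("A", 8), m$right_flank)
  a <- anchor_read(r_wt, panel)
  expect_equal(a$marker_id, "T1")
  expect_equal(a$observed_length, 8L)
  expect_equal(a$orientation, "+")

  # one repeat base deleted
  a7 <- anchor_read(paste0(m$left_flank, strrep("A", 7), m$right_flank), panel)
  expect_equal(a7$observed_length, 7L)

  # an interrupting substitution shortens the call (conservative convention)
  aint <- anchor_read(paste0(m$left_flank, "AAAGAAAA", m$right_flank), panel)
  expect_equal(aint$observed_length, 7L)

  # reverse-complement reads are recovered with orientation recorded
  arc <- anchor_read(msiscope:::revcomp(r_wt), panel)
  expect_equal(arc$marker_id, "T1")
  expect_equal(arc$observed_length, 8L)
  expect_equal(arc$orientation, "-")
})

test_that("anchoring honours the mismatch budget and uniqueness", {
  m <- panel[1, ]
  lf1 <- sub("^GG", "TG", m$left_flank)       # 1 substitution
  lf2 <- sub("^GGA", "TGC", m$left_flank)     # 2 substitutions
  tract <- strrep("A", 8)
  expect_equal(
    anchor_read(paste0(lf1, tract, m$right_flank), panel,
                max_mm = 1L)$observed_length, 8L)
  expect_null(anchor_read(paste0(lf2, tract, m$right_flank), panel,
                          max_mm = 1L))
  # anchors out of order
  expect_null(anchor_read(paste0(m$right_flank, tract, m$left_flank), panel))
  # a chimera matching two markers is ambiguous, hence no-match
  m2 <- panel[2, ]
  chimera <- paste0(m$left_flank, tract, m$right_flank,
                    m2$left_flank, strrep("T", 9), m2$right_flank)
  expect_null(anchor_read(chimera, panel))
  expect_error(anchor_reads("ACGTX", panel), class = "msi_input_error")
})

test_that("UMI extraction follows the configured scheme", {
  r5 <- extract_umi("ACGTGTTTTTT", umi_scheme = "read5:5")
  expect_equal(r5$umi, "ACGTG")
  expect_equal(r5$seq, "TTTTTT")
  expect_true(r5$ok)

  tag <- extract_umi("CCCC", names = "read1:UMI:GGAAC",
                     umi_scheme = "name:UMI")
  expect_equal(tag$umi, "GGAAC")
  expect_equal(tag$seq, "CCCC")   # sequence untouched

  short <- extract_umi("ACG", umi_scheme = "read5:5")
  expect_false(short$ok)
  expect_true(is.na(short$umi))

  expect_error(extract_umi("ACGT", umi_scheme = "bogus"),
               class = "msi_config_error")
})

test_that("families partition reads exactly by (marker, umi)", {
  anch <- data.frame(marker_id = c("T1", "T1", "T1"),
                     umi = c("X", "X", "Y"),
                     observed_length = c(8L, 8L, 7L),
                     stringsAsFactors = FALSE)
  fam <- build_families(anch)
  expect_equal(nrow(fam), 2L)
  expect_setequal(fam$family_size, c(2L, 1L))
  expect_equal(sum(fam$family_size), nrow(anch))
  empty <- build_families(anch[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("consensus calling is majority-vote with tie and size guards", {
  expect_equal(call_consensus(c(10L, 10L, 9L), 2L, 0.66), 10L)
  expect_true(is.na(call_consensus(c(10L, 9L), 2L, 0.66)))      # tie
  expect_true(is.na(call_consensus(8L, 2L, 0.66)))              # undersized
  expect_true(is.na(call_consensus(c(10L, 10L, 9L), 2L, 0.7)))  # 2/3 < 0.7
  expect_error(call_consensus(c(10L, 10L), 2L, 0.5),
               class = "msi_config_error")
})

test_that("sample tabulation applies the marker coverage QC", {
  fam <- build_families(data.frame(
    marker_id = rep(c("T1", "T2"), c(200, 10)),
    umi = sprintf("U%03d", 1:210),
    observed_length = rep(c(8L, 9L), c(200, 10)),
    stringsAsFactors = FALSE))
  cc <- tabulate_sample(fam, panel, "s1",
                        read_config(min_family_size = 1L,
                                    min_marker_families = 100L))
  cc <- cc[match(c("T1", "T2", "T3"), cc$marker_id), ]
  expect_true(cc$qc_pass[1])
  expect_false(cc$qc_pass[2])     # 10 families < 100
  expect_equal(cc$total_count[3], 0L)
  expect_equal(cc$wt_frequency[1], 1)
})

test_that("error-free simulated reads are assigned with 100% accuracy", {
  cfg <- sim_config(n_markers = 3L, panel = panel, mean_depth = 350,
                    depth_sd = 10, per_read_length_error = 0)
  set.seed(77)
  tr <- msiscope:::.draw_truth(cfg, "control")
  sim <- simulate_fastq(cfg, tr, seed = 78)
  expect_gt(length(sim$seqs), 1000L)
  um <- extract_umi(sim$seqs, sim$names, "read5:5")
  anch <- anchor_reads(um$seq, panel)
  expect_equal(nrow(anch), length(sim$seqs))
  truth_marker <- rep(sim$truth$marker_id, sim$truth$family_size)
  truth_len <- rep(sim$truth$true_length, sim$truth$family_size)
  expect_identical(anch$marker_id, truth_marker[anch$read])
  expect_identical(anch$observed_length, truth_len[anch$read])
})

test_that("read classes are conserved: anchored + no-match + umi-no-call = input", {
  cfg <- sim_config(n_markers = 3L, panel = panel, mean_depth = 200,
                    depth_sd = 10)
  set.seed(5)
  tr <- msiscope:::.draw_truth(cfg, "control")
  sim <- simulate_fastq(cfg, tr, seed = 6)
  # inject a too-short read (umi no-call) and a foreign read (no-match)
  seqs <- c(sim$seqs, "ACG", paste0("ACGTG", strrep("GATTACA", 6)))
  nms <- c(sim$names, "short", "foreign")
  res <- msiscope:::.process_reads(seqs, nms, "s1", panel,
                                   read_config(min_marker_families = 10L))
  expect_true(res$qc$conservation_ok)
  expect_equal(res$qc$n_umi_nocall, 1L)
  expect_equal(res$qc$n_no_match, 1L)
  expect_equal(res$qc$n_anchored + res$qc$n_no_match + res$qc$n_umi_nocall,
               length(seqs))
  # simulated molecule count matches distinct (marker, umi) pairs
  expect_equal(res$qc$n_families,
               nrow(unique(sim$truth[, c("marker_id", "umi")])))
})

test_that("FASTQ round trip through files matches in-memory processing", {
  cfg <- sim_config(n_markers = 3L, panel = panel, mean_depth = 200,
                    depth_sd = 10)
  set.seed(9)
  tr <- msiscope:::.draw_truth(cfg, "control")
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  sim <- simulate_fastq(cfg, tr, seed = 10, fastq = fq)
  res_file <- tabulate_fastq(fq, panel, "s1",
                             read_config(min_marker_families = 10L))
  res_mem <- msiscope:::.process_reads(sim$seqs, sim$names, "s1", panel,
                                       read_config(min_marker_families = 10L))
  expect_equal(res_file$counts, res_mem$counts, ignore_attr = TRUE)
})
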