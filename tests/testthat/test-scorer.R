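test_that("method-of-moments Beta fit matches the closed form", {
  # two-point sample engineered to have mean 0.9 and variance 0.009 exactly
  d <- sqrt(0.009 / 2)
  ab <- fit_beta(c(0.9 - d, 0.9 + d))
  expect_equal(unname(ab["alpha"]), 8.1, tolerance = 1e-9)
  expect_equal(unname(ab["beta"]), 0.9, tolerance = 1e-9)

  # frequencies symmetric about 0.5 give alpha == beta
  ab2 <- fit_beta(c(0.4, 0.6, 0.45, 0.55))
  expect_equal(unname(ab2["alpha"]), unname(ab2["beta"]), tolerance = 1e-6)

  expect_error(fit_beta(rep(0.9, 5)),
               class = "msi_degenerate_variance_error")
  expect_error(fit_beta(c(0.02, 0.98)),   # variance exceeds m(1-m)
               class = "msi_invalid_moments_error")
})

test_that("maximum-likelihood fitting recovers parameters on a large sample", {
  set.seed(42)
  x <- rbeta(5000, 60, 2)
  x <- msiscope:::clamp(x, 1e-6, 1 - 1e-6)
  ab <- fit_beta(x, method = "mle")
  expect_lt(abs(ab["alpha"] - 60) / 60, 0.1)
  expect_lt(abs(ab["beta"] - 2) / 2, 0.1)
})

test_that("control-model fitting trains per marker on qc-passing controls", {
  set.seed(1)
  cc <- draw_control_cohort(40, c(60, 30), c(2, 3), c("M1", "M2"))
  model <- fit_control_model(cc)
  expect_s3_class(model, "msi_control_model")
  expect_equal(model$markers$n_controls, c(40L, 40L))
  mu <- model$markers$alpha / (model$markers$alpha + model$markers$beta)
  expect_true(all(mu > 0.5))     # controls are predominantly WT
  # too few usable controls
  cc2 <- freq_counts("s1", "M1", 0.9)
  expect_error(fit_control_model(cc2), class = "msi_validation_error")
})

test_that("control model files round-trip including metadata", {
  set.seed(2)
  cc <- draw_control_cohort(20, c(60, 30), c(2, 3), c("M1", "M2"))
  model <- fit_control_model(cc, clamp_epsilon = 1e-6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_control_model(model, path)
  back <- read_control_model(path)
  expect_equal(back$markers$alpha, model$markers$alpha, tolerance = 1e-12)
  expect_equal(back$markers$beta, model$markers$beta, tolerance = 1e-12)
  expect_equal(back$fit_method, "moments")
  expect_equal(back$clamp_epsilon, 1e-6)
})

test_that("marker tail probability is the lower-tail Beta CDF", {
  model <- structure(list(
    markers = data.frame(marker_id = c("M1", "M2"),
                         alpha = c(8.1, 3), beta = c(0.9, 3),
                         n_controls = 40L, stringsAsFactors = FALSE),
    fit_method = "moments", clamp_epsilon = 1e-6),
    class = "msi_control_model")
  # support maximum
  expect_equal(marker_tail_probability(model, "M1", 1), 1)
  # symmetry at alpha == beta
  expect_equal(marker_tail_probability(model, "M2", 0.5), 0.5,
               tolerance = 1e-9)
  # against a trapezoid integration of the density (h = 1e-6, frozen)
  expect_equal(marker_tail_probability(model, "M1", 0.5),
               0.00291983775575427, tolerance = 1e-6)
  # lower WT frequency => smaller probability
  p <- marker_tail_probability(model, "M1", c(0.9, 0.7, 0.5))
  expect_true(all(diff(p) < 0))
  expect_error(marker_tail_probability(model, "NOPE", 0.5),
               class = "msi_key_error")
  expect_error(marker_tail_probability(model, "M1", 1.5),
               class = "msi_domain_error")
})

test_that("empirical-rank mode gives the add-one rank probability", {
  cc <- freq_counts(sprintf("s%d", 1:9), "M1", seq(0.91, 0.99, by = 0.01))
  model <- fit_control_model(cc)
  expect_equal(marker_tail_probability(model, "M1", 0.5, mode = "empirical"),
               1 / 10)
  expect_equal(marker_tail_probability(model, "M1", 1, mode = "empirical"),
               1)   # 10/10 after clamping to 1 - eps... all controls below
})

test_that("Fisher combination matches its chi-square identities", {
  f1 <- fisher_combine(rep(1, 24))
  expect_equal(f1$statistic, 0)
  expect_equal(f1$p, 1)
  # k = 1: Fisher returns the input probability exactly
  expect_equal(fisher_combine(0.05)$p, 0.05, tolerance = 1e-12)
  # 24 p-values of 0.5; survival checked against the Erlang series oracle
  f24 <- fisher_combine(rep(0.5, 24))
  expect_equal(f24$statistic, 48 * log(2), tolerance = 1e-10)
  expect_equal(f24$df, 48L)
  expect_equal(f24$p, 0.947620951136264, tolerance = 1e-9)
  expect_error(fisher_combine(numeric(0)), class = "msi_no_markers_error")
  expect_error(fisher_combine(c(0.5, 0)), class = "msi_domain_error")
})

test_that("the score transform and thresholds reproduce the 5%/1% identities", {
  expect_equal(round(score_from_probability(0.05), 2), 1.30)
  expect_equal(round(score_from_probability(0.01), 2), 2.00)
  expect_equal(score_from_probability(1), 0)
  expect_error(score_from_probability(0), class = "msi_domain_error")
  expect_error(score_from_probability(1.2), class = "msi_domain_error")

  # a CMMRD sample at the bottom of the published range, and the top control
  c159 <- classify(1.59)
  expect_true(c159$call_lenient); expect_false(c159$call_conservative)
  c147 <- classify(1.47)
  expect_true(c147$call_lenient); expect_false(c147$call_conservative)
  c0 <- classify(0)
  expect_false(c0$call_lenient); expect_false(c0$call_conservative)
  # thresholds are inclusive
  c2 <- classify(2.00)
  expect_true(c2$call_lenient); expect_true(c2$call_conservative)
})

test_that("sample scoring composes tails, Fisher and classification", {
  set.seed(3)
  mk <- sprintf("M%02d", 1:24)
  model <- fit_control_model(draw_control_cohort(40, rep(60, 24), rep(2, 24), mk))
  # all-WT sample: every tail probability is 1, score 0
  s0 <- score_sample(model, freq_counts("clean", mk, rep(1, 24)))
  expect_equal(s0$score, 0)
  expect_equal(s0$k, 24L)
  expect_false(s0$call_lenient); expect_false(s0$call_conservative)

  # one marker failing QC: k and degrees of freedom shrink, no imputation
  qc <- rep(TRUE, 24); qc[7] <- FALSE
  s23 <- score_sample(model, freq_counts("holey", mk, rep(0.95, 24), qc))
  expect_equal(s23$k, 23L)
  expect_equal(s23$df, 46L)
  expect_equal(s23$markers$exclusion_reason[7], "qc_fail")

  # marker order is irrelevant
  cc <- freq_counts("perm", mk, seq(0.8, 0.99, length.out = 24))
  perm <- sample(24)
  expect_equal(score_sample(model, cc[perm, ])$score,
               score_sample(model, cc)$score, tolerance = 1e-12)

  # depressed frequencies raise the score
  slow <- score_sample(model, freq_counts("msi", mk, rep(0.75, 24)))
  expect_gt(slow$score, 2)
  expect_true(slow$call_conservative)

  expect_error(score_sample(model, freq_counts("none", mk, rep(0.9, 24),
                                               qc = FALSE)),
               class = "msi_unscorable_sample_error")
})

test_that("score is calibrated against the generative model at large training n", {
  # with ample training data the fraction of control-model samples at or
  # above the 5% / 1% thresholds converges to 0.05 / 0.01
  set.seed(8)
  mk <- sprintf("M%02d", 1:24)
  a0 <- rep(60, 24); b0 <- rep(2, 24)
  model <- fit_control_model(draw_control_cohort(3000, a0, b0, mk))
  n <- 4000
  freq <- matrix(rbeta(n * 24, rep(a0, each = n), rep(b0, each = n)), n, 24)
  P <- vapply(seq_len(24),
              function(j) marker_tail_probability(model, mk[j], freq[, j]),
              numeric(n))
  sc <- apply(P, 1, function(p) score_from_probability(fisher_combine(p)$p))
  expect_lt(abs(mean(sc >= 1.30) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_lt(abs(mean(sc >= 2.00) - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})
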