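#' Fit the per-marker Beta control model
#'
#' For each marker, the distribution of wild-type (WT) read frequencies
#' across a control cohort is modelled with a Beta distribution. Frequencies
#' are clamped into `[eps, 1 - eps]` before fitting because observed
#' frequencies of exactly 1 are common in controls and the Beta log-density
#' is unbounded at the support boundary.
#'
#' Method of moments (default): with sample mean `m` and sample variance `v`,
#' `c = m(1 - m)/v - 1`, `alpha = m c`, `beta = (1 - m) c`. Maximum
#' likelihood: numerical optimisation of the Beta log-likelihood initialised
#' at the moments estimate.
#'
#' @param control_counts long counts table covering the control cohort
#'   (columns as [read_counts_table()]); only `qc_pass` rows train.
#' @param fit_method `"moments"` (closed-form, default) or `"mle"`.
#' @param clamp_epsilon boundary offset for frequency clamping (default 1e-6).
#' @param min_controls minimum usable controls per marker (default 2).
#' @param on_degenerate what to do with a marker whose control frequencies
#'   are all identical (no variance to fit, typical for near-monomorphic
#'   markers at low coverage): `"error"` (default) aborts naming the marker;
#'   `"drop"` excludes it from the model with a warning, so scoring proceeds
#'   on the remaining markers with reduced degrees of freedom.
#' @return A `msi_control_model`: data frame `markers` (marker_id, alpha,
#'   beta, n_controls) plus fit metadata.
#' @export
fit_control_model <- function(control_counts,
                              fit_method = c("moments", "mle"),
                              clamp_epsilon = 1e-6,
                              min_controls = 2L,
                              on_degenerate = c("error", "drop")) {
  fit_method <- match.arg(fit_method)
  on_degenerate <- match.arg(on_degenerate)
  markers <- unique(control_counts$marker_id)
  rows <- lapply(markers, function(mk) {
    x <- control_counts[control_counts$marker_id == mk &
                        control_counts$qc_pass &
                        !is.na(control_counts$wt_frequency), "wt_frequency"]
    if (length(x) < min_controls)
      stop_msi("marker '%s': only %d usable control(s), need >= %d",
               mk, length(x), min_controls, class = "msi_validation_error")
    x <- clamp(x, clamp_epsilon, 1 - clamp_epsilon)
    ab <- if (on_degenerate == "drop") {
      tryCatch(fit_beta(x, method = fit_method, marker_id = mk),
               msi_degenerate_variance_error = function(e) {
                 warning("dropping unmodellable marker '", mk, "': ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    } else {
      fit_beta(x, method = fit_method, marker_id = mk)
    }
    if (is.null(ab)) return(NULL)
    list(row = data.frame(marker_id = mk, alpha = ab[["alpha"]],
                          beta = ab[["beta"]], n_controls = length(x),
                          stringsAsFactors = FALSE),
         freqs = x)
  })
  keep <- !vapply(rows, is.null, TRUE)
  rows <- rows[keep]
  if (!length(rows))
    stop_msi("no marker could be modelled", class = "msi_validation_error")
  training <- lapply(rows, `[[`, "freqs")
  names(training) <- markers[keep]
  structure(list(markers = do.call(rbind, lapply(rows, `[[`, "row")),
                 fit_method = fit_method,
                 clamp_epsilon = clamp_epsilon,
                 training = training),
            class = "msi_control_model")
}

#' Fit a Beta distribution to frequencies
#'
#' @param x numeric vector in (0, 1), already clamped away from {0, 1}.
#' @param method `"moments"` or `"mle"`.
#' @param marker_id label used in error messages.
#' @return Named vector `c(alpha=, beta=)`, both > 0.
#' @export
fit_beta <- function(x, method = c("moments", "mle"), marker_id = "?") {
  method <- match.arg(method)
  m <- mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0)
    stop_msi("marker '%s': degenerate variance (all control frequencies identical)",
             marker_id, class = "msi_degenerate_variance_error")
  cc <- m * (1 - m) / v - 1
  if (cc <= 0)
    stop_msi("marker '%s': invalid moments (variance >= m(1-m))",
             marker_id, class = "msi_invalid_moments_error")
  mom <- c(alpha = m * cc, beta = (1 - m) * cc)
  if (method == "moments") return(mom)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  opt <- optim(log(mom), nll, method = "Nelder-Mead")
  c(alpha = unname(exp(opt$par[1])), beta = unname(exp(opt$par[2])))
}

#' @export
print.msi_control_model <- function(x, ...) {
  cat(sprintf("msi control model: %d markers, fit=%s, eps=%g\n",
              nrow(x$markers), x$fit_method, x$clamp_epsilon))
  mu <- x$markers$alpha / (x$markers$alpha + x$markers$beta)
  cat(sprintf("  fitted mean WT frequency: %.4f - %.4f\n", min(mu), max(mu)))
  invisible(x)
}

#' Write / read a control model file
#'
#' TSV with columns marker_id, alpha, beta, n_controls, preceded by a single
#' `#`-prefixed JSON metadata header carrying the fit method and clamp
#' epsilon. Round-trips exactly.
#'
#' @param model an `msi_control_model`.
#' @param path file path.
#' @return `write_control_model()`: the path, invisibly;
#'   `read_control_model()`: the model.
#' @export
write_control_model <- function(model, path) {
  meta <- jsonlite::toJSON(list(format = "msiscope_control_model",
                                version = as.character(packageVersion("msiscope")),
                                fit_method = model$fit_method,
                                clamp_epsilon = model$clamp_epsilon),
                           auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  df <- model$markers
  df$alpha <- sprintf("%.15g", df$alpha)
  df$beta <- sprintf("%.15g", df$beta)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop_msi("'%s' lacks the model metadata header", path,
             class = "msi_parse_error")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$alpha <- as.numeric(df$alpha)
  df$beta <- as.numeric(df$beta)
  structure(list(markers = df,
                 fit_method = meta$fit_method,
                 clamp_epsilon = meta$clamp_epsilon),
            class = "msi_control_model")
}

#' Per-marker lower-tail probability of an observed WT frequency
#'
#' The probability that a control draw from the marker's fitted Beta is at or
#' below the observed frequency — the lower-tail Beta CDF at the (clamped)
#' observation. A depressed WT frequency therefore yields a small
#' probability. Results are clamped to `[1e-300, 1]` so logarithms stay
#' finite downstream.
#'
#' @param model fitted `msi_control_model`.
#' @param marker_id marker to look up.
#' @param observed_frequency WT frequency in `[0, 1]` (vectorised).
#' @param mode `"beta"` (default) uses the fitted continuous CDF;
#'   `"empirical"` uses the add-one empirical rank against the stored
#'   training frequencies, `(#{controls <= obs} + 1) / (n + 1)`, as a
#'   distribution-free cross-check (only available on freshly fitted models,
#'   not ones re-read from disk).
#' @return Probability vector in `[1e-300, 1]`.
#' @export
marker_tail_probability <- function(model, marker_id, observed_frequency,
                                    mode = c("beta", "empirical")) {
  mode <- match.arg(mode)
  i <- match(marker_id, model$markers$marker_id)
  if (is.na(i))
    stop_msi("marker '%s' not in control model", marker_id,
             class = "msi_key_error")
  if (any(observed_frequency < 0 | observed_frequency > 1, na.rm = TRUE))
    stop_msi("observed_frequency outside [0, 1]", class = "msi_domain_error")
  eps <- model$clamp_epsilon %||% 1e-6
  x <- clamp(observed_frequency, eps, 1 - eps)
  if (mode == "empirical") {
    tr <- model$training[[marker_id]]
    if (is.null(tr))
      stop_msi("model carries no training frequencies for empirical mode",
               class = "msi_config_error")
    p <- vapply(x, function(xx) (sum(tr <= xx) + 1) / (length(tr) + 1), 1)
  } else {
    p <- pbeta(x, model$markers$alpha[i], model$markers$beta[i])
    # frequencies at the support maximum must give p = 1 exactly
    p[observed_frequency >= 1 - eps] <- 1
  }
  clamp(p, 1e-300, 1)
}

#' Combine p-values with Fisher's method
#'
#' `X^2 = -2 sum(log p_i)` referred to a chi-square distribution with `2k`
#' degrees of freedom; the combined probability is the upper tail at `X^2`.
#'
#' @param p probabilities in (0, 1], non-empty.
#' @return list with `statistic` (X^2), `df` (2k) and `p` (combined).
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L)
    stop_msi("no p-values to combine", class = "msi_no_markers_error")
  if (any(p <= 0 | p > 1))
    stop_msi("p-values must lie in (0, 1]", class = "msi_domain_error")
  x2 <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x2, df = 2L * k,
       p = clamp(pchisq(x2, df = 2 * k, lower.tail = FALSE), 1e-300, 1))
}

#' Transform a combined probability into the MSI score
#'
#' `score = -log10(p)`: a sample with 5% probability of coming from the
#' control population scores 1.30, and 1% scores 2.00. Full precision is
#' retained; reports round to 2 decimals.
#'
#' @param combined_p probability in (0, 1] (vectorised).
#' @return Non-negative score.
#' @export
score_from_probability <- function(combined_p) {
  if (any(combined_p <= 0 | combined_p > 1))
    stop_msi("combined probability must lie in (0, 1]",
             class = "msi_domain_error")
  -log10(combined_p)
}

#' Classify a score against the diagnostic thresholds
#'
#' Thresholds are inclusive: a score at or above 1.30 (5% control
#' probability) is lenient-positive, at or above 2.00 (1%) is
#' conservative-positive.
#'
#' @param score non-negative score (vectorised).
#' @param threshold_5pct,threshold_1pct thresholds (defaults 1.30, 2.00).
#' @return list with logical `call_lenient` and `call_conservative`.
#' @export
classify <- function(score, threshold_5pct = 1.30, threshold_1pct = 2.00) {
  list(call_lenient = score >= threshold_5pct,
       call_conservative = score >= threshold_1pct)
}

#' Score one sample against the control model
#'
#' Pipeline: per-marker lower-tail probability at the observed WT frequency,
#' Fisher combination across the `k` included markers (those with `qc_pass`
#' and present in the model), score transform, threshold classification.
#' Excluded markers are listed with reasons and the chi-square degrees of
#' freedom are `2k` — exclusion adjusts the combination rather than imputing.
#'
#' @param model fitted `msi_control_model`.
#' @param sample_counts counts rows for one sample.
#' @param threshold_5pct,threshold_1pct classification thresholds.
#' @return An `msi_sample_score` list: `sample_id`, per-marker data frame
#'   (`marker_id`, `wt_frequency`, `p`, `included`, `exclusion_reason`), `k`,
#'   `fisher_statistic`, `df`, `combined_p`, `score`, `call_lenient`,
#'   `call_conservative`.
#' @export
score_sample <- function(model, sample_counts,
                         threshold_5pct = 1.30, threshold_1pct = 2.00) {
  sid <- unique(sample_counts$sample_id)
  if (length(sid) != 1L)
    stop_msi("score_sample() expects counts for exactly one sample",
             class = "msi_validation_error")
  in_model <- sample_counts$marker_id %in% model$markers$marker_id
  usable <- in_model & sample_counts$qc_pass &
    !is.na(sample_counts$wt_frequency)
  reason <- rep(NA_character_, nrow(sample_counts))
  reason[!in_model] <- "not_in_model"
  reason[in_model & !sample_counts$qc_pass] <- "qc_fail"
  reason[in_model & sample_counts$qc_pass &
           is.na(sample_counts$wt_frequency)] <- "no_coverage"
  if (!any(usable))
    stop_msi("sample '%s': no scoreable markers", sid,
             class = "msi_unscorable_sample_error")
  pm <- rep(NA_real_, nrow(sample_counts))
  for (j in which(usable))
    pm[j] <- marker_tail_probability(model, sample_counts$marker_id[j],
                                     sample_counts$wt_frequency[j])
  fc <- fisher_combine(pm[usable])
  score <- score_from_probability(fc$p)
  calls <- classify(score, threshold_5pct, threshold_1pct)
  structure(list(
    sample_id = sid,
    markers = data.frame(marker_id = sample_counts$marker_id,
                         wt_frequency = sample_counts$wt_frequency,
                         p = pm, included = usable,
                         exclusion_reason = reason,
                         stringsAsFactors = FALSE),
    k = sum(usable),
    fisher_statistic = fc$statistic,
    df = fc$df,
    combined_p = fc$p,
    score = score,
    call_lenient = calls$call_lenient,
    call_conservative = calls$call_conservative,
    thresholds = c(lenient = threshold_5pct, conservative = threshold_1pct)
  ), class = "msi_sample_score")
}

#' @export
print.msi_sample_score <- function(x, ...) {
  cat(sprintf("%s: score %.2f (p = %.3g, k = %d markers, X2 = %.2f, df = %d)\n",
              x$sample_id, x$score, x$combined_p, x$k,
              x$fisher_statistic, x$df))
  cat(sprintf("  call at %.2f (5%%): %s;  call at %.2f (1%%): %s\n",
              x$thresholds["lenient"],
              if (x$call_lenient) "POSITIVE" else "negative",
              x$thresholds["conservative"],
              if (x$call_conservative) "POSITIVE" else "negative"))
  invisible(x)
}

#' Score every sample in a counts table
#'
#' @param model fitted `msi_control_model`.
#' @param counts long counts table (any number of samples).
#' @param ... passed to [score_sample()].
#' @return list with `report` (one row per sample: sample_id, k,
#'   fisher_statistic, combined_p, score, call_1.30, call_2.00) and `detail`
#'   (long per-marker data frame).
#' @export
score_cohort <- function(model, counts, ...) {
  samples <- unique(counts$sample_id)
  scored <- lapply(samples, function(s)
    score_sample(model, counts[counts$sample_id == s, , drop = FALSE], ...))
  report <- data.frame(
    sample_id = samples,
    k = vapply(scored, `[[`, 1L, "k"),
    fisher_statistic = vapply(scored, `[[`, 1, "fisher_statistic"),
    combined_p = vapply(scored, `[[`, 1, "combined_p"),
    score = vapply(scored, `[[`, 1, "score"),
    call_1.30 = vapply(scored, `[[`, TRUE, "call_lenient"),
    call_2.00 = vapply(scored, `[[`, TRUE, "call_conservative"),
    stringsAsFactors = FALSE)
  detail <- do.call(rbind, lapply(scored, function(s)
    cbind(sample_id = s$sample_id, s$markers, stringsAsFactors = FALSE)))
  list(report = report, detail = detail)
}

#' Write / read a score report
#'
#' Tab-delimited, one row per sample, scores rounded to 2 decimals in the
#' file (full precision is available from [score_cohort()]).
#'
#' @param report report data frame from [score_cohort()].
#' @param path file path.
#' @export
write_score_report <- function(report, path) {
  out <- report
  out$score <- sprintf("%.2f", out$score)
  out$fisher_statistic <- sprintf("%.4f", out$fisher_statistic)
  out$combined_p <- sprintf("%.6g", out$combined_p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_report
#' @export
read_score_report <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$score <- as.numeric(df$score)
  df
}
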