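# Sample-level array quality control.
#
# Two gates, applied to every genotyped sample:
#   1. minimum genotyping call rate (default 0.95);
#   2. per-sample LRR s.d. and BAF s.d. within mean +/- k s.d. of the full
#      cohort (default k = 3, sample s.d. with n-1 denominator).
# Values exactly at a bound pass ("within" is read inclusively). Bounds are
# computed once on the full cohort, including samples that fail the
# call-rate gate.

#' QC thresholds
#'
#' @param min_call_rate Minimum genotyping call rate in (0, 1\]; default 0.95.
#' @param sd_multiplier Width of the cohort noise-metric band in s.d. units;
#'   default 3.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, sd_multiplier = 3.0) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1, sd_multiplier > 0)
  structure(list(min_call_rate = min_call_rate,
                 sd_multiplier = sd_multiplier),
            class = "qc_thresholds")
}

#' Cohort bounds for the array noise metrics
#'
#' For each of `lrr_sd` and `baf_sd`, computes cohort mean plus/minus
#' `sd_multiplier` times the cohort sample standard deviation.
#'
#' @param metrics QC metrics table (sample, call_rate, lrr_sd, baf_sd).
#' @param sd_multiplier Band width in s.d. units.
#' @return A list with elements `lrr_sd` and `baf_sd`, each `c(lower, upper)`.
#' @export
cohort_metric_bounds <- function(metrics, sd_multiplier = 3.0) {
  if (nrow(metrics) < 2) {
    stop("cohort bounds need at least 2 samples (s.d. undefined)")
  }
  one <- function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    c(lower = m - sd_multiplier * s, upper = m + sd_multiplier * s)
  }
  list(lrr_sd = one(metrics$lrr_sd), baf_sd = one(metrics$baf_sd))
}

#' Filter samples on the QC gates
#'
#' A sample passes iff call_rate >= min_call_rate AND both noise metrics lie
#' inside the cohort bounds (inclusive). The exclusion report names the
#' first failed gate per excluded sample, in the fixed order call_rate,
#' lrr_sd, baf_sd.
#'
#' @param metrics QC metrics table.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list: `passing` (character vector of sample ids), `excluded`
#'   (data.frame sample/reason), `bounds` (the cohort bounds used).
#' @export
filter_samples <- function(metrics, thresholds = qc_thresholds()) {
  b <- cohort_metric_bounds(metrics, thresholds$sd_multiplier)
  fail_cr <- metrics$call_rate < thresholds$min_call_rate
  fail_lrr <- metrics$lrr_sd < b$lrr_sd["lower"] |
    metrics$lrr_sd > b$lrr_sd["upper"]
  fail_baf <- metrics$baf_sd < b$baf_sd["lower"] |
    metrics$baf_sd > b$baf_sd["upper"]
  reason <- rep(NA_character_, nrow(metrics))
  reason[fail_baf] <- "baf_sd"
  reason[fail_lrr] <- "lrr_sd"
  reason[fail_cr] <- "call_rate"
  list(passing = metrics$sample[is.na(reason)],
       excluded = data.frame(sample = metrics$sample[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE),
       bounds = b)
}
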