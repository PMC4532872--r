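# Rare-variant filtering.
#
# Four gates, all evaluated for every call (no short-circuit) so the audit
# trail is complete; a call survives iff it passes all of them:
#   size      — strictly greater than min_size_bp (default 10 kb)
#   probes    — at least min_probes supporting probes (default 5)
#   stable    — coverage by copy-number-stable regions strictly greater
#               than min_stable_coverage (default 0.75)
#   frequency — carrier frequency strictly below max_control_freq (default
#               0.1%) in EVERY control cohort, at min_ro reciprocal overlap
# Carrier counting is per control sample, not per call, so a fragmented
# control event is never double-counted. With a 2,988-sample primary cohort
# the 0.1% gate means at most 2 carriers.

#' Build a frequency-queryable control cohort index
#'
#' @param calls Control CNV call table (internal coordinates). The `caller`
#'   column is ignored; control sets are taken as published call lists.
#' @param n_samples Number of samples in the cohort (the frequency
#'   denominator), >= 1.
#' @param name Cohort name used in audits.
#' @return An object of class `control_cohort_index`.
#' @export
control_cohort_index <- function(calls, n_samples, name = "controls") {
  stopifnot(is.numeric(n_samples), n_samples >= 1)
  idx <- split(calls[, c("sample", "chrom", "start", "end", "type")],
               paste(calls$chrom, calls$type, sep = "\r"))
  structure(list(cohort_name = name, n_samples = as.integer(n_samples),
                 index = idx),
            class = "control_cohort_index")
}

#' @export
print.control_cohort_index <- function(x, ...) {
  cat("Control cohort '", x$cohort_name, "': ", x$n_samples, " samples, ",
      sum(vapply(x$index, nrow, integer(1))), " calls\n", sep = "")
  invisible(x)
}

#' Control carrier count and frequency for one call
#'
#' Counts the distinct control samples having at least one call of the same
#' type with reciprocal overlap >= `min_ro` against the query.
#'
#' @param call Single-row consensus (or call) table.
#' @param cohort A [control_cohort_index()].
#' @param min_ro Reciprocal-overlap threshold (default 0.5).
#' @return List with `carrier_count` and `frequency`
#'   (`carrier_count / n_samples`).
#' @export
control_frequency <- function(call, cohort, min_ro = 0.5) {
  stopifnot(nrow(call) == 1, inherits(cohort, "control_cohort_index"))
  cc <- cohort$index[[paste(call$chrom, call$type, sep = "\r")]]
  carriers <- 0L
  if (!is.null(cc) && nrow(cc) > 0) {
    ov <- pmax(0, pmin(cc$end, call$end) - pmax(cc$start, call$start))
    ro <- ov / pmax(cc$end - cc$start, call$end - call$start)
    carriers <- length(unique(cc$sample[ro >= min_ro]))
  }
  list(carrier_count = carriers, frequency = carriers / cohort$n_samples)
}

#' Rare-filter configuration
#'
#' @param max_control_freq Frequency above which a variant is considered
#'   polymorphic (strict upper bound, default 0.001 = 0.1%).
#' @param min_ro_vs_controls Reciprocal overlap at which a control call
#'   counts as the same variant (default 0.5).
#' @param min_stable_coverage Required stable-region coverage (strict lower
#'   bound, default 0.75).
#' @param min_probes Minimum supporting probes (inclusive, default 5).
#' @param min_size_bp Minimum size in bp (strict lower bound, default 10000).
#' @return A list of class `rare_filter_config`.
#' @export
rare_filter_config <- function(max_control_freq = 0.001,
                               min_ro_vs_controls = 0.5,
                               min_stable_coverage = 0.75,
                               min_probes = 5L, min_size_bp = 10000L) {
  stopifnot(max_control_freq > 0, max_control_freq <= 1,
            min_ro_vs_controls > 0, min_ro_vs_controls <= 1,
            min_stable_coverage > 0, min_stable_coverage <= 1,
            min_probes >= 1, min_size_bp >= 1)
  structure(list(max_control_freq = max_control_freq,
                 min_ro_vs_controls = min_ro_vs_controls,
                 min_stable_coverage = min_stable_coverage,
                 min_probes = as.integer(min_probes),
                 min_size_bp = as.numeric(min_size_bp)),
            class = "rare_filter_config")
}

#' Apply the rare-variant gates with a full audit trail
#'
#' @param calls Consensus call table (any samples).
#' @param cohorts Non-empty list of [control_cohort_index()] objects; a call
#'   must be rare in every cohort.
#' @param stable_regions Copy-number-stable region table (BED-like).
#' @param probes Probe map.
#' @param config A [rare_filter_config()].
#' @return A list: `survivors` (subset of `calls`, with a `filter_audit`
#'   summary column) and `audit` (one row per call x gate with the measured
#'   value, threshold and verdict; the frequency row reports the worst — that
#'   is, highest — cohort frequency, and per-cohort carrier counts appear in
#'   `audit_frequency`).
#' @export
apply_rare_filters <- function(calls, cohorts, stable_regions, probes,
                               config = rare_filter_config()) {
  if (length(cohorts) == 0) {
    stop("rare filtering needs at least one control cohort (frequency gate cannot be evaluated)")
  }
  stopifnot(all(vapply(cohorts, inherits, logical(1),
                       "control_cohort_index")))
  n <- nrow(calls)
  size <- calls$end - calls$start
  nprobe <- vapply(seq_len(n), function(i)
    count_probes(calls[i, ], probes), integer(1))
  stable <- vapply(seq_len(n), function(i)
    coverage_fraction(calls[i, ], stable_regions), numeric(1))
  freq_by_cohort <- lapply(cohorts, function(co) {
    vapply(seq_len(n), function(i) {
      cf <- control_frequency(calls[i, ], co, config$min_ro_vs_controls)
      c(cf$carrier_count, cf$frequency)
    }, numeric(2))
  })
  worst_freq <- if (n == 0) numeric(0) else {
    do.call(pmax, lapply(freq_by_cohort, function(m) m[2, ]))
  }

  pass_size <- size > config$min_size_bp
  pass_probes <- nprobe >= config$min_probes
  pass_stable <- stable > config$min_stable_coverage
  pass_freq <- worst_freq < config$max_control_freq

  call_id <- paste0(calls$sample, ":", calls$chrom, ":", calls$start, "-",
                    calls$end, ":", calls$type)
  gate_row <- function(gate, value, threshold, pass) {
    data.frame(call_id = call_id, gate = gate, value = value,
               threshold = threshold, pass = pass, stringsAsFactors = FALSE)
  }
  audit <- rbind(
    gate_row("size", size, config$min_size_bp, pass_size),
    gate_row("probes", nprobe, config$min_probes, pass_probes),
    gate_row("stable", stable, config$min_stable_coverage, pass_stable),
    gate_row("frequency", worst_freq, config$max_control_freq, pass_freq))
  audit <- audit[order(audit$call_id,
                       match(audit$gate,
                             c("size", "probes", "stable", "frequency"))), ,
                 drop = FALSE]
  rownames(audit) <- NULL

  audit_frequency <- do.call(rbind, lapply(seq_along(cohorts), function(k) {
    data.frame(call_id = call_id,
               cohort = cohorts[[k]]$cohort_name,
               n_samples = cohorts[[k]]$n_samples,
               carrier_count = if (n == 0) integer(0) else freq_by_cohort[[k]][1, ],
               frequency = if (n == 0) numeric(0) else freq_by_cohort[[k]][2, ],
               stringsAsFactors = FALSE)
  }))

  keep <- pass_size & pass_probes & pass_stable & pass_freq
  survivors <- calls[keep, , drop = FALSE]
  survivors$n_probes_measured <- nprobe[keep]
  survivors$filter_audit <- sprintf(
    "size=%.0f;probes=%d;stable=%.3f;max_ctrl_freq=%.5f",
    size[keep], nprobe[keep], stable[keep], worst_freq[keep])
  rownames(survivors) <- NULL
  list(survivors = survivors, audit = audit,
       audit_frequency = audit_frequency)
}
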