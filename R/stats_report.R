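# Cohort-level statistics: severity association, burden comparison,
# percentage reporting.

#' Dichotomize a GMFCS level
#'
#' Gross Motor Function Classification System levels I-III are grouped as
#' mild-moderate and IV-V as severe; "unknown" propagates and is excluded
#' from contingency tables downstream.
#'
#' @param level Character vector of levels among I, II, III, IV, V, unknown.
#' @return Character vector over {mild_moderate, severe, unknown}.
#' @export
dichotomize_gmfcs <- function(level) {
  map <- c(I = "mild_moderate", II = "mild_moderate", III = "mild_moderate",
           IV = "severe", V = "severe", unknown = "unknown")
  out <- map[as.character(level)]
  if (any(is.na(out))) {
    stop("unrecognized GMFCS level: ",
         paste(unique(level[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass method (the convention of
#' mainstream statistical software): the sum of hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table, the comparison made with relative tolerance
#' 1e-7 to absorb floating-point ties. Computed by full enumeration over the
#' feasible range of the top-left cell.
#'
#' @param a,b,c,d Non-negative integer cells: a = exposed with outcome,
#'   b = exposed without, c = unexposed with outcome, d = unexposed without.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return The two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact_two_sided(3, 22, 1, 77)  # ~0.0434
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table: test undefined")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- sum(cells)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- probs[x == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Classical two-sample t with df = n1 + n2 - 2 and two-sided p. Degenerate
#' input with zero pooled variance yields p = 1 when the means agree and an
#' error otherwise (the statistic is undefined).
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and `p`.
#' @export
burden_t_test <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) / df
  delta <- mean(group1) - mean(group2)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Format a rate as a printed percentage
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal and
#' rendered as "X.Y%".
#'
#' @param numerator,denominator Integers with
#'   `0 <= numerator <= denominator`, `denominator >= 1`.
#' @return A string such as "7.0%".
#' @examples
#' rate_report(8, 115)
#' @export
rate_report <- function(numerator, denominator) {
  if (denominator < 1) stop("denominator must be >= 1")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  pct <- 100 * numerator / denominator
  sprintf("%.1f%%", floor(pct * 10 + 0.5 + 1e-9) / 10)
}

#' Build the severity-by-carrier 2x2 table
#'
#' Exposure: the proband carries at least one de novo event of size at least
#' `large_cnv_bp`. Outcome: severe motor impairment (GMFCS IV-V). Probands
#' with unknown GMFCS are excluded. Cell layout matches
#' [fisher_exact_two_sided()]: a = severe carriers, b = severe non-carriers,
#' c = mild-moderate carriers, d = mild-moderate non-carriers.
#'
#' @param verdicts Verdict-bearing variant table (needs `sample`,
#'   `inheritance`, `start`, `end`).
#' @param phenotypes Phenotype table (sample, gmfcs); its samples define the
#'   probands considered.
#' @param large_cnv_bp Size threshold for a "large" de novo event (default
#'   5 Mb).
#' @return List: `table` (named a, b, c, d), `carriers` (sample ids),
#'   `n_phenotyped`.
#' @export
build_severity_table <- function(verdicts, phenotypes, large_cnv_bp = 5e6) {
  sev <- dichotomize_gmfcs(phenotypes$gmfcs)
  keep <- sev != "unknown"
  samples <- phenotypes$sample[keep]
  sev <- sev[keep]
  big_dn <- verdicts$inheritance == "de_novo" &
    (verdicts$end - verdicts$start) >= large_cnv_bp
  carriers <- unique(verdicts$sample[big_dn])
  exposed <- samples %in% carriers
  list(table = c(a = sum(exposed & sev == "severe"),
                 b = sum(!exposed & sev == "severe"),
                 c = sum(exposed & sev == "mild_moderate"),
                 d = sum(!exposed & sev == "mild_moderate")),
       carriers = intersect(carriers, samples),
       n_phenotyped = length(samples))
}

#' Assemble the cohort report
#'
#' Headline rates (trio-level), the severity 2x2 table with its Fisher
#' p-value, and the proband-versus-parent burden t-tests on per-sample call
#' count and mean call size.
#'
#' @param verdicts Classified variant table (post [classify_variants()]).
#' @param trios Trio table for the denominator.
#' @param phenotypes Phenotype table.
#' @param consensus All-sample consensus table (for the burden comparison).
#' @param large_cnv_bp "Large CNV" threshold (default 5 Mb).
#' @return List of class `triocnv_report` with elements `n_trios`,
#'   `de_novo` (summary), `rates` (named character), `severity` (table,
#'   fisher p), `burden` (t-tests or NULL when either group is too small).
#' @export
cohort_report <- function(verdicts, trios, phenotypes, consensus = NULL,
                          large_cnv_bp = 5e6) {
  n_trios <- nrow(trios)
  dn <- de_novo_summary(verdicts, trios)
  reported <- verdicts$tier %in% c("pathogenic", "likely_pathogenic", "vus")
  n_reportable_trios <- length(unique(verdicts$family_id[reported]))
  inh <- verdicts$inheritance %in% c("maternal", "paternal", "biparental")
  n_inherited_trios <- length(unique(verdicts$family_id[inh & reported]))
  big_dn <- verdicts$inheritance == "de_novo" &
    (verdicts$end - verdicts$start) >= large_cnv_bp
  n_large_dn_trios <- length(unique(verdicts$family_id[big_dn]))

  sev <- build_severity_table(verdicts, phenotypes, large_cnv_bp)
  fisher_p <- if (sum(sev$table) > 0) {
    fisher_exact_two_sided(sev$table["a"], sev$table["b"],
                           sev$table["c"], sev$table["d"])
  } else NA_real_

  burden <- NULL
  if (!is.null(consensus) && nrow(consensus) > 0) {
    is_child <- consensus$sample %in% trios$child_id
    is_parent <- consensus$sample %in% c(trios$father_id, trios$mother_id)
    per_sample <- function(keep) {
      s <- consensus[keep, , drop = FALSE]
      list(count = as.numeric(table(s$sample)),
           mean_size = as.numeric(tapply(s$end - s$start, s$sample, mean)))
    }
    ch <- per_sample(is_child); pa <- per_sample(is_parent)
    if (length(ch$count) >= 2 && length(pa$count) >= 2) {
      burden <- list(
        n_calls = burden_t_test(ch$count, pa$count),
        mean_size = burden_t_test(ch$mean_size, pa$mean_size))
    }
  }

  structure(list(
    n_trios = n_trios,
    de_novo = dn,
    counts = c(de_novo_trios = dn$n_trios_with_de_novo,
               reportable_trios = n_reportable_trios,
               inherited_reportable_trios = n_inherited_trios,
               large_de_novo_trios = n_large_dn_trios),
    rates = c(
      de_novo = rate_report(dn$n_trios_with_de_novo, max(n_trios, 1)),
      reportable = rate_report(n_reportable_trios, max(n_trios, 1)),
      inherited_reportable = rate_report(n_inherited_trios, max(n_trios, 1)),
      large_de_novo = rate_report(n_large_dn_trios, max(n_trios, 1))),
    severity = c(sev, list(fisher_p = fisher_p)),
    burden = burden), class = "triocnv_report")
}

#' @export
print.triocnv_report <- function(x, ...) {
  cat("Trio CNV cohort report\n")
  cat(sprintf("  complete trios analysed: %d\n", x$n_trios))
  cat(sprintf("  trios with >=1 de novo CNV: %d/%d (%s)\n",
              x$counts["de_novo_trios"], x$n_trios, x$rates["de_novo"]))
  cat(sprintf("  trios with reportable variants (non-benign tier): %d/%d (%s)\n",
              x$counts["reportable_trios"], x$n_trios, x$rates["reportable"]))
  cat(sprintf("  trios with reportable inherited variants: %d/%d (%s)\n",
              x$counts["inherited_reportable_trios"], x$n_trios,
              x$rates["inherited_reportable"]))
  cat(sprintf("  trios with large (>=5 Mb) de novo CNVs: %d/%d (%s)\n",
              x$counts["large_de_novo_trios"], x$n_trios,
              x$rates["large_de_novo"]))
  t <- x$severity$table
  cat(sprintf("  severity 2x2 (severe/mild x carrier/non): a=%d b=%d c=%d d=%d over %d phenotyped\n",
              t["a"], t["b"], t["c"], t["d"], x$severity$n_phenotyped))
  cat(sprintf("  Fisher two-sided p (large de novo vs severe GMFCS): %s\n",
              format(x$severity$fisher_p, digits = 3)))
  if (!is.null(x$burden)) {
    cat(sprintf("  burden t-tests (probands vs parents): calls p=%.3g, mean size p=%.3g\n",
                x$burden$n_calls$p, x$burden$mean_size$p))
  }
  invisible(x)
}
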