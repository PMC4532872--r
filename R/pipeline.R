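# End-to-end orchestration: qc -> stitch -> consensus -> rare filter ->
# trio inheritance -> clinical tiering -> cohort report.

#' Pipeline configuration
#'
#' Bundles every stage's tunables. The config serializes to a stable hash
#' recorded in all output headers, so reruns from the same inputs and config
#' are byte-identical.
#'
#' @param qc A [qc_thresholds()].
#' @param max_gap_bp,max_gap_fraction Fragment-stitching tolerances.
#' @param consensus_min_ro Cross-caller matching reciprocal overlap.
#' @param rare A [rare_filter_config()].
#' @param trio_min_ro Parental-match reciprocal overlap.
#' @param tiers A [tier_rules()].
#' @param large_cnv_bp "Large CNV" size for the severity analysis (default
#'   5 Mb).
#' @param primary_callers Primary caller names for the consensus rules.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), max_gap_bp = 100000,
                            max_gap_fraction = 0.2, consensus_min_ro = 0.5,
                            rare = rare_filter_config(), trio_min_ro = 0.5,
                            tiers = tier_rules(), large_cnv_bp = 5e6,
                            primary_callers = PRIMARY_CALLERS) {
  structure(list(qc = qc, max_gap_bp = max_gap_bp,
                 max_gap_fraction = max_gap_fraction,
                 consensus_min_ro = consensus_min_ro, rare = rare,
                 trio_min_ro = trio_min_ro, tiers = tiers,
                 large_cnv_bp = large_cnv_bp,
                 primary_callers = primary_callers),
            class = "pipeline_config")
}

#' Run the full trio CNV pipeline
#'
#' @param inputs Named list as produced by [read_input_bundle()] or
#'   [simulate_cohort()]: `calls`, `trios`, `qc_metrics`, `phenotypes`,
#'   `probes`, `stable_regions`, `genes`, `known_loci`, `controls` (list of
#'   [control_cohort_index()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage writes its TSV
#'   there (deterministically, so reruns are byte-identical).
#' @return A list of class `triocnv_result`: `qc` (filter result),
#'   `trios` (complete trios surviving QC), `stitched`, `consensus` (all
#'   passing samples), `rare` (survivors + audit), `classified` (verdicts +
#'   tiers), `report` (a `triocnv_report`).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  need <- c("calls", "trios", "qc_metrics", "phenotypes", "probes",
            "stable_regions", "genes", "known_loci", "controls")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in) > 0) {
    stop("pipeline inputs missing: ", paste(missing_in, collapse = ", "))
  }
  if (length(inputs$controls) == 0) {
    stop("rare_filter stage needs at least one control cohort")
  }

  qc <- filter_samples(inputs$qc_metrics, config$qc)
  trios <- inputs$trios
  complete <- trios$child_id %in% qc$passing &
    trios$father_id %in% qc$passing & trios$mother_id %in% qc$passing
  trios_qc <- trios[complete, , drop = FALSE]

  calls <- inputs$calls[inputs$calls$sample %in% qc$passing, , drop = FALSE]
  stitched <- if (nrow(calls) > 0) {
    out <- do.call(rbind, lapply(
      split(calls, paste(calls$sample, calls$caller, sep = "\r")),
      stitch_fragments, max_gap_bp = config$max_gap_bp,
      max_gap_fraction = config$max_gap_fraction))
    rownames(out) <- NULL
    out
  } else calls

  consensus <- consensus_calls(stitched, min_ro = config$consensus_min_ro,
                               max_gap_bp = config$max_gap_bp,
                               max_gap_fraction = config$max_gap_fraction,
                               primary_callers = config$primary_callers)

  child_cons <- consensus[consensus$sample %in% trios_qc$child_id, ,
                          drop = FALSE]
  rare <- apply_rare_filters(child_cons, inputs$controls,
                             inputs$stable_regions, inputs$probes,
                             config$rare)

  parent_ids <- c(trios_qc$father_id, trios_qc$mother_id)
  parent_raw <- stitched[stitched$sample %in% parent_ids, , drop = FALSE]
  verdicts <- trio_verdicts(rare$survivors, parent_raw, trios_qc,
                            min_ro = config$trio_min_ro,
                            available_samples = intersect(parent_ids,
                                                          qc$passing))
  classified <- classify_variants(verdicts, inputs$genes,
                                  inputs$known_loci, config$tiers)
  phen <- inputs$phenotypes[inputs$phenotypes$sample %in% trios_qc$child_id, ,
                            drop = FALSE]
  report <- cohort_report(classified, trios_qc, phen, consensus,
                          large_cnv_bp = config$large_cnv_bp)

  result <- structure(list(qc = qc, trios = trios_qc, stitched = stitched,
                           consensus = consensus, rare = rare,
                           classified = classified, report = report,
                           config = config),
                      class = "triocnv_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.triocnv_result <- function(x, ...) {
  cat("triocnv pipeline result: ", length(x$qc$passing),
      " samples passing QC, ", nrow(x$trios), " complete trios, ",
      nrow(x$consensus), " consensus CNVs, ", nrow(x$rare$survivors),
      " rare proband CNVs\n", sep = "")
  print(x$report)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c("pipeline: triocnv",
            paste("config_hash:", config_hash(result$config)))
  write_tsv_with_header(result$qc$excluded,
                        file.path(out_dir, "qc_exclusions.tsv"), prov)
  cons <- result$consensus
  cons$start <- cons$start + 1
  write_tsv_with_header(cons, file.path(out_dir, "consensus.tsv"),
                        c(prov, "coordinates: 1-based inclusive"))
  write_tsv_with_header(result$rare$audit,
                        file.path(out_dir, "rare_filter_audit.tsv"), prov)
  write_classified_variants(result$classified,
                            file.path(out_dir, "classified_variants.tsv"),
                            prov)
  verd_cols <- intersect(c("family_id", "sample", "chrom", "start", "end",
                           "type", "inheritance", "best_ro_father",
                           "best_ro_mother"), names(result$classified))
  verd <- result$classified[, verd_cols, drop = FALSE]
  if (nrow(verd) > 0) verd$start <- verd$start + 1
  write_tsv_with_header(verd, file.path(out_dir, "trio_verdicts.tsv"),
                        c(prov, "coordinates: 1-based inclusive"))
  rates <- data.frame(measure = names(result$report$rates),
                      count = unname(result$report$counts),
                      n_trios = result$report$n_trios,
                      rate = unname(result$report$rates),
                      stringsAsFactors = FALSE)
  write_tsv_with_header(rates, file.path(out_dir, "report.tsv"), prov)
  rpt <- utils::capture.output(print(result$report))
  writeLines(c(paste("#", prov), rpt),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
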