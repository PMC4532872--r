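# Trio segregation of child CNVs.
#
# Parental evidence deliberately uses the RAW UNION of all parental
# per-caller calls (stitched per caller), never parental consensus: a
# single-caller false negative in a parent must not manufacture a de novo
# call. A child call is declared present in a parent when any same-type
# parental call on the same chromosome reaches the reciprocal-overlap
# threshold (default 0.5).
#
# Chromosome X in male children: matching is by interval and type only, so a
# hemizygous male deletion (copy number 0) matches a maternal heterozygous
# deletion (copy number 1); copy-number states are never compared.

INHERITANCE_STATES <- c("de_novo", "maternal", "paternal", "biparental",
                        "unresolved")

#' Classify one child CNV against both parents
#'
#' @param child_call Single-row consensus table for the child event.
#' @param father_calls,mother_calls Call tables holding the raw per-caller
#'   union for each parent (fragments stitched per caller). Pass `NULL` when
#'   a parent's call data are missing entirely: the verdict is then
#'   `unresolved`, never `de_novo` by absence of data. An empty table is
#'   evidence of absence and does count toward `de_novo`.
#' @param min_ro Reciprocal overlap at which a parental call confirms the
#'   child event (default 0.5).
#' @return List with `status` (`de_novo`, `maternal`, `paternal`,
#'   `biparental` or `unresolved`), `best_ro_father`, `best_ro_mother` and
#'   `best_parent_ro`.
#' @export
classify_inheritance <- function(child_call, father_calls, mother_calls,
                                 min_ro = 0.5) {
  stopifnot(nrow(child_call) == 1)
  best_ro <- function(parent_calls) {
    if (is.null(parent_calls)) return(NA_real_)
    p <- parent_calls[parent_calls$chrom == child_call$chrom &
                        parent_calls$type == child_call$type, , drop = FALSE]
    if (nrow(p) == 0) return(0)
    ov <- pmax(0, pmin(p$end, child_call$end) -
                 pmax(p$start, child_call$start))
    max(ov / pmax(p$end - p$start, child_call$end - child_call$start))
  }
  ro_f <- best_ro(father_calls)
  ro_m <- best_ro(mother_calls)
  status <- if (is.na(ro_f) || is.na(ro_m)) {
    "unresolved"
  } else if (ro_f >= min_ro && ro_m >= min_ro) {
    "biparental"
  } else if (ro_f >= min_ro) {
    "paternal"
  } else if (ro_m >= min_ro) {
    "maternal"
  } else {
    "de_novo"
  }
  list(status = status, best_ro_father = ro_f, best_ro_mother = ro_m,
       best_parent_ro = suppressWarnings(max(ro_f, ro_m, na.rm = TRUE)))
}

#' Segregation verdicts for all trios
#'
#' @param child_calls Consensus table of child events (typically the
#'   rare-filter survivors), any number of children.
#' @param parent_calls Stitched raw call table for all parents (per-caller
#'   union); samples absent from it are treated as missing data.
#' @param trios Trio table (family_id, child_id, father_id, mother_id).
#' @param min_ro Parental-match threshold (default 0.5).
#' @param available_samples Sample ids for which call data exist (defaults to
#'   the samples present in `parent_calls`). A parent listed here but absent
#'   from `parent_calls` is a genotyped parent with zero calls — evidence of
#'   absence; a parent not listed is missing data and yields `unresolved`.
#' @return The child table with columns `family_id`, `inheritance`,
#'   `best_ro_father`, `best_ro_mother` appended. Children not in any trio
#'   are dropped.
#' @export
trio_verdicts <- function(child_calls, parent_calls, trios, min_ro = 0.5,
                          available_samples = unique(parent_calls$sample)) {
  m <- match(child_calls$sample, trios$child_id)
  out <- child_calls[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  out$family_id <- trios$family_id[m]
  out$inheritance <- character(nrow(out))
  out$best_ro_father <- numeric(nrow(out))
  out$best_ro_mother <- numeric(nrow(out))
  by_sample <- split(parent_calls, parent_calls$sample)
  lookup <- function(id) {
    calls <- by_sample[[id]]
    if (is.null(calls) && id %in% available_samples) calls <- parent_calls[0, ]
    calls
  }
  for (i in seq_len(nrow(out))) {
    v <- classify_inheritance(out[i, ],
                              lookup(trios$father_id[m[i]]),
                              lookup(trios$mother_id[m[i]]),
                              min_ro = min_ro)
    out$inheritance[i] <- v$status
    out$best_ro_father[i] <- v$best_ro_father
    out$best_ro_mother[i] <- v$best_ro_mother
  }
  rownames(out) <- NULL
  out
}

#' De novo burden summary over trios
#'
#' Counts trios carrying at least one de novo verdict (trio-level, not
#' event-level counting) plus the total number of de novo events.
#'
#' @param verdicts Output of [trio_verdicts()].
#' @param trios Optional trio table; when given, the per-trio count vector
#'   covers every complete trio, including those with zero de novo events.
#' @return List: `n_trios_with_de_novo`, `n_de_novo_events`,
#'   `per_trio` (named integer vector of de novo event counts).
#' @export
de_novo_summary <- function(verdicts, trios = NULL) {
  fams <- if (!is.null(trios)) trios$family_id else
    unique(verdicts$family_id)
  per_trio <- stats::setNames(integer(length(fams)), fams)
  dn <- verdicts[verdicts$inheritance == "de_novo", , drop = FALSE]
  if (nrow(dn) > 0) {
    tab <- table(dn$family_id)
    per_trio[names(tab)] <- as.integer(tab)
  }
  list(n_trios_with_de_novo = sum(per_trio > 0),
       n_de_novo_events = nrow(dn),
       per_trio = per_trio)
}
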