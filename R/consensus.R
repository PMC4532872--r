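# Multi-caller consensus.
#
# Evidence rules:
#   * autosomes — a CNV must be called by >= 2 distinct algorithms, at least
#     one of them a primary caller (iPattern or PennCNV);
#   * chromosome X — only the two primary callers are considered, both must
#     have called the event, and both calls must carry the stringent flag.
# Matching across callers uses same-type reciprocal overlap (default 0.5),
# grouped transitively. Consensus boundaries are taken from the
# highest-priority supporting caller (ipattern > penncnv > quantisnp >
# cnvpartition > anything else) so that probe counts stay coherent.

PRIMARY_CALLERS <- c("ipattern", "penncnv")

caller_priority <- function(caller) {
  p <- match(caller, CALLERS)
  p[is.na(p)] <- length(CALLERS) + 1L
  p
}

is_chrx <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "X"
}

#' Group one sample's calls across callers
#'
#' Calls of identical type on the same chromosome are grouped transitively
#' when their pairwise reciprocal overlap reaches `min_ro`. Each call ends
#' up in exactly one group.
#'
#' @param calls Call table for a single sample (fragments already stitched
#'   per caller); multiple samples are rejected.
#' @param min_ro Reciprocal-overlap threshold for declaring two callers saw
#'   the same event (default 0.5).
#' @return The call table with an integer `group` column.
#' @export
match_calls_across_callers <- function(calls, min_ro = 0.5) {
  if (nrow(calls) == 0) {
    calls$group <- integer(0)
    return(calls)
  }
  if (length(unique(calls$sample)) > 1) {
    stop("match_calls_across_callers expects calls from a single sample; got: ",
         paste(unique(calls$sample), collapse = ", "))
  }
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$type,
                       calls$caller), , drop = FALSE]
  rownames(calls) <- NULL
  # union-find over same-chrom same-type pairs with RO >= min_ro
  parent <- seq_len(nrow(calls))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  key <- paste(calls$chrom, calls$type, sep = "\r")
  s <- calls$start; e <- calls$end
  for (idx in split(seq_len(nrow(calls)), key)) {
    if (length(idx) < 2) next
    for (ii in seq_along(idx)[-1]) {
      for (jj in seq_len(ii - 1)) {
        i <- idx[ii]; j <- idx[jj]
        ov <- min(e[i], e[j]) - max(s[i], s[j])
        ro <- max(0, ov) / max(e[i] - s[i], e[j] - s[j])
        if (ro >= min_ro) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(nrow(calls)), find, integer(1))
  calls$group <- match(roots, unique(roots))
  calls
}

#' Emit consensus CNVs from matched caller groups
#'
#' Applies the autosome and chromosome-X evidence rules to each group and
#' emits one consensus event per retained group, with the boundary-donating
#' representative caller, the supporting caller set, and the stitching
#' history carried through.
#'
#' @param groups Output of [match_calls_across_callers()].
#' @param child_sex Carried for bookkeeping; the evidence rules are applied
#'   identically to both sexes.
#' @param primary_callers The callers at least one of which must support an
#'   autosomal event and both of which must stringently support a chrX
#'   event. Default ipattern and penncnv.
#' @return A consensus table: sample, chrom, start, end, type,
#'   supporting_callers (comma-joined), representative_caller,
#'   stringent_support, n_probes, stitched_from.
#' @export
consensus_call_set <- function(groups, child_sex = "unknown",
                               primary_callers = PRIMARY_CALLERS) {
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      type = character(0), supporting_callers = character(0),
                      representative_caller = character(0),
                      stringent_support = logical(0),
                      n_probes = integer(0), stitched_from = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(groups) == 0) return(empty)
  if (is.null(groups$stitched_from)) groups$stitched_from <- 1L

  emit <- lapply(split(groups, groups$group), function(g) {
    on_x <- is_chrx(g$chrom[1])
    if (on_x) {
      g <- g[g$caller %in% primary_callers, , drop = FALSE]
      callers <- unique(g$caller)
      keep <- length(callers) == length(primary_callers) && all(g$stringent)
    } else {
      callers <- unique(g$caller)
      keep <- length(callers) >= 2 && any(callers %in% primary_callers)
    }
    if (!keep) return(NULL)
    g <- g[order(caller_priority(g$caller), g$start, g$end), , drop = FALSE]
    rep_call <- g[1, ]
    data.frame(sample = rep_call$sample, chrom = rep_call$chrom,
               start = rep_call$start, end = rep_call$end,
               type = rep_call$type,
               supporting_callers = paste(sort(callers), collapse = ","),
               representative_caller = rep_call$caller,
               stringent_support = all(g$stringent),
               n_probes = rep_call$n_probes,
               stitched_from = rep_call$stitched_from,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), emit))
  out <- out[order(out$sample, out$chrom, out$start, out$end, out$type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch and build consensus calls for many samples
#'
#' Convenience wrapper: stitches fragments per (sample, caller), groups
#' across callers per sample, and applies the consensus evidence rules.
#'
#' @param calls Call table, any number of samples.
#' @param min_ro Cross-caller matching threshold (default 0.5).
#' @param max_gap_bp,max_gap_fraction Stitching tolerances, see
#'   [stitch_fragments()].
#' @inheritParams consensus_call_set
#' @return Consensus table across all samples.
#' @export
consensus_calls <- function(calls, min_ro = 0.5, max_gap_bp = 100000,
                            max_gap_fraction = 0.2,
                            primary_callers = PRIMARY_CALLERS) {
  if (nrow(calls) == 0) return(consensus_call_set(calls[0, ]))
  stitched <- do.call(rbind, lapply(
    split(calls, paste(calls$sample, calls$caller, sep = "\r")),
    stitch_fragments, max_gap_bp = max_gap_bp,
    max_gap_fraction = max_gap_fraction))
  out <- do.call(rbind, lapply(
    split(stitched, stitched$sample),
    function(s) consensus_call_set(
      match_calls_across_callers(s, min_ro = min_ro),
      primary_callers = primary_callers)))
  rownames(out) <- NULL
  out
}
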