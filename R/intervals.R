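# Genomic interval algebra on plain BED-like data.frames.
# Internal convention everywhere in this package: 0-based, half-open [start, end).

#' Construct a genomic interval table
#'
#' Builds the minimal interval representation used throughout the package: a
#' data.frame with columns `chrom`, `start`, `end` in 0-based half-open
#' coordinates. All input dialects are converted to this convention at the
#' I/O boundary.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Numeric vector, 0-based inclusive starts (bp).
#' @param end Numeric vector, 0-based exclusive ends (bp); must exceed
#'   `start` element-wise, so every interval has length at least 1.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' interval("chr2", 100000, 250000)
#' @export
interval <- function(chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom must be a non-empty string")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start)) {
    stop("interval end must be strictly greater than start")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval length in bp
#' @param a Interval table (see [interval()]).
#' @return Numeric vector of lengths `end - start`.
#' @export
interval_length <- function(a) a$end - a$start

#' Overlap length between paired intervals
#'
#' @param a,b Interval tables of equal length (or either of length 1,
#'   recycled). Overlap is computed pairwise.
#' @return Non-negative numeric vector: number of shared bases, 0 when the
#'   chromosomes differ or the intervals are disjoint.
#' @examples
#' overlap_length(interval("chr1", 0, 100), interval("chr1", 50, 150))
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ifelse(a$chrom[ai] == b$chrom[bi], pmax(0, ov), 0)
}

#' Reciprocal overlap between paired intervals
#'
#' The fraction `overlap / max(length(a), length(b))`. This equals the
#' largest f such that the overlap covers at least f of BOTH intervals, the
#' prevailing convention for matching CNV calls ("f reciprocal overlap").
#'
#' @inheritParams overlap_length
#' @return Numeric vector in \[0, 1\]: 1 iff the intervals are identical, 0
#'   iff disjoint or on different chromosomes.
#' @examples
#' reciprocal_overlap(interval("chr1", 0, 100), interval("chr1", 50, 150))
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  overlap_length(a, b) /
    pmax(a$end[ai] - a$start[ai], b$end[bi] - b$start[bi])
}

#' Merge a region set into disjoint sorted intervals
#'
#' Unions overlapping or bookended intervals per chromosome. Used to
#' normalise region files (copy-number-stable maps, gene spans) before
#' coverage queries.
#'
#' @param regions Interval table; may contain mutually overlapping rows.
#' @return Interval table of disjoint intervals sorted by (chrom, start).
#' @export
merge_regions <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(interval("chr0", 0, 1)[0, ])
  }
  regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                     drop = FALSE]
  out <- lapply(split(regions, regions$chrom), function(r) {
    # running-maximum sweep: a row starts a new block iff it begins after
    # every earlier end on the chromosome
    run_end <- cummax(r$end)
    new_block <- c(TRUE, r$start[-1] > run_end[-nrow(r)])
    grp <- cumsum(new_block)
    data.frame(chrom = r$chrom[!duplicated(grp)],
               start = tapply(r$start, grp, min)[],
               end = tapply(r$end, grp, max)[],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), c("chrom", "start", "end"), drop = FALSE]
}

#' Fraction of an interval covered by a region set
#'
#' Computes the fraction of `a`'s bases lying in the union of `regions`
#' (regions are merged internally, so overlapping rows are not
#' double-counted). This is the quantity behind the stable-region gate:
#' rare-variant candidates must overlap copy-number-stable territory by more
#' than a configurable fraction.
#'
#' @param a Single-row interval table.
#' @param regions Interval table (possibly empty).
#' @return A fraction in \[0, 1\].
#' @examples
#' coverage_fraction(interval("chr1", 100, 200),
#'                   interval(c("chr1", "chr1"), c(0, 160), c(150, 300)))
#' @export
coverage_fraction <- function(a, regions) {
  stopifnot(nrow(a) == 1)
  if (is.null(regions) || nrow(regions) == 0) return(0)
  r <- regions[regions$chrom == a$chrom, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  r <- merge_regions(r)
  ov <- pmax(0, pmin(r$end, a$end) - pmax(r$start, a$start))
  sum(ov) / (a$end - a$start)
}

#' Count array probes inside an interval
#'
#' @param a Single-row interval table.
#' @param probes A probe map: named list (by chromosome) of strictly
#'   increasing probe positions (bp, 0-based), as returned by
#'   [load_probe_map()] or [probe_map()].
#' @return Number of probe positions p with `start <= p < end` on `a`'s
#'   chromosome. CNV callers emit runs of consecutive probes, so containment
#'   counts successive probes.
#' @export
count_probes <- function(a, probes) {
  stopifnot(nrow(a) == 1)
  p <- probes[[a$chrom]]
  if (is.null(p) || length(p) == 0) return(0L)
  as.integer(findInterval(a$end - 0.5, p) - findInterval(a$start - 0.5, p))
}

#' Build a probe map from chromosome/position vectors
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of probe positions (bp, 0-based).
#' @return Named list of sorted, de-duplicated position vectors.
#' @export
probe_map <- function(chrom, pos) {
  lapply(split(as.numeric(pos), as.character(chrom)),
         function(p) sort(unique(p)))
}

#' Stitch fragmented CNV calls from one sample and caller
#'
#' Very large CNVs are often emitted by a caller as several adjacent
#' sub-calls (array noise breaks the segmentation). Same-chromosome,
#' same-type calls separated by a gap no larger than
#' `max(max_gap_bp, max_gap_fraction * merged span)` are merged transitively
#' into one call spanning the outer boundaries. Probe counts sum, the merged
#' confidence is the minimum of the members, the stringent flag survives only
#' if all members carried it, and `stitched_from` counts the original
#' fragments so merges stay auditable. The operation is idempotent.
#'
#' @param calls CNV call table (see [load_call_set()] for the columns) from a
#'   single sample and single caller; mixed input is rejected.
#' @param max_gap_bp Absolute gap tolerance in bp (default 100000).
#' @param max_gap_fraction Gap tolerance as a fraction of the merged span
#'   (default 0.2); the larger of the two tolerances applies.
#' @return A call table sorted by (chrom, start, end, type) with a
#'   `stitched_from` column.
#' @export
stitch_fragments <- function(calls, max_gap_bp = 100000,
                             max_gap_fraction = 0.2) {
  if (nrow(calls) == 0) {
    calls$stitched_from <- integer(0)
    return(calls)
  }
  if (length(unique(calls$sample)) > 1) {
    bad <- calls[calls$sample != calls$sample[1], ][1, ]
    stop(sprintf("stitch_fragments expects one sample; found call %s:%.0f-%.0f for sample '%s' mixed with '%s'",
                 bad$chrom, bad$start, bad$end, bad$sample, calls$sample[1]))
  }
  if (length(unique(calls$caller)) > 1) {
    bad <- calls[calls$caller != calls$caller[1], ][1, ]
    stop(sprintf("stitch_fragments expects one caller; found call %s:%.0f-%.0f from caller '%s' mixed with '%s'",
                 bad$chrom, bad$start, bad$end, bad$caller, calls$caller[1]))
  }
  if (is.null(calls$stitched_from)) calls$stitched_from <- 1L

  merge_block <- function(b) {
    b$start <- min(b$start); b$end <- max(b$end)
    b$n_probes[1] <- if (any(is.na(b$n_probes))) NA_integer_ else sum(b$n_probes)
    b$confidence[1] <- if (all(is.na(b$confidence))) NA_real_ else min(b$confidence, na.rm = TRUE)
    b$copy_number[1] <- if (length(unique(b$copy_number)) == 1) b$copy_number[1] else NA_integer_
    b$stringent[1] <- all(b$stringent)
    b$stitched_from[1] <- sum(b$stitched_from)
    b[1, ]
  }

  stitch_group <- function(g) {
    repeat {
      g <- g[order(g$start, g$end), , drop = FALSE]
      if (nrow(g) == 1) return(g)
      # sequential sweep; repeated until fixpoint because merging extends the
      # span and the fractional tolerance with it
      grp <- integer(nrow(g))
      grp[1] <- 1L
      cur_start <- g$start[1]; cur_end <- g$end[1]
      for (i in 2:nrow(g)) {
        gap <- g$start[i] - cur_end
        span <- max(cur_end, g$end[i]) - cur_start
        if (gap <= max(max_gap_bp, max_gap_fraction * span)) {
          grp[i] <- grp[i - 1]
          cur_end <- max(cur_end, g$end[i])
        } else {
          grp[i] <- grp[i - 1] + 1L
          cur_start <- g$start[i]; cur_end <- g$end[i]
        }
      }
      if (max(grp) == nrow(g)) return(g)
      g <- do.call(rbind, lapply(split(g, grp), merge_block))
    }
  }

  key <- paste(calls$chrom, calls$type, sep = "\r")
  out <- do.call(rbind, lapply(split(calls, key), stitch_group))
  out <- out[order(out$chrom, out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
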