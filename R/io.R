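# Readers and writers for every pipeline file.
#
# Coordinate dialects:
#   * internal         — 0-based half-open (all in-memory tables)
#   * one_based_inclusive — default CNV-call input dialect (common caller output)
#   * bed_half_open    — BED region files, probe maps
# Human-readable output tables are written 1-based inclusive.

CNV_TYPES <- c("del", "dup")
CALLERS <- c("ipattern", "penncnv", "quantisnp", "cnvpartition")
CALL_COLUMNS <- c("sample", "caller", "chrom", "start", "end", "type",
                  "copy_number", "confidence", "n_probes", "stringent")

#' Construct a CNV call table
#'
#' The shared record for one CNV interval from one caller on one sample.
#' Coordinates are internal 0-based half-open.
#'
#' @param sample,caller Character vectors (caller is typically one of
#'   ipattern, penncnv, quantisnp, cnvpartition; other strings are accepted
#'   but can never satisfy the primary-caller consensus requirement).
#' @param chrom,start,end Interval fields, 0-based half-open.
#' @param type "del" or "dup".
#' @param copy_number Optional integer copy number (NA allowed). A deletion
#'   must carry copy number < 2 when present (0 for hemizygous male chrX).
#' @param confidence Optional caller confidence score.
#' @param n_probes Optional supporting probe count (>= 1 when present).
#' @param stringent Logical: caller-reported high-confidence flag (required
#'   for chromosome-X consensus).
#' @return A data.frame with the canonical call columns.
#' @export
cnv_calls <- function(sample, caller, chrom, start, end, type,
                      copy_number = NA_integer_, confidence = NA_real_,
                      n_probes = NA_integer_, stringent = FALSE) {
  n <- max(length(sample), length(caller), length(chrom), length(start),
           length(end), length(type))
  iv <- interval(rep_len(as.character(chrom), n),
                 rep_len(as.numeric(start), n),
                 rep_len(as.numeric(end), n))
  type <- rep_len(as.character(type), n)
  if (!all(type %in% CNV_TYPES)) {
    stop("type must be one of: ", paste(CNV_TYPES, collapse = ", "))
  }
  cn <- rep_len(as.integer(copy_number), n)
  if (any(!is.na(cn) & type == "del" & cn >= 2)) {
    stop("a deletion must have copy_number < 2 when copy_number is given")
  }
  np <- rep_len(as.integer(n_probes), n)
  if (any(!is.na(np) & np < 1)) stop("n_probes must be >= 1 when present")
  data.frame(sample = rep_len(as.character(sample), n),
             caller = rep_len(as.character(caller), n),
             chrom = iv$chrom, start = iv$start, end = iv$end, type = type,
             copy_number = cn,
             confidence = rep_len(as.numeric(confidence), n),
             n_probes = np,
             stringent = rep_len(as.logical(stringent), n),
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  cnv_calls("s", "c", "chr1", 0, 1, "del")[0, ]
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    ...)
}

#' Load a CNV call set
#'
#' Reads a tab-separated call file with header columns sample, caller,
#' chrom, start, end, type, copy_number, confidence, n_probes, stringent.
#' Coordinates are normalised to the internal 0-based half-open convention.
#' Malformed rows (unknown type token, non-positive length after
#' normalisation) are dropped and collected in the `rejected` attribute with
#' their line numbers; a missing mandatory column fails the whole load.
#'
#' @param path Path to the TSV ('#'-prefixed comment lines ignored).
#' @param dialect Coordinate dialect of the file: `"one_based_inclusive"`
#'   (default; length = end - start + 1) or `"bed_half_open"`.
#' @return A call table sorted by (sample, caller, chrom, start, end, type),
#'   with attribute `rejected`: a data.frame of line numbers and reasons.
#' @export
load_call_set <- function(path,
                          dialect = c("one_based_inclusive", "bed_half_open")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv(path, colClasses = "character")
  missing_cols <- setdiff(c("sample", "caller", "chrom", "start", "end", "type"),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop("call set ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(CALL_COLUMNS, names(raw))) raw[[col]] <- NA
  if (nrow(raw) == 0) return(empty_calls())

  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  if (dialect == "one_based_inclusive") start <- start - 1
  line <- seq_len(nrow(raw)) + 1L  # +1 for the header line

  reason <- rep(NA_character_, nrow(raw))
  reason[!(raw$type %in% CNV_TYPES)] <- "unknown type token"
  bad_coord <- is.na(start) | is.na(end) | end <= start
  reason[is.na(reason) & bad_coord] <- "end <= start after normalization"
  rejected <- data.frame(line = line[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- is.na(reason)

  out <- cnv_calls(sample = raw$sample[keep], caller = raw$caller[keep],
                   chrom = raw$chrom[keep], start = start[keep],
                   end = end[keep], type = raw$type[keep],
                   copy_number = suppressWarnings(as.integer(raw$copy_number[keep])),
                   confidence = suppressWarnings(as.numeric(raw$confidence[keep])),
                   n_probes = suppressWarnings(as.integer(raw$n_probes[keep])),
                   stringent = parse_flag(raw$stringent[keep]))
  out <- out[order(out$sample, out$caller, out$chrom, out$start, out$end,
                   out$type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

parse_flag <- function(x) {
  x <- tolower(as.character(x))
  out <- x %in% c("1", "true", "t", "yes")
  out[is.na(x) | x == "na" | x == ""] <- FALSE
  out
}

#' Write a CNV call set
#'
#' Inverse of [load_call_set()]: writes the canonical columns as TSV in the
#' requested dialect under a '#'-prefixed provenance header, so that
#' load -> write -> load round-trips every field.
#'
#' @param calls Call table (internal coordinates).
#' @param path Output path.
#' @param dialect Output coordinate dialect (default one_based_inclusive).
#' @param provenance Optional named character vector echoed as '# key: value'
#'   header lines.
#' @export
write_call_set <- function(calls, path, dialect = c("one_based_inclusive",
                                                    "bed_half_open"),
                           provenance = NULL) {
  dialect <- match.arg(dialect)
  out <- calls[, CALL_COLUMNS, drop = FALSE]
  if (dialect == "one_based_inclusive") out$start <- out$start + 1
  out$stringent <- as.integer(out$stringent)
  write_tsv_with_header(out, path,
                        c(paste("coordinate dialect:", dialect), provenance))
}

write_tsv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste("#", h), con)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                            justify = "none"),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pedigree and extract complete trios
#'
#' Reads a PED-like TSV with columns family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown) and optional role. Only families
#' where a child and both named parents are present as rows become trios;
#' incomplete families (singletons, duos) are reported in the `incomplete`
#' attribute, rows with an invalid sex code in `rejected`.
#'
#' @param path Path to the pedigree file.
#' @return A data.frame of trios with columns `family_id`, `child_id`,
#'   `father_id`, `mother_id`, `child_sex` ("male"/"female"/"unknown");
#'   attributes `incomplete` and `rejected`.
#' @export
load_pedigree <- function(path) {
  ped <- read_tsv(path, colClasses = "character")
  need <- c("family", "individual", "father", "mother", "sex")
  missing_cols <- setdiff(need, names(ped))
  if (length(missing_cols) > 0) {
    stop("pedigree ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  self_parent <- ped$individual == ped$father | ped$individual == ped$mother
  if (any(self_parent)) {
    stop("pedigree lists individual '", ped$individual[self_parent][1],
         "' as its own parent")
  }
  ok_sex <- ped$sex %in% c("0", "1", "2")
  rejected <- data.frame(individual = ped$individual[!ok_sex],
                         reason = sprintf("invalid sex code '%s'",
                                          ped$sex[!ok_sex]),
                         stringsAsFactors = FALSE)
  ped <- ped[ok_sex, , drop = FALSE]

  is_child <- ped$father != "0" & ped$mother != "0"
  kids <- ped[is_child, , drop = FALSE]
  complete <- kids$father %in% ped$individual & kids$mother %in% ped$individual
  sex_label <- c(`0` = "unknown", `1` = "male", `2` = "female")
  trios <- data.frame(family_id = kids$family[complete],
                      child_id = kids$individual[complete],
                      father_id = kids$father[complete],
                      mother_id = kids$mother[complete],
                      child_sex = unname(sex_label[kids$sex[complete]]),
                      stringsAsFactors = FALSE)
  dup_ids <- trios$child_id == trios$father_id |
    trios$child_id == trios$mother_id | trios$father_id == trios$mother_id
  if (any(dup_ids)) {
    stop("trio for child '", trios$child_id[dup_ids][1],
         "' does not have three distinct sample ids")
  }
  incomplete <- data.frame(family_id = kids$family[!complete],
                           child_id = kids$individual[!complete],
                           stringsAsFactors = FALSE)
  trios <- trios[order(trios$family_id, trios$child_id), , drop = FALSE]
  rownames(trios) <- NULL
  attr(trios, "incomplete") <- incomplete
  attr(trios, "rejected") <- rejected
  trios
}

#' Load a BED region file
#'
#' BED3/BED4(+flag) reader: 0-based half-open, tab-separated, '#' comments
#' ignored, no header. Column 4 (if present) is a region name; column 5 an
#' optional flag such as "dominant" for known pathogenic loci.
#'
#' @param path Path to the BED file.
#' @return Interval table with optional `name` and `dominant` columns,
#'   sorted by (chrom, start, end).
#' @export
load_regions <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, header = FALSE,
                           colClasses = "character",
                           col.names = paste0("V", 1:5), fill = TRUE)
  if (nrow(raw) == 0) return(interval("chr0", 0, 1)[0, ])
  out <- interval(raw$V1, as.numeric(raw$V2), as.numeric(raw$V3))
  if (any(nzchar(raw$V4))) out$name <- raw$V4
  if (any(nzchar(raw$V5))) out$dominant <- tolower(raw$V5) == "dominant"
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a probe map
#'
#' Two-column TSV (chrom, position; 0-based bp), header optional, sorted on
#' load.
#'
#' @param path Path to the probe TSV.
#' @return Named list of sorted probe position vectors (see [probe_map()]).
#' @export
load_probe_map <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, header = FALSE,
                           colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) {
    raw <- raw[-1, , drop = FALSE]  # header line
  }
  probe_map(raw[[1]], as.numeric(raw[[2]]))
}

#' Load per-sample array QC metrics
#'
#' TSV with columns sample, call_rate, lrr_sd, baf_sd (s.d. of the log R
#' ratio and B allele frequency tracks — the standard array noise metrics).
#'
#' @param path Path to the metrics TSV.
#' @return Data.frame with those four columns.
#' @export
load_qc_metrics <- function(path) {
  m <- read_tsv(path)
  need <- c("sample", "call_rate", "lrr_sd", "baf_sd")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    stop("QC metrics ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(m$call_rate < 0 | m$call_rate > 1, na.rm = TRUE)) {
    stop("call_rate must lie in [0, 1]")
  }
  m[, need]
}

GMFCS_LEVELS <- c("I", "II", "III", "IV", "V", "unknown")

#' Load per-sample phenotypes
#'
#' TSV with columns sample, gmfcs (I-V or "unknown") and optional
#' cp_subtype.
#'
#' @param path Path to the phenotype TSV.
#' @return Data.frame with columns sample, gmfcs, cp_subtype.
#' @export
load_phenotypes <- function(path) {
  ph <- read_tsv(path, colClasses = "character")
  missing_cols <- setdiff(c("sample", "gmfcs"), names(ph))
  if (length(missing_cols) > 0) {
    stop("phenotypes ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !(ph$gmfcs %in% GMFCS_LEVELS)
  if (any(bad)) {
    stop("unrecognized GMFCS level '", ph$gmfcs[bad][1], "' in ", path)
  }
  if (is.null(ph$cp_subtype)) ph$cp_subtype <- NA_character_
  ph[, c("sample", "gmfcs", "cp_subtype")]
}

#' Write classified variants
#'
#' One row per variant with 1-based inclusive coordinates, size, type,
#' inheritance status, gene count, clinical tier, supporting callers and the
#' rare-filter audit string; rows sorted by (sample, chrom, start) for
#' deterministic output.
#'
#' @param variants Classified-variant table (see [classify_variants()]).
#' @param path Output path.
#' @param provenance Optional '# key: value' header lines.
#' @export
write_classified_variants <- function(variants, path, provenance = NULL) {
  cols <- c("sample", "chrom", "start", "end", "size_bp", "type",
            "inheritance", "n_genes", "tier", "supporting_callers",
            "filter_audit")
  v <- variants
  if (nrow(v) > 0) {
    v <- v[order(v$sample, v$chrom, v$start), , drop = FALSE]
    out <- data.frame(sample = v$sample, chrom = v$chrom,
                      start = v$start + 1, end = v$end,
                      size_bp = v$end - v$start, type = v$type,
                      inheritance = v$inheritance, n_genes = v$n_genes,
                      tier = v$tier,
                      supporting_callers = v$supporting_callers,
                      filter_audit = v$filter_audit,
                      stringsAsFactors = FALSE)
  } else {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  tryCatch(
    write_tsv_with_header(out, path,
                          c("coordinates: 1-based inclusive", provenance)),
    error = function(e) stop("cannot write classified variants to ", path,
                             ": ", conditionMessage(e)))
}

#' Read a pipeline input bundle directory
#'
#' Loads the file layout written by [write_simulation()]: cnv_calls.tsv,
#' pedigree.ped, qc_metrics.tsv, phenotypes.tsv, probes.tsv,
#' stable_regions.bed, genes.bed, known_loci.bed, control_manifest.tsv plus
#' one call TSV per control cohort.
#'
#' @param dir Bundle directory.
#' @return A named list of loaded inputs suitable for [run_pipeline()].
#' @export
read_input_bundle <- function(dir) {
  need <- c("cnv_calls.tsv", "pedigree.ped", "qc_metrics.tsv",
            "phenotypes.tsv", "probes.tsv", "stable_regions.bed",
            "genes.bed", "known_loci.bed", "control_manifest.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files) > 0) {
    stop("input bundle ", dir, " is missing: ",
         paste(missing_files, collapse = ", "))
  }
  manifest <- read_tsv(file.path(dir, "control_manifest.tsv"),
                       colClasses = c("character", "character", "integer"))
  controls <- lapply(seq_len(nrow(manifest)), function(i) {
    control_cohort_index(
      load_call_set(file.path(dir, manifest$path[i])),
      n_samples = manifest$n_samples[i],
      name = manifest$cohort_name[i])
  })
  list(calls = load_call_set(file.path(dir, "cnv_calls.tsv")),
       trios = load_pedigree(file.path(dir, "pedigree.ped")),
       qc_metrics = load_qc_metrics(file.path(dir, "qc_metrics.tsv")),
       phenotypes = load_phenotypes(file.path(dir, "phenotypes.tsv")),
       probes = load_probe_map(file.path(dir, "probes.tsv")),
       stable_regions = load_regions(file.path(dir, "stable_regions.bed")),
       genes = load_regions(file.path(dir, "genes.bed")),
       known_loci = load_regions(file.path(dir, "known_loci.bed")),
       controls = controls)
}
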