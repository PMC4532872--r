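# Clinical tiering.
#
# Expert curation against CNV databases is replaced by an explicit decision
# table over size, de novo status, gene content and a user-supplied
# known-pathogenic-locus BED. First matching rule wins:
#   1. de novo AND size >= large_cnv_bp (default 5 Mb)      -> pathogenic
#   2. known-locus hit at RO >= locus_ro                     -> likely_pathogenic
#      (pathogenic when the locus is flagged dominant, any inheritance)
#   3. de novo AND n_genes >= likely_path_min_genes (20)     -> likely_pathogenic
#   4. de novo AND n_genes >= 1                              -> vus
#   5. otherwise                                             -> likely_benign
# Inherited variants hitting a variable-expressivity known locus thus land
# in likely_pathogenic, mirroring recurrent microdeletion/duplication
# syndromes with incomplete penetrance.

TIERS <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign")

#' Clinical tier rules
#'
#' @param large_cnv_bp De novo events at or above this size are pathogenic
#'   outright (default 5,000,000 bp).
#' @param likely_path_min_genes Gene count at which a de novo event becomes
#'   likely pathogenic (default 20).
#' @param locus_ro Reciprocal overlap with a known pathogenic locus that
#'   counts as a hit (default 0.5).
#' @return A list of class `tier_rules`.
#' @export
tier_rules <- function(large_cnv_bp = 5e6, likely_path_min_genes = 20L,
                       locus_ro = 0.5) {
  stopifnot(large_cnv_bp > 0, likely_path_min_genes >= 1,
            locus_ro > 0, locus_ro <= 1)
  structure(list(large_cnv_bp = as.numeric(large_cnv_bp),
                 likely_path_min_genes = as.integer(likely_path_min_genes),
                 locus_ro = locus_ro),
            class = "tier_rules")
}

#' Gene content of a variant
#'
#' A gene counts if it overlaps the variant by at least 1 bp (genes
#' straddling a boundary count).
#'
#' @param variant Single-row interval table.
#' @param genes Region table with a `name` column (BED4).
#' @return List with `n_genes` and `gene_names` (distinct, sorted).
#' @export
annotate_genes <- function(variant, genes) {
  stopifnot(nrow(variant) == 1)
  if (is.null(genes) || nrow(genes) == 0) {
    return(list(n_genes = 0L, gene_names = character(0)))
  }
  g <- genes[genes$chrom == variant$chrom &
               genes$end > variant$start & genes$start < variant$end, ,
             drop = FALSE]
  nm <- sort(unique(g$name))
  list(n_genes = length(nm), gene_names = nm)
}

known_locus_hits <- function(variant, known_loci, locus_ro) {
  if (is.null(known_loci) || nrow(known_loci) == 0) {
    return(data.frame(name = character(0), ro = numeric(0),
                      dominant = logical(0), stringsAsFactors = FALSE))
  }
  k <- known_loci[known_loci$chrom == variant$chrom, , drop = FALSE]
  if (nrow(k) == 0) {
    return(data.frame(name = character(0), ro = numeric(0),
                      dominant = logical(0), stringsAsFactors = FALSE))
  }
  ov <- pmax(0, pmin(k$end, variant$end) - pmax(k$start, variant$start))
  ro <- ov / pmax(k$end - k$start, variant$end - variant$start)
  hit <- ro >= locus_ro
  data.frame(name = if (is.null(k$name)) paste0(k$chrom, ":", k$start)[hit] else k$name[hit],
             ro = ro[hit],
             dominant = if (is.null(k$dominant)) rep(FALSE, sum(hit)) else k$dominant[hit] %in% TRUE,
             stringsAsFactors = FALSE)
}

#' Assign a clinical tier to one variant
#'
#' Applies the decision table documented above. An `unresolved` inheritance
#' verdict is tiered as if inherited and flagged for manual review.
#'
#' @param variant Single-row table with interval columns and an
#'   `inheritance` column.
#' @param rules A [tier_rules()] object.
#' @param known_loci Known pathogenic locus table (BED4 + optional dominant
#'   flag).
#' @param n_genes Gene count for the variant (from [annotate_genes()]).
#' @return List: `tier`, `rule` (which rule fired, 1-5), `locus_hits`
#'   (data.frame), `review` (logical: inheritance was unresolved).
#' @export
assign_clinical_tier <- function(variant, rules = tier_rules(),
                                 known_loci = NULL, n_genes = 0L) {
  stopifnot(nrow(variant) == 1)
  review <- identical(variant$inheritance, "unresolved")
  de_novo <- identical(variant$inheritance, "de_novo")
  size <- variant$end - variant$start
  hits <- known_locus_hits(variant, known_loci, rules$locus_ro)
  if (de_novo && size >= rules$large_cnv_bp) {
    tier <- "pathogenic"; rule <- 1L
  } else if (nrow(hits) > 0) {
    tier <- if (any(hits$dominant)) "pathogenic" else "likely_pathogenic"
    rule <- 2L
  } else if (de_novo && n_genes >= rules$likely_path_min_genes) {
    tier <- "likely_pathogenic"; rule <- 3L
  } else if (de_novo && n_genes >= 1) {
    tier <- "vus"; rule <- 4L
  } else {
    tier <- "likely_benign"; rule <- 5L
  }
  list(tier = tier, rule = rule, locus_hits = hits, review = review)
}

#' Annotate and tier a verdict-bearing variant table
#'
#' @param verdicts Output of [trio_verdicts()] (rare survivors with an
#'   `inheritance` column).
#' @param genes Gene region table (BED4).
#' @param known_loci Known pathogenic locus table.
#' @param rules A [tier_rules()] object.
#' @return The input table with `n_genes`, `gene_names` (comma-joined),
#'   `known_locus_hits` (comma-joined "name(ro)"), `tier`, `tier_rule` and
#'   `needs_review` columns appended.
#' @export
classify_variants <- function(verdicts, genes, known_loci = NULL,
                              rules = tier_rules()) {
  n <- nrow(verdicts)
  out <- verdicts
  out$n_genes <- integer(n)
  out$gene_names <- character(n)
  out$known_locus_hits <- character(n)
  out$tier <- character(n)
  out$tier_rule <- integer(n)
  out$needs_review <- logical(n)
  for (i in seq_len(n)) {
    ann <- annotate_genes(out[i, ], genes)
    cls <- assign_clinical_tier(out[i, ], rules, known_loci, ann$n_genes)
    out$n_genes[i] <- ann$n_genes
    out$gene_names[i] <- paste(ann$gene_names, collapse = ",")
    out$known_locus_hits[i] <- paste(
      sprintf("%s(%.2f)", cls$locus_hits$name, cls$locus_hits$ro),
      collapse = ",")
    out$tier[i] <- cls$tier
    out$tier_rule[i] <- cls$rule
    out$needs_review[i] <- cls$review
  }
  out
}
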