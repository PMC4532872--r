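gene_bed <- function(n, chrom = "chr1", start0 = 0, spacing = 1e5,
                     len = 3e4) {
  starts <- start0 + (seq_len(n) - 1) * spacing
  data.frame(chrom = chrom, start = starts, end = starts + len,
             name = sprintf("G%03d", seq_len(n)), stringsAsFactors = FALSE)
}

variant_row <- function(size, inheritance = "de_novo", chrom = "chr1",
                        start = 0, type = "del") {
  data.frame(sample = "P1", family_id = "F1", chrom = chrom, start = start,
             end = start + size, type = type, inheritance = inheritance,
             stringsAsFactors = FALSE)
}

test_that("gene annotation uses the 1 bp overlap rule with distinct sorted names", {
  genes <- data.frame(chrom = "chr1", start = c(500, 2000), end = c(600, 3000),
                      name = c("A", "B"), stringsAsFactors = FALSE)
  ann <- annotate_genes(interval("chr1", 0, 1000), genes)
  expect_equal(ann$n_genes, 1L); expect_equal(ann$gene_names, "A")
  expect_equal(annotate_genes(interval("chr1", 700, 1000), genes)$n_genes, 0L)
  # a gene straddling the variant boundary counts
  strad <- data.frame(chrom = "chr1", start = 900, end = 1500, name = "C",
                      stringsAsFactors = FALSE)
  expect_equal(annotate_genes(interval("chr1", 0, 1000), strad)$gene_names, "C")
  # the same name on overlapping rows is counted once
  dup <- rbind(strad, strad)
  expect_equal(annotate_genes(interval("chr1", 0, 1000), dup)$n_genes, 1L)
})

test_that("the tier decision table reproduces the reference scenarios", {
  rules <- tier_rules()
  loci <- data.frame(chrom = "chr2", start = 10e6, end = 12.1e6,
                     name = "recurrent_locus", dominant = FALSE,
                     stringsAsFactors = FALSE)

  # large de novo deletion: pathogenic by size (rule 1)
  t1 <- assign_clinical_tier(variant_row(25.5e6), rules, loci, n_genes = 150L)
  expect_equal(t1$tier, "pathogenic"); expect_equal(t1$rule, 1L)

  # 2.8 Mb de novo duplication hitting 20 genes: likely pathogenic (rule 3)
  t3 <- assign_clinical_tier(variant_row(2.8e6, type = "dup"), rules, loci,
                             n_genes = 20L)
  expect_equal(t3$tier, "likely_pathogenic"); expect_equal(t3$rule, 3L)

  # 48 kb single-gene de novo duplication: VUS (rule 4)
  t4 <- assign_clinical_tier(variant_row(48e3, type = "dup"), rules, loci,
                             n_genes = 1L)
  expect_equal(t4$tier, "vus"); expect_equal(t4$rule, 4L)

  # inherited, no locus hit: likely benign (rule 5)
  t5 <- assign_clinical_tier(variant_row(1e5, inheritance = "paternal"),
                             rules, loci, n_genes = 2L)
  expect_equal(t5$tier, "likely_benign"); expect_equal(t5$rule, 5L)

  # maternally inherited hit on a variable-expressivity locus: likely pathogenic (rule 2)
  t2 <- assign_clinical_tier(
    variant_row(2.1e6, inheritance = "maternal", chrom = "chr2", start = 10e6),
    rules, loci, n_genes = 18L)
  expect_equal(t2$tier, "likely_pathogenic"); expect_equal(t2$rule, 2L)

  # a dominant-flagged locus upgrades to pathogenic regardless of inheritance
  dom <- loci; dom$dominant <- TRUE
  td <- assign_clinical_tier(
    variant_row(2.1e6, inheritance = "maternal", chrom = "chr2", start = 10e6),
    rules, dom, n_genes = 18L)
  expect_equal(td$tier, "pathogenic")

  # unresolved inheritance is tiered as inherited and flagged for review
  tu <- assign_clinical_tier(variant_row(25.5e6, inheritance = "unresolved"),
                             rules, loci, n_genes = 150L)
  expect_equal(tu$tier, "likely_benign")
  expect_true(tu$review)
})

test_that("exactly one rule fires and growing a de novo variant never demotes it", {
  rules <- tier_rules()
  tier_rank <- c(likely_benign = 1, vus = 2, likely_pathogenic = 3,
                 pathogenic = 4)
  genes <- gene_bed(600)
  set.seed(101)
  for (k in 1:30) {
    size <- sample(c(2e4, 5e5, 2e6, 6e6, 2e7), 1)
    v <- variant_row(size)
    ann <- annotate_genes(v, genes)
    res <- assign_clinical_tier(v, rules, NULL, ann$n_genes)
    expect_true(res$rule %in% 1:5)
    expect_true(res$tier %in% c("pathogenic", "likely_pathogenic", "vus",
                                "likely_benign"))
    bigger <- variant_row(size * 2)
    res_big <- assign_clinical_tier(bigger, rules, NULL,
                                    annotate_genes(bigger, genes)$n_genes)
    expect_gte(tier_rank[res_big$tier], tier_rank[res$tier])
  }
})

test_that("classify_variants annotates a verdict table end to end", {
  genes <- gene_bed(600)
  loci <- data.frame(chrom = "chr1", start = 30e6, end = 32e6,
                     name = "locusX", dominant = FALSE,
                     stringsAsFactors = FALSE)
  v <- rbind(variant_row(10e6),                       # rule 1
             variant_row(1.5e6, "maternal", start = 30e6),  # rule 2 via locus
             variant_row(5e4, "paternal", start = 50e6))    # rule 5
  out <- classify_variants(v, genes, loci)
  expect_equal(out$tier, c("pathogenic", "likely_pathogenic", "likely_benign"))
  expect_equal(out$tier_rule, c(1L, 2L, 5L))
  expect_equal(out$n_genes[1], 100L)
  expect_match(out$known_locus_hits[2], "locusX")
})
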