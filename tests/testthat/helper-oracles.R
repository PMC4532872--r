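# Independent brute-force oracles: per-base set membership and linear scans.
# Deliberately naive; they exist to check the interval arithmetic, not to
# share code with it.

bases_of <- function(start, end) seq(start, end - 1)

oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  length(intersect(bases_of(a$start, a$end), bases_of(b$start, b$end)))
}

oracle_ro <- function(a, b) {
  oracle_overlap(a, b) / max(a$end - a$start, b$end - b$start)
}

oracle_coverage <- function(a, regions) {
  pos <- bases_of(a$start, a$end)
  covered <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    if (regions$chrom[i] != a$chrom) next
    covered <- covered | (pos >= regions$start[i] & pos < regions$end[i])
  }
  mean(covered)
}

oracle_probe_count <- function(a, chrom, pos) {
  sum(chrom == a$chrom & pos >= a$start & pos < a$end)
}

# two-sided Fisher by explicit log-factorial enumeration (lchoose), kept
# separate from the dhyper-based implementation under test
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  logp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  p <- exp(vapply(xs, logp, numeric(1)))
  sum(p[p <= exp(logp(a)) * (1 + 1e-7)])
}

random_interval <- function(max_len = 10000, chroms = c("chr1", "chr2")) {
  start <- sample(0:20000, 1)
  interval(sample(chroms, 1), start, start + sample(1:max_len, 1))
}
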