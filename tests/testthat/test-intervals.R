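test_that("overlap length handles identity, disjoint chromosomes and partial overlap", {
  expect_equal(overlap_length(interval("chr1", 0, 100), interval("chr1", 0, 100)), 100)
  expect_equal(overlap_length(interval("chr1", 0, 100), interval("chr2", 0, 100)), 0)
  expect_equal(overlap_length(interval("chr1", 0, 100), interval("chr1", 50, 150)), 50)
  expect_equal(overlap_length(interval("chr1", 0, 10), interval("chr1", 10, 20)), 0)
})

test_that("reciprocal overlap follows the longer-interval convention", {
  expect_equal(reciprocal_overlap(interval("chr1", 0, 100), interval("chr1", 0, 100)), 1.0)
  expect_equal(reciprocal_overlap(interval("chr1", 0, 100), interval("chr1", 50, 150)), 0.5)
  a <- interval("chr1", 0, 1000); b <- interval("chr1", 900, 910)
  expect_equal(reciprocal_overlap(a, b), 0.01)
  expect_equal(reciprocal_overlap(a, b), oracle_ro(a, b))
})

test_that("reciprocal overlap is symmetric, bounded, 1 iff identical, 0 iff disjoint", {
  set.seed(41)
  for (k in 1:200) {
    a <- random_interval(); b <- random_interval()
    ro <- reciprocal_overlap(a, b)
    expect_equal(ro, reciprocal_overlap(b, a))
    expect_gte(ro, 0); expect_lte(ro, 1)
    expect_equal(ro == 1,
                 a$chrom == b$chrom && a$start == b$start && a$end == b$end)
    expect_equal(ro == 0, oracle_overlap(a, b) == 0)
  }
})

test_that("coverage fraction matches hand-computed and degenerate cases", {
  regions <- interval(c("chr1", "chr1"), c(0, 160), c(150, 300))
  expect_equal(coverage_fraction(interval("chr1", 100, 200), regions), 0.9)
  expect_equal(coverage_fraction(interval("chr1", 100, 200), regions[0, ]), 0)
  expect_equal(coverage_fraction(interval("chr1", 100, 200),
                                 interval("chr1", 0, 1000)), 1.0)
  # overlapping regions must be merged internally, not double-counted
  dup_regions <- interval(c("chr1", "chr1"), c(0, 50), c(150, 150))
  expect_equal(coverage_fraction(interval("chr1", 100, 200), dup_regions), 0.5)
})

test_that("reciprocal overlap and coverage agree with the per-base oracle on random intervals", {
  set.seed(42)
  for (k in 1:150) {
    a <- random_interval(); b <- random_interval()
    expect_equal(reciprocal_overlap(a, b), oracle_ro(a, b))
    regions <- do.call(rbind, lapply(1:3, function(i) random_interval()))
    expect_equal(coverage_fraction(a, regions), oracle_coverage(a, regions))
  }
})

test_that("probe counting is half-open and matches a linear scan", {
  pm <- probe_map(rep("chr1", 5), c(10, 20, 30, 40, 50))
  expect_equal(count_probes(interval("chr1", 0, 100), pm), 5L)
  expect_equal(count_probes(interval("chr2", 0, 100), pm), 0L)
  expect_equal(count_probes(interval("chr1", 25, 45), pm), 2L)
  expect_equal(count_probes(interval("chr1", 10, 11), pm), 1L)

  set.seed(43)
  for (k in 1:100) {
    chrom <- sample(c("chr1", "chr2"), 40, replace = TRUE)
    pos <- sample(0:5000, 40)
    pm <- probe_map(chrom, pos)
    a <- interval(sample(c("chr1", "chr2"), 1), s <- sample(0:4000, 1),
                  s + sample(1:1000, 1))
    expect_equal(count_probes(a, pm), oracle_probe_count(a, chrom, pos))
  }
})

make_frags <- function(starts, ends, type = "del", sample = "S1",
                       caller = "ipattern", n_probes = 10L) {
  cnv_calls(sample, caller, "chr2", starts, ends, type,
            confidence = 0.9, n_probes = n_probes)
}

test_that("stitching merges fragments within the gap rule and respects type", {
  merged <- stitch_fragments(make_frags(c(0, 1050000), c(1000000, 2000000)),
                             max_gap_bp = 100000)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 0); expect_equal(merged$end, 2000000)
  expect_equal(merged$n_probes, 20L)
  expect_equal(merged$stitched_from, 2L)

  mixed <- rbind(make_frags(0, 1000000, "del"),
                 make_frags(1050000, 2000000, "dup"))
  expect_equal(nrow(stitch_fragments(mixed, max_gap_bp = 100000)), 2)

  far <- make_frags(c(0, 5000000), c(10000, 5010000))
  out <- stitch_fragments(far, max_gap_bp = 100000, max_gap_fraction = 0.2)
  expect_equal(nrow(out), 2)  # gap 4.99 Mb > max(100 kb, 0.2 * 5.01 Mb)
})

test_that("stitching rejects mixed samples or callers, naming the offender", {
  two_samples <- rbind(make_frags(0, 1000, sample = "S1"),
                       make_frags(2000, 3000, sample = "S2"))
  expect_error(stitch_fragments(two_samples), "S2")
  two_callers <- rbind(make_frags(0, 1000, caller = "ipattern"),
                       make_frags(2000, 3000, caller = "penncnv"))
  expect_error(stitch_fragments(two_callers), "penncnv")
})

test_that("stitching is idempotent and never reduces covered bases", {
  set.seed(44)
  for (k in 1:40) {
    n <- sample(2:8, 1)
    starts <- sort(sample(seq(0, 5e6, by = 1e4), n))
    lens <- sample(seq(1e4, 8e5, by = 1e4), n, replace = TRUE)
    calls <- make_frags(starts, starts + lens,
                        type = sample(c("del", "dup"), n, replace = TRUE))
    once <- stitch_fragments(calls)
    twice <- stitch_fragments(once)
    expect_equal(once, twice)
    for (ty in unique(calls$type)) {
      before <- merge_regions(calls[calls$type == ty, c("chrom", "start", "end")])
      after <- once[once$type == ty, , drop = FALSE]
      expect_gte(sum(after$end - after$start),
                 sum(before$end - before$start))
    }
  }
})
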