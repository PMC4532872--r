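cons_row <- function(sample = "P1", chrom = "chr1", start = 0, end = 1e5,
                     type = "del") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             type = type, supporting_callers = "ipattern,penncnv",
             representative_caller = "ipattern", stringent_support = TRUE,
             n_probes = 50L, stitched_from = 1L, stringsAsFactors = FALSE)
}

ctrl_calls <- function(sample, chrom = "chr1", start = 0, end = 1e5,
                       type = "del") {
  cnv_calls(sample, "control_set", chrom, start, end, type)
}

dense_probes <- probe_map(rep("chr1", 1000), seq(0, 999) * 1000)
whole_chr1 <- interval("chr1", 0, 1e9)

test_that("carrier counting is per distinct control sample at the RO threshold", {
  q <- cons_row(start = 0, end = 1e5)
  empty <- control_cohort_index(ctrl_calls("X1")[0, ], 1000)
  cf <- control_frequency(q, empty)
  expect_equal(cf$carrier_count, 0L); expect_equal(cf$frequency, 0)

  two <- control_cohort_index(ctrl_calls(c("X1", "X2")), 1000)
  cf <- control_frequency(q, two)
  expect_equal(cf$carrier_count, 2L); expect_equal(cf$frequency, 0.002)

  # one sample with two fragments at RO 0.4 each: fragments are not unioned
  frag <- control_cohort_index(
    ctrl_calls(c("X1", "X1"), start = c(0, 60000), end = c(40000, 100000)),
    1000)
  expect_equal(reciprocal_overlap(interval("chr1", 0, 40000),
                                  interval("chr1", 0, 1e5)), 0.4)
  expect_equal(control_frequency(q, frag, min_ro = 0.5)$carrier_count, 0L)

  # the same sample with many matching calls still counts once
  dup <- control_cohort_index(ctrl_calls(c("X1", "X1")), 1000)
  expect_equal(control_frequency(q, dup)$carrier_count, 1L)
})

test_that("each gate fails for the documented reason and all gates are audited", {
  cohort <- control_cohort_index(ctrl_calls("X1")[0, ], 2988)
  calls <- rbind(
    cons_row("P1", start = 0, end = 9000),            # too small
    cons_row("P2", start = 500e3, end = 550e3),       # fine
    cons_row("P3", start = 600e3, end = 603e3))       # small AND few probes
  res <- apply_rare_filters(calls, list(cohort), whole_chr1, dense_probes)
  expect_equal(res$survivors$sample, "P2")
  a <- res$audit
  expect_equal(nrow(a), 3 * 4)  # every gate evaluated for every call, pass or fail
  expect_false(a$pass[a$gate == "size" & grepl("P1", a$call_id)])
  expect_false(a$pass[a$gate == "probes" & grepl("P3", a$call_id)])
  # probe gate: a 50 kb call supported by only 4 probes fails
  sparse <- probe_map(rep("chr1", 4), c(1000, 2000, 3000, 4000))
  res4 <- apply_rare_filters(cons_row(start = 0, end = 5e4), list(cohort),
                             whole_chr1, sparse)
  expect_equal(nrow(res4$survivors), 0)
  expect_false(res4$audit$pass[res4$audit$gate == "probes"])
})

test_that("a variant must be rare in every cohort, and the audit makes <0.1% of 2,988 concrete", {
  q <- cons_row(start = 0, end = 1e5)
  primary <- control_cohort_index(ctrl_calls("X1")[0, ], 2988, "primary")
  refine <- control_cohort_index(
    ctrl_calls(sprintf("Y%02d", 1:10)), 1000, "refinement")  # 1% frequency
  res <- apply_rare_filters(q, list(primary, refine), whole_chr1,
                            dense_probes)
  expect_equal(nrow(res$survivors), 0)
  af <- res$audit_frequency
  expect_equal(af$carrier_count[af$cohort == "refinement"], 10)
  expect_equal(af$frequency[af$cohort == "primary"], 0)
  # 2 carriers of 2,988 still passes the <0.1% gate; 3 does not
  two <- control_cohort_index(ctrl_calls(c("X1", "X2")), 2988)
  expect_equal(nrow(apply_rare_filters(q, list(two), whole_chr1,
                                       dense_probes)$survivors), 1)
  three <- control_cohort_index(ctrl_calls(c("X1", "X2", "X3")), 2988)
  expect_equal(nrow(apply_rare_filters(q, list(three), whole_chr1,
                                       dense_probes)$survivors), 0)
  expect_error(apply_rare_filters(q, list(), whole_chr1, dense_probes),
               "cohort")
})

test_that("stable-region coverage must strictly exceed the threshold", {
  cohort <- control_cohort_index(ctrl_calls("X1")[0, ], 2988)
  q <- cons_row(start = 0, end = 1e5)
  at_75 <- interval("chr1", 0, 75000)
  res <- apply_rare_filters(q, list(cohort), at_75, dense_probes)
  expect_equal(nrow(res$survivors), 0)  # exactly 0.75 is not > 0.75
  above <- interval("chr1", 0, 76000)
  expect_equal(nrow(apply_rare_filters(q, list(cohort), above,
                                       dense_probes)$survivors), 1)
})

random_fixture <- function(n_calls = 15, n_controls = 60) {
  starts <- sample(seq(0, 9e5, by = 1e3), n_calls)
  calls <- do.call(rbind, lapply(seq_len(n_calls), function(i)
    cons_row(paste0("P", i), start = starts[i],
             end = starts[i] + sample(seq(5e3, 8e4, by = 1e3), 1),
             type = sample(c("del", "dup"), 1))))
  cs <- sample(seq(0, 9e5, by = 1e3), n_controls, replace = TRUE)
  ctl <- cnv_calls(sample = paste0("X", sample(1:20, n_controls, replace = TRUE)),
                   caller = "control_set", chrom = "chr1", start = cs,
                   end = cs + sample(seq(5e3, 8e4, by = 1e3), n_controls,
                                     replace = TRUE),
                   type = sample(c("del", "dup"), n_controls, replace = TRUE))
  stable <- interval("chr1", sample(0:100, 1) * 1e3, 1e9)
  list(calls = calls, cohort = control_cohort_index(ctl, 20), stable = stable)
}

test_that("survivors shrink as any gate tightens and grow as cohorts are removed", {
  set.seed(81)
  weak <- rare_filter_config(max_control_freq = 0.2, min_ro_vs_controls = 0.5,
                             min_stable_coverage = 0.5, min_probes = 5,
                             min_size_bp = 6000)
  for (k in 1:10) {
    fx <- random_fixture()
    base <- apply_rare_filters(fx$calls, list(fx$cohort), fx$stable,
                               dense_probes, weak)$survivors
    tighter <- list(
      rare_filter_config(0.05, 0.5, 0.5, 5, 6000),
      rare_filter_config(0.2, 0.5, 0.9, 5, 6000),
      rare_filter_config(0.2, 0.5, 0.5, 30, 6000),
      rare_filter_config(0.2, 0.5, 0.5, 5, 40000))
    for (cfg in tighter) {
      surv <- apply_rare_filters(fx$calls, list(fx$cohort), fx$stable,
                                 dense_probes, cfg)$survivors
      expect_true(all(surv$sample %in% base$sample))
    }
    extra_cohort <- control_cohort_index(
      cnv_calls(paste0("Z", 1:4), "control_set", "chr1",
                fx$calls$start[1:4], fx$calls$end[1:4],
                fx$calls$type[1:4]), 4, "extra")
    fewer <- apply_rare_filters(fx$calls, list(fx$cohort, extra_cohort),
                                fx$stable, dense_probes, weak)$survivors
    expect_true(all(fewer$sample %in% base$sample))
  }
})
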