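small_cfg <- function(seed = 5, n_trios = 12, ...) {
  sim_config(seed = seed, n_trios = n_trios,
             n_controls_per_cohort = c(ctl = 150), ...)
}

test_that("identical configs regenerate identical cohorts, including on disk", {
  cfg <- small_cfg()
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$ledger$events, s2$ledger$events)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$qc_metrics, s2$qc_metrics)
  expect_identical(s1$phenotypes, s2$phenotypes)

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_simulation(s1, d1); write_simulation(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  s3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(s1$calls, s3$calls))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the planted de novo trio count is exactly round(rate * n_trios)", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_trios = 115,
                      n_controls_per_cohort = c(ctl = 50),
                      rare_inherited_rate = 0.5,
                      control_background_rate = 0.2)
    led <- simulate_truth_cohort(cfg)
    expect_length(led$de_novo_families, 8)  # round(8/115 * 115)
    dn_events <- led$events[led$events$origin == "de_novo", ]
    expect_setequal(unique(dn_events$family_id), led$de_novo_families)
  }
})

test_that("a polymorphism at frequency 1 is carried by every parent and control", {
  poly <- data.frame(chrom = "chr1", start = 5e6, end = 5.1e6, type = "del",
                     frequency = 1, stringsAsFactors = FALSE)
  cfg <- small_cfg(polymorphic_regions = poly, rare_inherited_rate = 0,
                   control_background_rate = 0)
  led <- simulate_truth_cohort(cfg)
  parents <- led$events[led$events$role != "child", ]
  expect_equal(sum(parents$origin == "polymorphic"), 2 * cfg$n_trios)
  expect_equal(length(unique(led$controls$sample)), 150)
})

test_that("every inherited child event has an identical-coordinate parental source", {
  led <- simulate_truth_cohort(small_cfg(seed = 9))
  ev <- led$events
  kids <- ev[ev$role == "child" & ev$origin != "de_novo", ]
  for (i in seq_len(nrow(kids))) {
    fam <- kids$family_id[i]
    parents <- ev[ev$family_id == fam & ev$role != "child", ]
    hit <- parents$chrom == kids$chrom[i] & parents$start == kids$start[i] &
      parents$end == kids$end[i] & parents$type == kids$type[i]
    expect_true(any(hit))
    expect_false(kids$expected_verdict[i] == "de_novo")
  }
  # de novo events never match a parental event at the trio threshold
  dn <- ev[ev$origin == "de_novo", ]
  expect_true(all(dn$expected_verdict == "de_novo"))
})

test_that("zero-noise caller outputs reproduce the truth ledger for every caller", {
  cfg <- small_cfg(caller_models = zero_noise_caller_models())
  led <- simulate_truth_cohort(cfg)
  out <- simulate_caller_outputs(led, cfg)
  truth_key <- sort(paste(led$events$sample, led$events$chrom,
                          led$events$start, led$events$end, led$events$type))
  for (cal in c("ipattern", "penncnv", "quantisnp", "cnvpartition")) {
    cc <- out$calls[out$calls$caller == cal, ]
    expect_identical(sort(paste(cc$sample, cc$chrom, cc$start, cc$end,
                                cc$type)), truth_key, label = cal)
    expect_true(all(cc$stringent))
  }
  expect_null(out$fp_records)
})

test_that("forced fragmentation emits multiple fragments that stitch back to the truth", {
  frag_model <- caller_model(1, 0, 0, fragmentation_prob = 1,
                             stringent_prob = 1)
  cfg <- small_cfg(seed = 13, n_trios = 3,
                   caller_models = list(ipattern = frag_model),
                   rare_inherited_rate = 0, de_novo_rate = 1,
                   de_novo_size_mix = c(small = 0, large = 1),
                   polymorphic_regions = default_polymorphic_regions()[0, ],
                   control_background_rate = 0)
  led <- simulate_truth_cohort(cfg)
  out <- simulate_caller_outputs(led, cfg)
  big <- led$events[led$events$origin == "de_novo", ]
  for (i in seq_len(nrow(big))) {
    emitted <- out$calls[out$calls$sample == big$sample[i] &
                           out$calls$chrom == big$chrom[i], ]
    expect_gte(nrow(emitted), 2)
    stitched <- stitch_fragments(emitted)
    expect_equal(nrow(stitched), 1)
    expect_equal(stitched$start, big$start[i])
    expect_equal(stitched$end, big$end[i])
    expect_equal(stitched$stitched_from, nrow(emitted))
  }
})

test_that("a dead caller emits only false positives", {
  cfg <- small_cfg(seed = 17, caller_models = list(
    ipattern = caller_model(1, 0, 0, 0, 1),
    cnvpartition = caller_model(sensitivity = 0, fp_rate = 2)))
  led <- simulate_truth_cohort(cfg)
  out <- simulate_caller_outputs(led, cfg)
  cp <- out$calls[out$calls$caller == "cnvpartition", ]
  fp <- out$fp_records
  expect_gt(nrow(cp), 0)
  expect_equal(sort(paste(cp$sample, cp$chrom, cp$start, cp$end)),
               sort(paste(fp$sample, fp$chrom, fp$start, fp$end)))
})

test_that("phenotype severity follows the de novo carrier model under forced probabilities", {
  cfg <- small_cfg(seed = 21, n_trios = 30, de_novo_rate = 0.5,
                   de_novo_size_mix = c(small = 0, large = 1),
                   severe_gmfcs_prob_base = 0,
                   severe_gmfcs_prob_large_de_novo = 1,
                   gmfcs_known_prob = 1, qc_outlier_rate = 0)
  led <- simulate_truth_cohort(cfg)
  phqc <- simulate_phenotypes_and_qc(led, cfg)
  sev <- dichotomize_gmfcs(phqc$phenotypes$gmfcs)
  carriers <- unique(led$events$sample[led$events$origin == "de_novo" &
                                         led$events$end - led$events$start >= 5e6])
  is_carrier <- phqc$phenotypes$sample %in% carriers
  expect_true(all(sev[is_carrier] == "severe"))
  expect_true(all(sev[!is_carrier] == "mild_moderate"))
  # no planted outliers: nobody fails QC on call rate
  expect_true(all(phqc$qc_metrics$call_rate >= 0.95))
})

test_that("planted QC outliers are recovered by the sample filter", {
  cfg <- small_cfg(seed = 23, n_trios = 40, qc_outlier_rate = 0.1)
  led <- simulate_truth_cohort(cfg)
  phqc <- simulate_phenotypes_and_qc(led, cfg)
  res <- filter_samples(phqc$qc_metrics)
  expect_gt(nrow(res$excluded), 0)
  bad_cr <- phqc$qc_metrics$sample[phqc$qc_metrics$call_rate < 0.95]
  expect_true(all(bad_cr %in% res$excluded$sample))
})
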