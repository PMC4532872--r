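# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: parent-child
# trios with polymorphic CNVs segregating at population frequency, rare
# inherited events transmitted Mendelian-style, de novo events planted in a
# fixed fraction of trios, four caller outputs with per-caller sensitivity,
# boundary jitter, fragmentation of large events and false positives,
# control cohorts, array QC metrics with planted outliers, and GMFCS
# phenotypes whose severity probability is elevated for carriers of large
# de novo CNVs. Every emitted caller call traces back to a ground-truth
# ledger event or a false-positive record.
#
# The genome is scaled down (three 100 Mb autosomes plus a 100 Mb X) so
# fixtures stay small, but coordinates keep realistic magnitudes so the
# 10 kb and 5 Mb size gates are meaningful.

#' Per-caller error model
#'
#' @param sensitivity Probability a true event is detected.
#' @param fp_rate Expected false-positive calls per genome (Poisson).
#' @param boundary_jitter_sd S.d. (bp) of truncated-normal boundary noise;
#'   truncation guarantees the emitted interval is never inverted.
#' @param fragmentation_prob Probability an event larger than 2 Mb is split
#'   into 2-4 fragments separated by sub-100-kb gaps.
#' @param stringent_prob Probability a detected call carries the caller's
#'   stringent (high-confidence) flag.
#' @return A named list.
#' @export
caller_model <- function(sensitivity = 0.95, fp_rate = 2,
                         boundary_jitter_sd = 2500,
                         fragmentation_prob = 0.3, stringent_prob = 0.9) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0,
            boundary_jitter_sd >= 0, fragmentation_prob >= 0,
            fragmentation_prob <= 1, stringent_prob >= 0,
            stringent_prob <= 1)
  list(sensitivity = sensitivity, fp_rate = fp_rate,
       boundary_jitter_sd = boundary_jitter_sd,
       fragmentation_prob = fragmentation_prob,
       stringent_prob = stringent_prob)
}

#' Default caller error models
#'
#' Primary callers modelled slightly more sensitive and less noisy than the
#' secondary ones.
#' @return Named list of [caller_model()]s for ipattern, penncnv, quantisnp,
#'   cnvpartition.
#' @export
default_caller_models <- function() {
  list(ipattern = caller_model(0.95, 2, 2500, 0.30, 0.90),
       penncnv = caller_model(0.95, 2, 2500, 0.30, 0.90),
       quantisnp = caller_model(0.90, 3, 4000, 0.35, 0.85),
       cnvpartition = caller_model(0.85, 3, 5000, 0.40, 0.80))
}

#' Noise-free caller models
#'
#' Sensitivity 1, no false positives, no jitter, no fragmentation, always
#' stringent — caller outputs reproduce the truth ledger exactly. Used for
#' end-to-end recovery checks.
#' @return Named list of [caller_model()]s.
#' @export
zero_noise_caller_models <- function() {
  m <- caller_model(1, 0, 0, 0, 1)
  list(ipattern = m, penncnv = m, quantisnp = m, cnvpartition = m)
}

# Common polymorphisms are confined to chr1/chr2 (as are the known loci),
# leaving chr3 and chrX as open territory where the largest de novo events
# can be placed without colliding with fixed features.
default_polymorphic_regions <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
    start = c(5e6, 20e6, 42e6, 77e6, 12e6, 30e6, 55e6, 68e6),
    end = c(5e6 + 40e3, 20e6 + 35e3, 42e6 + 120e3, 77e6 + 150e3,
            12e6 + 60e3, 30e6 + 50e3, 55e6 + 80e3, 68e6 + 250e3),
    type = c("del", "dup", "dup", "del", "dup", "del", "del", "dup"),
    frequency = c(0.05, 0.30, 0.10, 0.12, 0.20, 0.25, 0.15, 0.08),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline targets: 115
#' complete trios, one primary control cohort of 2,988 samples, a de novo
#' event in round(8/115 * n_trios) trios with half the events large
#' (5-30 Mb on the scaled genome), about three rare inherited events per
#' parent genome, and a
#' severity model in which carriers of large de novo CNVs are severe
#' (GMFCS IV-V) with probability 0.75 against a 0.22 baseline.
#'
#' @param seed Integer RNG seed; identical configs regenerate byte-identical
#'   bundles.
#' @param n_trios Number of complete parent-child trios.
#' @param n_controls_per_cohort Named integer vector: control cohort sizes.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param probe_spacing_bp Array probe spacing (default 1200 bp, a
#'   2.5M-probe array scaled to the reduced genome).
#' @param polymorphic_regions Data.frame (chrom, start, end, type,
#'   frequency) of common CNV polymorphisms; default ships eight regions at
#'   carrier frequencies 0.05-0.30.
#' @param rare_inherited_rate Expected rare events per parent genome
#'   (Poisson).
#' @param rare_size_range Rare-event size range in bp (log-uniform).
#' @param known_locus_hit_rate Probability a rare parental event sits
#'   exactly on a known pathogenic locus (default 0.01, which yields on the
#'   order of 3 locus-hit families per 115 trios, the frequency at which
#'   recurrent syndromic loci turn up in cohorts of this size).
#' @param de_novo_rate Fraction of trios planted with a de novo event
#'   (default 8/115); exactly `round(de_novo_rate * n_trios)` trios are
#'   planted.
#' @param de_novo_size_mix Named probabilities c(small=, large=) for the de
#'   novo size classes (small 20-500 kb; large 5-30 Mb, so the largest
#'   events span about a third of a scaled chromosome, as the largest real
#'   chromosomal abnormalities do).
#' @param caller_models Named list of [caller_model()]s.
#' @param control_background_rate Expected rare background events per
#'   control genome.
#' @param qc_outlier_rate Fraction of family samples pushed outside the QC
#'   gates.
#' @param severe_gmfcs_prob_base Probability a non-carrier proband is severe
#'   (GMFCS IV-V).
#' @param severe_gmfcs_prob_large_de_novo Severity probability for carriers
#'   of a true de novo event of at least 5 Mb.
#' @param gmfcs_known_prob Probability a proband's GMFCS level is recorded.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_trios = 115L,
                       n_controls_per_cohort = c(population_controls = 2988L),
                       chrom_lengths = c(chr1 = 1e8, chr2 = 1e8,
                                         chr3 = 1e8, chrX = 1e8),
                       probe_spacing_bp = 1200L,
                       polymorphic_regions = default_polymorphic_regions(),
                       rare_inherited_rate = 3,
                       rare_size_range = c(2e4, 3e6),
                       known_locus_hit_rate = 0.01,
                       de_novo_rate = 8 / 115,
                       de_novo_size_mix = c(small = 0.5, large = 0.5),
                       caller_models = default_caller_models(),
                       control_background_rate = 1,
                       qc_outlier_rate = 0.02,
                       severe_gmfcs_prob_base = 0.22,
                       severe_gmfcs_prob_large_de_novo = 0.75,
                       gmfcs_known_prob = 0.9) {
  probs <- c(de_novo_rate, de_novo_size_mix, qc_outlier_rate,
             severe_gmfcs_prob_base, severe_gmfcs_prob_large_de_novo,
             gmfcs_known_prob, known_locus_hit_rate,
             polymorphic_regions$frequency)
  stopifnot(all(probs >= 0), all(probs <= 1), n_trios >= 1,
            all(n_controls_per_cohort >= 1), probe_spacing_bp >= 1)
  if (is.null(names(n_controls_per_cohort))) {
    names(n_controls_per_cohort) <-
      paste0("cohort", seq_along(n_controls_per_cohort))
  }
  structure(list(seed = as.integer(seed), n_trios = as.integer(n_trios),
                 n_controls_per_cohort = n_controls_per_cohort,
                 chrom_lengths = chrom_lengths,
                 probe_spacing_bp = as.integer(probe_spacing_bp),
                 polymorphic_regions = polymorphic_regions,
                 rare_inherited_rate = rare_inherited_rate,
                 rare_size_range = rare_size_range,
                 known_locus_hit_rate = known_locus_hit_rate,
                 de_novo_rate = de_novo_rate,
                 de_novo_size_mix = de_novo_size_mix,
                 caller_models = caller_models,
                 control_background_rate = control_background_rate,
                 qc_outlier_rate = qc_outlier_rate,
                 severe_gmfcs_prob_base = severe_gmfcs_prob_base,
                 severe_gmfcs_prob_large_de_novo = severe_gmfcs_prob_large_de_novo,
                 gmfcs_known_prob = gmfcs_known_prob),
            class = "sim_config")
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% .Machine$integer.max)
}

# Fixed annotation tracks for the scaled genome: copy-number-unstable holes,
# a tiled gene map, and three known pathogenic loci (one flagged dominant).
sim_annotation <- function(config) {
  cl <- config$chrom_lengths
  holes <- do.call(rbind, lapply(names(cl), function(ch) {
    data.frame(chrom = ch, start = c(85e6, 97e6), end = c(86e6, 97.5e6),
               stringsAsFactors = FALSE)
  }))
  holes <- holes[holes$end <= cl[holes$chrom], , drop = FALSE]
  stable <- do.call(rbind, lapply(names(cl), function(ch) {
    h <- holes[holes$chrom == ch, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(h$start, h$end)), cl[[ch]])
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    data.frame(chrom = ch, start = s[e > s], end = e[e > s],
               stringsAsFactors = FALSE)
  }))
  rownames(stable) <- NULL
  genes <- do.call(rbind, lapply(names(cl), function(ch) {
    starts <- seq(1e4, cl[[ch]] - 3e4, by = 15e4)
    data.frame(chrom = ch, start = starts, end = starts + 3e4,
               stringsAsFactors = FALSE)
  }))
  genes$name <- sprintf("GENE%05d", seq_len(nrow(genes)))
  known <- data.frame(
    chrom = c("chr1", "chr2", "chr2"),
    start = c(60e6, 40e6, 75e6),
    end = c(61.5e6, 41e6, 77e6),
    name = c("locus_1q21_like", "locus_16p13_like", "locus_syndromic_A"),
    dominant = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  known <- known[known$chrom %in% names(cl), , drop = FALSE]
  probes <- lapply(cl, function(L) seq(0, L - 1, by = config$probe_spacing_bp))
  list(holes = holes, stable_regions = stable, genes = genes,
       known_loci = known, probes = probes)
}

count_probes_vec <- function(chrom, start, end, probes) {
  n <- length(chrom)
  out <- integer(n)
  for (ch in unique(chrom)) {
    p <- probes[[ch]]
    i <- chrom == ch
    if (is.null(p)) next
    out[i] <- findInterval(end[i] - 0.5, p) - findInterval(start[i] - 0.5, p)
  }
  out
}

# TRUE where event i overlaps any same-type row of `others` at RO >= min_ro
# (type NULL disables the type restriction and min_ro 0 means any overlap).
matches_any <- function(chrom, start, end, type, others, min_ro = 0.5) {
  if (is.null(others) || nrow(others) == 0) return(FALSE)
  o <- others[others$chrom == chrom, , drop = FALSE]
  if (!is.null(type) && !is.null(o$type)) {
    o <- o[o$type == type, , drop = FALSE]
  }
  if (nrow(o) == 0) return(FALSE)
  ov <- pmax(0, pmin(o$end, end) - pmax(o$start, start))
  if (min_ro <= 0) return(any(ov > 0))
  any(ov / pmax(o$end - o$start, end - start) >= min_ro)
}

# TRUE when the candidate lies within stitching distance of any row of
# `others` on the same chromosome: gap below max(2e5, 0.3 * summed lengths),
# a margin above the default stitch rule max(1e5, 0.2 * merged span), so
# distinct planted events can never be stitched or consensus-grouped into
# one.
too_close <- function(chrom, start, end, others) {
  if (is.null(others) || nrow(others) == 0) return(FALSE)
  o <- others[others$chrom == chrom, , drop = FALSE]
  if (nrow(o) == 0) return(FALSE)
  gap <- pmax(o$start, start) - pmin(o$end, end)
  any(gap <= pmax(2e5, 0.3 * ((end - start) + (o$end - o$start))))
}

draw_event <- function(config, size, avoid, type = NULL, min_ro = 0,
                       spaced = FALSE, max_tries = 100, on_fail = "error") {
  cl <- config$chrom_lengths
  ok <- cl > size
  if (!any(ok)) stop("no chromosome can hold an event of size ", size)
  for (try in seq_len(max_tries)) {
    ch <- sample(names(cl)[ok], 1, prob = cl[ok])
    start <- floor(stats::runif(1, 0, cl[[ch]] - size))
    end <- start + size
    clash <- FALSE
    for (av in avoid) {
      hit <- if (spaced) too_close(ch, start, end, av) else
        matches_any(ch, start, end, type, av, min_ro)
      if (hit) { clash <- TRUE; break }
    }
    if (!clash) return(data.frame(chrom = ch, start = start, end = end,
                                  stringsAsFactors = FALSE))
  }
  if (identical(on_fail, "null")) return(NULL)
  stop("could not place a non-overlapping event after ", max_tries, " tries")
}

de_novo_size <- function(config) {
  big <- stats::runif(1) < config$de_novo_size_mix[["large"]]
  if (big) floor(stats::runif(1, 5e6, 3e7)) else
    floor(stats::runif(1, 2e4, 5e5))
}

rare_size <- function(config, n = 1) {
  r <- log(config$rare_size_range)
  floor(exp(stats::runif(n, r[1], r[2])))
}

event_copy_number <- function(type, chrom, sex) {
  hemi <- is_chrx(chrom) & sex == "male"
  ifelse(type == "del", ifelse(hemi, 0L, 1L), ifelse(hemi, 2L, 3L))
}

#' Simulate the ground-truth cohort
#'
#' Draws trio structures, parental polymorphic and rare events, Mendelian
#' transmission to children (chrX events follow sex: a father's X event
#' passes to daughters only), planted de novo events in exactly
#' `round(de_novo_rate * n_trios)` trios, and control-cohort events.
#' De novo events are redrawn if they would match a parental event, and
#' control background events are redrawn if they would match a planted rare
#' proband event at 50% reciprocal overlap, so planted events are de novo
#' and rare by construction. Each child event records the segregation
#' verdict an overlap-based classifier should reach
#' (`expected_verdict`): biparental when both parents carry a matching
#' event, regardless of which one transmitted.
#'
#' @param config A [sim_config()].
#' @return A list of class `truth_ledger`: `trios`, `events` (family
#'   samples), `controls`, `de_novo_families`, plus the fixed annotation
#'   (`genes`, `known_loci`, `stable_regions`, `probes`,
#'   `polymorphic_regions`, `chrom_lengths`).
#' @export
simulate_truth_cohort <- function(config) {
  set.seed(sub_seed(config$seed, 0))
  ann <- sim_annotation(config)
  poly <- config$polymorphic_regions
  fams <- sprintf("F%03d", seq_len(config$n_trios))
  trios <- data.frame(
    family_id = fams,
    child_id = paste0(fams, "C"),
    father_id = paste0(fams, "F"),
    mother_id = paste0(fams, "M"),
    child_sex = ifelse(stats::runif(config$n_trios) < 0.55, "male", "female"),
    stringsAsFactors = FALSE)

  avoid_static <- list(poly, ann$holes, ann$known_loci)
  parent_events <- function(sample_id, sex, partner = NULL) {
    ev <- list()
    carrier <- stats::runif(nrow(poly)) < poly$frequency
    if (any(carrier)) {
      p <- poly[carrier, , drop = FALSE]
      ev[[length(ev) + 1]] <- data.frame(
        chrom = p$chrom, start = p$start, end = p$end, type = p$type,
        origin = "polymorphic", stringsAsFactors = FALSE)
    }
    n_rare <- stats::rpois(1, config$rare_inherited_rate)
    own <- do.call(rbind, ev)
    for (k in seq_len(n_rare)) {
      locus_hit <- stats::runif(1) < config$known_locus_hit_rate
      if (locus_hit) {
        i <- sample(nrow(ann$known_loci), 1)
        e <- ann$known_loci[i, c("chrom", "start", "end")]
        rownames(e) <- NULL
        if (matches_any(e$chrom, e$start, e$end, NULL, own, 0)) {
          locus_hit <- FALSE  # already an event here; place elsewhere
        }
      }
      if (!locus_hit) {
        e <- draw_event(config, rare_size(config),
                        c(avoid_static[-3], list(ann$known_loci, own,
                                                 partner)),
                        spaced = TRUE)
      }
      e$type <- sample(CNV_TYPES, 1)
      e$origin <- "rare_inherited"
      own <- rbind(own, e)
      ev[[length(ev) + 1]] <- e
    }
    out <- do.call(rbind, ev)
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), type = character(0),
                        origin = character(0), stringsAsFactors = FALSE)
    }
    out$sample <- rep(sample_id, nrow(out))
    out$sex <- rep(sex, nrow(out))
    out
  }

  n_dn <- round(config$de_novo_rate * config$n_trios)
  dn_fams <- sort(sample(fams, n_dn))

  all_events <- vector("list", config$n_trios)
  for (i in seq_len(config$n_trios)) {
    fa <- parent_events(trios$father_id[i], "male")
    mo <- parent_events(trios$mother_id[i], "female", partner = fa)
    child_sex <- trios$child_sex[i]

    transmit <- function(pev, parent) {
      if (nrow(pev) == 0) return(pev[0, ])
      p_tx <- rep(0.5, nrow(pev))
      on_x <- is_chrx(pev$chrom)
      if (parent == "father") p_tx[on_x] <- ifelse(child_sex == "female", 1, 0)
      pev[stats::runif(nrow(pev)) < p_tx, , drop = FALSE]
    }
    tx_f <- transmit(fa, "father")
    tx_m <- transmit(mo, "mother")
    tx_f$source_parent <- rep("father", nrow(tx_f))
    tx_m$source_parent <- rep("mother", nrow(tx_m))
    child <- rbind(tx_f, tx_m)
    # a polymorphic allele transmitted by both parents is one child event
    if (nrow(child) > 1) {
      key <- paste(child$chrom, child$start, child$end, child$type)
      dup <- duplicated(key)
      if (any(dup)) {
        child$source_parent[key %in% key[dup]] <- "both"
        child <- child[!dup, , drop = FALSE]
      }
    }

    if (trios$family_id[i] %in% dn_fams) {
      dn <- NULL
      for (attempt in 1:40) {  # redraw the size too if placement fails
        dn <- draw_event(config, de_novo_size(config),
                         c(avoid_static, list(child, fa, mo)),
                         spaced = TRUE, max_tries = 50, on_fail = "null")
        if (!is.null(dn)) break
      }
      if (is.null(dn)) stop("could not place a de novo event in family ",
                            trios$family_id[i])
      dn$type <- sample(CNV_TYPES, 1)
      dn$origin <- "de_novo"
      dn$sample <- NA_character_
      dn$sex <- NA_character_
      dn$source_parent <- NA_character_
      child <- rbind(child, dn[, names(child)])
    }
    child$sample <- rep(trios$child_id[i], nrow(child))
    child$sex <- rep(child_sex, nrow(child))

    # overlap-based segregation truth: checked against parental carrier
    # status, not transmission
    ev <- function(j) {
      in_f <- matches_any(child$chrom[j], child$start[j], child$end[j],
                          child$type[j], fa, 0.5)
      in_m <- matches_any(child$chrom[j], child$start[j], child$end[j],
                          child$type[j], mo, 0.5)
      if (in_f && in_m) "biparental" else if (in_f) "paternal"
      else if (in_m) "maternal" else "de_novo"
    }
    child$expected_verdict <- vapply(seq_len(nrow(child)), ev, character(1))
    fa$source_parent <- rep(NA_character_, nrow(fa))
    mo$source_parent <- rep(NA_character_, nrow(mo))
    fa$expected_verdict <- rep(NA_character_, nrow(fa))
    mo$expected_verdict <- rep(NA_character_, nrow(mo))
    fam <- rbind(child, fa, mo)
    fam$family_id <- rep(trios$family_id[i], nrow(fam))
    all_events[[i]] <- fam
  }
  events <- do.call(rbind, all_events)
  events$role <- ifelse(grepl("C$", events$sample), "child",
                        ifelse(grepl("F$", events$sample), "father", "mother"))
  events$copy_number <- event_copy_number(events$type, events$chrom,
                                          events$sex)
  events <- events[, c("sample", "family_id", "role", "sex", "chrom",
                       "start", "end", "type", "copy_number", "origin",
                       "source_parent", "expected_verdict")]
  rownames(events) <- NULL

  planted_rare <- events[events$role == "child" &
                           events$origin %in% c("rare_inherited", "de_novo"), ,
                         drop = FALSE]
  controls <- list()
  for (co in names(config$n_controls_per_cohort)) {
    nc <- config$n_controls_per_cohort[[co]]
    ids <- sprintf("%s_S%05d", co, seq_len(nc))
    carr <- lapply(seq_len(nrow(poly)), function(r) {
      hit <- stats::runif(nc) < poly$frequency[r]
      if (!any(hit)) return(NULL)
      data.frame(sample = ids[hit], chrom = poly$chrom[r],
                 start = poly$start[r], end = poly$end[r],
                 type = poly$type[r], origin = "polymorphic",
                 stringsAsFactors = FALSE)
    })
    n_bg <- stats::rpois(nc, config$control_background_rate)
    bg <- NULL
    if (sum(n_bg) > 0) {
      who <- rep(ids, n_bg)
      bg_rows <- lapply(seq_along(who), function(k) {
        type <- sample(CNV_TYPES, 1)
        e <- draw_event(config, rare_size(config),
                        list(poly, planted_rare), type = type, min_ro = 0.5)
        data.frame(sample = who[k], chrom = e$chrom, start = e$start,
                   end = e$end, type = type, origin = "background",
                   stringsAsFactors = FALSE)
      })
      bg <- do.call(rbind, bg_rows)
    }
    ctab <- do.call(rbind, c(carr, list(bg)))
    if (is.null(ctab)) {
      ctab <- data.frame(sample = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         type = character(0), origin = character(0),
                         stringsAsFactors = FALSE)
    }
    ctab$cohort <- rep(co, nrow(ctab))
    controls[[co]] <- ctab
  }
  controls <- do.call(rbind, controls)
  rownames(controls) <- NULL

  structure(list(trios = trios, events = events, controls = controls,
                 de_novo_families = dn_fams,
                 genes = ann$genes, known_loci = ann$known_loci,
                 stable_regions = ann$stable_regions, holes = ann$holes,
                 probes = ann$probes,
                 polymorphic_regions = poly,
                 chrom_lengths = config$chrom_lengths),
            class = "truth_ledger")
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat("Truth ledger:", nrow(x$trios), "trios,",
      nrow(x$events), "family events,",
      length(x$de_novo_families), "de novo families,",
      nrow(x$controls), "control events\n")
  invisible(x)
}

jitter_bounds <- function(start, end, sd) {
  if (sd == 0) return(cbind(start, end))
  len <- end - start
  cap <- 0.45 * len
  ds <- pmax(-cap, pmin(cap, stats::rnorm(length(start), 0, sd)))
  de <- pmax(-cap, pmin(cap, stats::rnorm(length(end), 0, sd)))
  cbind(pmax(0, round(start + ds)), round(end + de))
}

fragment_event <- function(chrom, start, end) {
  k <- sample(2:4, 1)
  len <- end - start
  for (try in 1:20) {
    cuts <- sort(floor(stats::runif(k - 1, start + 0.1 * len,
                                    end - 0.1 * len)))
    if (min(diff(c(start, cuts, end))) > 2e5) break
    if (try == 20) return(data.frame(start = start, end = end))
  }
  gaps <- floor(stats::runif(k - 1, 5e3, 9e4))  # always under the 100 kb stitch gap
  s <- c(start, cuts)
  e <- c(cuts - gaps, end)
  data.frame(start = s, end = e)
}

#' Simulate per-caller call files from a truth ledger
#'
#' Each true family event is detected by each caller with the caller's
#' sensitivity; detected boundaries get truncated-normal jitter; events over
#' 2 Mb may be emitted as 2-4 fragments (gaps below the default stitching
#' tolerance); false positives land uniformly on probe-covered territory.
#' Probe counts come from the shared probe map; the stringent flag is drawn
#' per caller model. Control events are emitted noise-free as a published
#' call list under the pseudo-caller "control_set".
#'
#' @param ledger A [simulate_truth_cohort()] result.
#' @param config The same [sim_config()].
#' @return List: `calls` (family caller calls, canonical columns),
#'   `control_calls`, and `fp_records` (the planted false positives).
#' @export
simulate_caller_outputs <- function(ledger, config) {
  set.seed(sub_seed(config$seed, 1))
  ev <- ledger$events
  pieces <- list()
  fps <- list()
  trios <- ledger$trios
  samples <- sort(c(trios$child_id, trios$father_id, trios$mother_id))
  sex_of <- c(stats::setNames(trios$child_sex, trios$child_id),
              stats::setNames(rep("male", nrow(trios)), trios$father_id),
              stats::setNames(rep("female", nrow(trios)),
                              trios$mother_id))[samples]
  for (cal in names(config$caller_models)) {
    m <- config$caller_models[[cal]]
    det <- ev[stats::runif(nrow(ev)) < m$sensitivity, , drop = FALSE]
    if (nrow(det) > 0) {
      jb <- jitter_bounds(det$start, det$end, m$boundary_jitter_sd)
      det$start <- jb[, 1]; det$end <- jb[, 2]
      frag <- det$end - det$start > 2e6 &
        stats::runif(nrow(det)) < m$fragmentation_prob
      out <- vector("list", nrow(det))
      for (j in seq_len(nrow(det))) {
        if (frag[j]) {
          fr <- fragment_event(det$chrom[j], det$start[j], det$end[j])
        } else {
          fr <- data.frame(start = det$start[j], end = det$end[j])
        }
        out[[j]] <- data.frame(sample = det$sample[j], chrom = det$chrom[j],
                               start = fr$start, end = fr$end,
                               type = det$type[j],
                               copy_number = det$copy_number[j],
                               stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, out)
      out$caller <- cal
      out$stringent <- stats::runif(nrow(out)) < m$stringent_prob
      pieces[[length(pieces) + 1]] <- out
    }
    n_fp <- stats::rpois(length(samples), m$fp_rate)
    if (sum(n_fp) > 0) {
      who <- rep(seq_along(samples), n_fp)
      fp <- do.call(rbind, lapply(who, function(si) {
        size <- floor(exp(stats::runif(1, log(2e4), log(2e5))))
        e <- draw_event(config, size, list())
        type <- sample(CNV_TYPES, 1)
        data.frame(sample = samples[si], chrom = e$chrom, start = e$start,
                   end = e$end, type = type,
                   copy_number = event_copy_number(type, e$chrom,
                                                   sex_of[si]),
                   stringsAsFactors = FALSE)
      }))
      fp$caller <- cal
      fp$stringent <- stats::runif(nrow(fp)) < m$stringent_prob
      pieces[[length(pieces) + 1]] <- fp
      fps[[length(fps) + 1]] <- fp
    }
  }
  raw <- do.call(rbind, pieces)
  if (is.null(raw) || nrow(raw) == 0) {
    calls <- empty_calls()
  } else calls <- cnv_calls(sample = raw$sample, caller = raw$caller,
                     chrom = raw$chrom, start = raw$start, end = raw$end,
                     type = raw$type, copy_number = raw$copy_number,
                     confidence = round(stats::runif(nrow(raw), 0.5, 1), 3),
                     n_probes = pmax(1L, count_probes_vec(
                       raw$chrom, raw$start, raw$end, ledger$probes)),
                     stringent = raw$stringent)
  calls <- calls[order(calls$sample, calls$caller, calls$chrom, calls$start,
                       calls$end, calls$type), , drop = FALSE]
  rownames(calls) <- NULL

  ctl <- ledger$controls
  control_calls <- if (nrow(ctl) == 0) empty_calls() else cnv_calls(
    sample = ctl$sample, caller = "control_set", chrom = ctl$chrom,
    start = ctl$start, end = ctl$end, type = ctl$type,
    n_probes = pmax(1L, count_probes_vec(ctl$chrom, ctl$start, ctl$end,
                                         ledger$probes)))
  control_calls$cohort <- ctl$cohort
  control_calls <- control_calls[
    order(control_calls$cohort, control_calls$sample, control_calls$chrom,
          control_calls$start), , drop = FALSE]
  rownames(control_calls) <- NULL

  list(calls = calls, control_calls = control_calls,
       fp_records = if (length(fps)) do.call(rbind, fps) else NULL)
}

#' Simulate phenotypes and array QC metrics
#'
#' Probands carrying a true de novo event of at least 5 Mb are severe
#' (GMFCS IV-V) with probability `severe_gmfcs_prob_large_de_novo`, others
#' with `severe_gmfcs_prob_base`; the level within each stratum is uniform.
#' A fraction `gmfcs_known_prob` of probands have a recorded level. QC
#' metrics are drawn from reference normals with `qc_outlier_rate` of family
#' samples pushed beyond a gate (low call rate, or a noise metric far
#' outside the cohort band).
#'
#' @param ledger A [simulate_truth_cohort()] result.
#' @param config The same [sim_config()].
#' @return List: `phenotypes` (sample, gmfcs, cp_subtype) and `qc_metrics`
#'   (sample, call_rate, lrr_sd, baf_sd) for all family samples.
#' @export
simulate_phenotypes_and_qc <- function(ledger, config) {
  set.seed(sub_seed(config$seed, 2))
  trios <- ledger$trios
  ev <- ledger$events
  big_dn <- ev$role == "child" & ev$origin == "de_novo" &
    ev$end - ev$start >= 5e6
  carriers <- unique(ev$sample[big_dn])
  p_sev <- ifelse(trios$child_id %in% carriers,
                  config$severe_gmfcs_prob_large_de_novo,
                  config$severe_gmfcs_prob_base)
  severe <- stats::runif(nrow(trios)) < p_sev
  level <- ifelse(severe,
                  sample(c("IV", "V"), nrow(trios), replace = TRUE),
                  sample(c("I", "II", "III"), nrow(trios), replace = TRUE))
  level[stats::runif(nrow(trios)) >= config$gmfcs_known_prob] <- "unknown"
  subtypes <- c("spastic_diplegia", "spastic_quadriplegia",
                "spastic_hemiplegia", "dyskinetic", "ataxic")
  phenotypes <- data.frame(
    sample = trios$child_id, gmfcs = level,
    cp_subtype = sample(subtypes, nrow(trios), replace = TRUE),
    stringsAsFactors = FALSE)

  samples <- c(trios$child_id, trios$father_id, trios$mother_id)
  n <- length(samples)
  qc <- data.frame(
    sample = samples,
    call_rate = pmin(0.9995, stats::rnorm(n, 0.985, 0.004)),
    lrr_sd = abs(stats::rnorm(n, 0.12, 0.015)),
    baf_sd = abs(stats::rnorm(n, 0.035, 0.004)),
    stringsAsFactors = FALSE)
  outlier <- stats::runif(n) < config$qc_outlier_rate
  which_gate <- sample(1:3, n, replace = TRUE)
  push <- outlier & which_gate == 1
  qc$call_rate[push] <- stats::runif(sum(push), 0.88, 0.945)
  push <- outlier & which_gate == 2
  qc$lrr_sd[push] <- 0.12 + stats::runif(sum(push), 0.12, 0.2)
  push <- outlier & which_gate == 3
  qc$baf_sd[push] <- 0.035 + stats::runif(sum(push), 0.04, 0.08)
  qc <- qc[order(qc$sample), , drop = FALSE]
  rownames(qc) <- NULL
  list(phenotypes = phenotypes[order(phenotypes$sample), , drop = FALSE],
       qc_metrics = qc)
}

#' Simulate a complete input bundle
#'
#' Composes [simulate_truth_cohort()], [simulate_caller_outputs()] and
#' [simulate_phenotypes_and_qc()] under one seed and packages everything a
#' pipeline run needs, plus the truth ledger for validation.
#'
#' @param config A [sim_config()].
#' @return A list of class `triocnv_sim` with elements `config`, `ledger`,
#'   `calls`, `controls` (list of [control_cohort_index()]), `qc_metrics`,
#'   `phenotypes`, `trios`, and the annotation tracks (`genes`,
#'   `known_loci`, `stable_regions`, `probes`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  ledger <- simulate_truth_cohort(config)
  calls <- simulate_caller_outputs(ledger, config)
  phqc <- simulate_phenotypes_and_qc(ledger, config)
  controls <- lapply(names(config$n_controls_per_cohort), function(co) {
    control_cohort_index(
      calls$control_calls[calls$control_calls$cohort == co, , drop = FALSE],
      n_samples = config$n_controls_per_cohort[[co]], name = co)
  })
  names(controls) <- names(config$n_controls_per_cohort)
  structure(list(config = config, ledger = ledger, calls = calls$calls,
                 control_calls = calls$control_calls,
                 fp_records = calls$fp_records,
                 controls = controls,
                 qc_metrics = phqc$qc_metrics,
                 phenotypes = phqc$phenotypes,
                 trios = ledger$trios,
                 genes = ledger$genes, known_loci = ledger$known_loci,
                 stable_regions = ledger$stable_regions,
                 probes = ledger$probes),
            class = "triocnv_sim")
}

#' @export
print.triocnv_sim <- function(x, ...) {
  cat("Synthetic trio CNV cohort (seed ", x$config$seed, "): ",
      nrow(x$trios), " trios, ", nrow(x$calls), " caller calls, ",
      nrow(x$control_calls), " control calls\n", sep = "")
  invisible(x)
}

config_hash <- function(config) {
  # rolling polynomial hash of the serialized config; a stable provenance
  # tag for output headers, not a cryptographic digest
  bytes <- as.numeric(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a simulation to an input bundle directory
#'
#' Emits the complete file bundle in the layout [read_input_bundle()] and
#' the command-line interface consume: cnv_calls.tsv, pedigree.ped, control
#' cohort TSVs plus control_manifest.tsv, probes.tsv, stable_regions.bed,
#' genes.bed, known_loci.bed, qc_metrics.tsv, phenotypes.tsv, the truth
#' ledger, and manifest.yaml recording the seed and config hash. Output is
#' deterministic: identical configs regenerate byte-identical bundles.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "controls"), showWarnings = FALSE)
  prov <- c(paste("generator: triocnv synthetic cohort"),
            paste("seed:", sim$config$seed),
            paste("config_hash:", config_hash(sim$config)))
  write_call_set(sim$calls, file.path(dir, "cnv_calls.tsv"),
                 provenance = prov)

  trios <- sim$trios
  ped <- rbind(
    data.frame(family = trios$family_id, individual = trios$child_id,
               father = trios$father_id, mother = trios$mother_id,
               sex = ifelse(trios$child_sex == "male", 1L, 2L),
               role = "child", stringsAsFactors = FALSE),
    data.frame(family = trios$family_id, individual = trios$father_id,
               father = "0", mother = "0", sex = 1L, role = "father",
               stringsAsFactors = FALSE),
    data.frame(family = trios$family_id, individual = trios$mother_id,
               father = "0", mother = "0", sex = 2L, role = "mother",
               stringsAsFactors = FALSE))
  ped <- ped[order(ped$family, ped$individual), ]
  write_tsv_with_header(ped, file.path(dir, "pedigree.ped"), prov)

  manifest <- data.frame(cohort_name = names(sim$controls),
                         path = file.path("controls",
                                          paste0(names(sim$controls), ".tsv")),
                         n_samples = vapply(sim$controls,
                                            function(x) x$n_samples,
                                            integer(1)),
                         stringsAsFactors = FALSE)
  write_tsv_with_header(manifest, file.path(dir, "control_manifest.tsv"),
                        prov)
  for (i in seq_len(nrow(manifest))) {
    co <- manifest$cohort_name[i]
    write_call_set(
      sim$control_calls[sim$control_calls$cohort == co,
                        CALL_COLUMNS, drop = FALSE],
      file.path(dir, manifest$path[i]), provenance = prov)
  }

  probes_df <- do.call(rbind, lapply(names(sim$probes), function(ch) {
    data.frame(chrom = ch, position = sim$probes[[ch]],
               stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(probes_df, file.path(dir, "probes.tsv"), prov)

  write_bed <- function(df, path, extra = NULL) {
    out <- data.frame(chrom = df$chrom,
                      start = format(df$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(df$end, scientific = FALSE, trim = TRUE),
                      stringsAsFactors = FALSE)
    for (col in extra) out[[col]] <- df[[col]]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(sim$stable_regions, file.path(dir, "stable_regions.bed"))
  write_bed(sim$genes, file.path(dir, "genes.bed"), "name")
  kl <- sim$known_loci
  kl$flag <- ifelse(kl$dominant, "dominant", ".")
  write_bed(kl, file.path(dir, "known_loci.bed"), c("name", "flag"))

  write_tsv_with_header(sim$qc_metrics, file.path(dir, "qc_metrics.tsv"),
                        prov)
  write_tsv_with_header(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                        prov)
  led <- sim$ledger$events
  led$start <- led$start + 1  # 1-based inclusive like the other human tables
  write_tsv_with_header(led, file.path(dir, "truth_ledger.tsv"),
                        c(prov, "coordinates: 1-based inclusive"))
  yaml::write_yaml(list(seed = sim$config$seed,
                        config_hash = config_hash(sim$config),
                        n_trios = nrow(sim$trios),
                        de_novo_families = sim$ledger$de_novo_families),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
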