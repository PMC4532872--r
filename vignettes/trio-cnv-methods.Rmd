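---
title: "Methods: trio CNV consensus, rarity filtering and clinical tiering"
author: "triocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio CNV consensus, rarity filtering and clinical tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocnv)
```

## The analysis model

`triocnv` prioritizes copy number variants in parent–child trios genotyped
on a single SNP array platform, where CNVs are called independently by
several algorithms from the same intensity data. The pipeline's premise is
that clinical relevance in this setting is argued from four converging
lines of evidence, each of which is a distinct, auditable stage:

* **concordance** — an event is trusted only when multiple independent
  calling algorithms see it (segmentation noise is largely
  caller-specific);
* **rarity** — events common in population controls are presumed benign
  polymorphisms;
* **segregation** — an event present in a child but in neither parent is
  de novo, the strongest single prior for pathogenicity;
* **content** — size, gene count and hits on known recurrent syndromic
  loci stratify the surviving events into clinical tiers.

All interval arithmetic uses 0-based half-open coordinates internally;
1-based inclusive coordinates appear only at the I/O boundary (the default
input dialect, and all human-readable output). Reciprocal overlap is
defined as overlap length divided by the *longer* interval, so
RO ≥ f guarantees the overlap covers at least f of both intervals. Ties in
sorting are broken by (chrom, start, end, type) so every output is
deterministic.

## Stage-by-stage assumptions and tunables

**Sample QC** (`qc_thresholds()`): call rate ≥ 0.95 (fraction of genotyped
markers); LRR s.d. and BAF s.d. within cohort mean ± 3 s.d. (sample s.d.,
n − 1 denominator). Two deliberate choices: values exactly at a bound
*pass* (conservative retention), and the cohort bounds are computed once on
the full cohort, including samples that fail the call-rate gate — a
single-pass rule that avoids order-dependence between gates. Note the
arithmetic consequence of a k-s.d. band: in a cohort of n samples the
largest attainable z-score is (n − 1)/√n, so small cohorts can never fail
this gate, and in large clean cohorts ~0.3% of samples per metric fall
outside 3 s.d. by chance. Trios losing any member are analysed no further.

**Stitching** (`stitch_fragments()`): same-sample, same-caller, same-type
calls merge when the gap is ≤ max(`max_gap_bp` = 100 kb,
`max_gap_fraction` = 0.2 × merged span). The fractional term is what makes
multi-megabase fragments re-joinable; the absolute term handles small
events. Merging is run to a fixpoint so the operation is idempotent; probe
counts sum, confidence takes the minimum, the stringent flag survives only
if unanimous, and `stitched_from` preserves the fragment count for review.
The merge rule is configuration-exposed because fragment merging is, in
practice, a manual-review step that any fixed rule can only approximate.

**Consensus** (`consensus_calls()`): cross-caller matching at RO ≥ 0.5 for
identical types, grouped transitively (union–find). Transitive grouping can
in principle chain calls whose extremes overlap by less than the threshold;
this is accepted and bounded by the same-type/same-chromosome constraint.
Autosomes require ≥ 2 callers including a primary caller (iPattern or
PennCNV); chromosome X requires both primary callers with stringent calls,
ignoring other callers entirely. Consensus boundaries are copied from the
highest-priority supporting caller (ipattern > penncnv > quantisnp >
cnvpartition) rather than unioned or intersected, so the reported probe
count remains a real caller's probe count. The rules are applied
identically to both sexes; sex matters only to the simulator's X
transmission model and to hemizygous copy-number bookkeeping.

**Rare filter** (`rare_filter_config()`): four gates with the strictness
implied by their phrasing — size strictly > 10 kb, probes ≥ 5,
stable-region coverage strictly > 0.75, control frequency strictly < 0.001.
For a 2,988-sample primary cohort the frequency gate therefore tolerates at
most 2 carriers, a figure the audit table makes explicit. Carriers are
counted per control *sample* (a control with a fragmented event counts
once; two 40%-overlap fragments do not sum to a match). When several
control cohorts are supplied the event must be rare in *every* cohort —
the conservative reading of using additional cohorts to refine a rare list.
All four gates are always evaluated (no short-circuit) so the audit is
complete for survivors and casualties alike.

**Trio inheritance** (`trio_verdicts()`): parental evidence is the raw
per-caller union (stitched per caller), *not* parental consensus — a
single-caller false negative in a parent must not manufacture a de novo
call. A child event is present in a parent when any same-type parental call
reaches RO ≥ 0.5. Missing parental call data yields `unresolved`; an empty
call set from a genotyped parent is evidence of absence. Matching is by
interval and type only, never copy number, so a hemizygous male chrX
deletion (copy number 0) matches the mother's heterozygous deletion (copy
number 1). Adjacent del + dup pairs are reported as two events; no
unbalanced-translocation calling is attempted.

**Clinical tiering** (`tier_rules()`): a first-match-wins decision table
(pathogenic ≥ 5 Mb de novo; known-locus hit at RO ≥ 0.5 → likely
pathogenic, or pathogenic when the locus is flagged dominant; de novo with
≥ 20 genes → likely pathogenic; de novo with ≥ 1 gene → VUS; else likely
benign). Database curation and expert judgement are deliberately *not*
reproduced; the user-supplied known-locus BED (a demo ships in
`inst/extdata/`) is the single point where curated knowledge enters, and
inherited hits on variable-expressivity loci land in likely-pathogenic with
the locus named for genetic-counselling context. The 20-gene threshold
encodes the precedent that a multi-megabase, gene-dense de novo duplication
is reportable even below the 5 Mb line; the fired rule is recorded per
variant. Unresolved inheritance is tiered as inherited and flagged for
review rather than guessed.

**Statistics** (`fisher_exact_two_sided()`, `burden_t_test()`,
`rate_report()`): the Fisher test is the probability-mass two-sided
convention — the sum of hypergeometric probabilities of all tables with the
observed margins no more probable than the observed one — computed by full
enumeration, with a 1e-7 *relative* tolerance on the ≤ comparison to
absorb floating-point ties (mid-p and doubling conventions exist and give
different numbers; this is the mainstream-software convention). The burden
comparison is the classical pooled-variance unpaired t (not Welch), with
p = 1 when the pooled variance is zero and the means agree, and an error
when it is zero and they differ. Printed rates round half-up to one
decimal, matching how such percentages are conventionally reported.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, on a scaled genome of three 100 Mb autosomes plus a 100 Mb X with
one probe every 1.2 kb (a 2.5M-probe array scaled down). Defaults encode
the study conditions the pipeline targets:

* 115 complete trios; one population control cohort of 2,988 samples;
* eight polymorphic CNV regions at carrier frequencies 0.05–0.30, confined
  to chr1/chr2 (chr3 and chrX stay free of fixed features so the largest
  events have somewhere to live);
* ~3 rare inherited events per parent genome (≈ 3 rare CNVs per proband
  after transmission, the burden typical of such cohorts), sizes
  log-uniform on 20 kb–3 Mb, each with probability 0.01 of sitting exactly
  on a known pathogenic locus — about 3 locus-hit families per 115 trios;
* a de novo event planted in exactly round(8/115 × n_trios) trios, half
  small (20–500 kb), half large (5–30 Mb; the upper end spans about a third
  of a scaled chromosome, as the largest real chromosomal abnormalities
  do);
* four caller error models (sensitivity 0.85–0.95, boundary jitter s.d.
  2.5–5 kb, 2–3 false positives per genome, fragmentation of > 2 Mb events
  with probability 0.3–0.4, stringent-flag probability 0.8–0.9);
* GMFCS severity probability 0.75 for carriers of a ≥ 5 Mb true de novo
  event versus 0.22 baseline, with 90% of probands phenotyped — which makes
  the planted severity association recoverable by the Fisher stage;
* 2% of family samples pushed outside a QC gate.

Children inherit each parental event independently with probability 0.5
(chrX: father→daughter always, father→son never); a polymorphic allele
transmitted by both parents becomes one child event. The ledger records,
for every child event, the verdict an overlap-based classifier *should*
reach — `biparental` whenever both parents carry a matching event,
regardless of which one transmitted, since overlap evidence cannot
distinguish transmission from co-carriage.

Three constructions make the zero-noise recovery guarantees exact rather
than probabilistic. Planted events are spaced: no two events in one family
may lie within max(200 kb, 0.3 × summed lengths) of each other or of a
fixed feature, a margin strictly wider than the default stitch rule, so
distinct true events can never be stitched or consensus-grouped together
(this is also why the largest events need feature-free chromosomes).
De novo events are redrawn if they would match a parental event at any
overlap. Control background events are redrawn if they would match a
planted rare proband event at RO ≥ 0.5, so "planted rare" is rare in the
realized control set by construction, with the 0.1% gate untouched.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: raw LRR/BAF intensities (calls are
simulated at the caller-output level, so intensity-level artefacts shared
across callers are absent); caller-specific probe subsets or platform
differences between case and control arrays; correlated caller errors
(real callers fail on the same hard regions; simulated failures are
independent, which flatters multi-caller consensus); population
stratification and relatedness; sibling structure; and genuinely ambiguous
breakpoints (jitter is symmetric truncated-normal noise that never inverts
an interval). Zero-noise recovery shows the plumbing is lossless; the
noisy-model tests bound error propagation only under these independence
assumptions.

## Numerical and degenerate-input choices

* Stitching runs its merge sweep to a fixpoint; a single left-to-right
  pass is not idempotent because merging grows the span and with it the
  fractional gap tolerance.
* `count_probes` uses binary search on sorted probe positions; containment
  counts "successive" probes because callers only emit runs of consecutive
  probes.
* The Fisher enumeration errors on an all-zero table; `rate_report` errors
  when the numerator exceeds the denominator; `cohort_metric_bounds`
  errors below two samples (s.d. undefined).
* The generator's sub-stages draw from seeds seed+0/1/2 (truth, caller
  noise, phenotypes/QC) so each stage is independently reproducible and
  the composition is byte-identical across runs.
* Boundary jitter is capped at 45% of event length per endpoint, so an
  emitted interval always retains > 10% of its true length and can never
  invert.

## Validation strategy and problem sizes

The test suite checks every interval operation against per-base brute-force
oracles (10,000 random intervals in the acceptance suite), enumerates the
full caller-support truth table for the consensus rules (60 cases:
15 non-empty caller subsets × autosome/chrX × stringency), verifies
rare-filter monotonicity along each gate's grid on randomized fixtures, and
runs the full pipeline end to end: a zero-noise 115-trio cohort with 2,988
controls must reproduce its planted de novo trio count, rare-variant set
and tier labels exactly (restricted to trios surviving the stochastic QC
gate, which is the pipeline's documented incomplete-trio semantics), and a
200-trio cohort at caller sensitivity 0.9 must keep the false-de-novo rate
on > 500 inherited events within (1 − 0.9)² plus three binomial standard
errors — with four callers contributing to the parental union the expected
rate is (1 − 0.9)⁴, so this bound is loose by design. Determinism is
asserted byte-for-byte on regenerated bundles and rerun pipeline outputs.
The Fisher implementation is cross-checked against both an independent
log-factorial enumeration and `stats::fisher.test` on random tables; the
t-test against `stats::t.test(var.equal = TRUE)`.

## Known limitations

* Tiering is a rule-based approximation of expert curation; it has no
  dosage-sensitivity, inheritance-model or literature evidence, and no
  ACMG/ClinGen scoring.
* Consensus transitive grouping can, in adversarial geometries, chain
  calls whose extremes overlap by less than the threshold, and the
  "raising RO never increases consensus calls" intuition can fail in such
  geometries; both behaviours are documented and the property is only
  guaranteed (and only tested) in the jittered-shared-event regime.
* The frequency gate treats each control cohort's published call list at
  face value; no cross-platform sensitivity correction is attempted, so an
  event undetectable on a control platform is "rare" there.
* No liftover: all inputs must share one genome build. No chrY handling.
* Parent–child relationships are taken from the pedigree as given;
  relationship verification belongs upstream.
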