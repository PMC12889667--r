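---
title: "Quantifying mitochondrial dsRNA signatures from strand-aware pileups"
author: "mtdsrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dsRNA signatures from strand-aware pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Both strands of the circular mitochondrial chromosome (ChrM) are
transcribed, so complementary heavy- and light-strand transcripts — and
self-complementary regions within single transcripts — can hybridize into
mitochondrial double-stranded RNA (mt-dsRNA). When mt-dsRNA escapes to the
cytoplasm it is read by antiviral pattern-recognition receptors and drives
sterile inflammation. Direct measurement of dsRNA in archival RNA-seq is
impossible, but dsRNA leaves a footprint: ADAR enzymes, which act only on
double-stranded RNA in the cytoplasm or nucleus, deaminate adenosine to
inosine, and inosine is read as guanosine by sequencers. A-to-I edits on
mitochondrial transcripts are therefore a proxy for cytoplasmic mt-dsRNA.

This package implements the full quantification chain on top of
strand-aware per-position pileup evidence:

1. a per-sample A-to-I **editing caller** that discriminates edits from
   homoplasmic variants, sequencing errors and artifacts;
2. **ChrM scaling-factor normalization** with percentile-based sample QC,
   yielding the per-sample **mt-dsRNA signature**;
3. an **editing landscape** (200-nt bins, per-gene shares, antisense-read
   fractions);
4. **group statistics** (Shapiro–Wilk screening, Welch and Brown–Forsythe
   ANOVA, Dunnett T3 post hoc, relative-expression ratios);
5. an **association suite** (gene retention, Pearson correlation panels
   with BH/Bonferroni control, three-way intersection, hypergeometric
   gene-set overlap);
6. a **synthetic-cohort generator** with complete ground truth, used by
   every test.

## Evidence model and the caller

The caller consumes a per-sample `PileupTable`: one row per (position,
read-orientation stratum) with counts of A/C/G/T and a mean base quality.
Transcript strand comes from the annotation, not from read orientation: on
an H-strand (+) gene an A-to-I edit appears as A>G in the plus-strand
pileup; on an L-strand (−) gene it appears as T>C. Read-orientation strata
are retained only for the antisense-read analysis. Evidence for a gene is
evaluated on the stratum matching its strand (sense reads); a position
covered by two genes on the *same* strand is an annotation error, while
H/L overlap is legal and evaluated independently per strand.

Candidates are positions with any non-reference base; the dominant
alternate allele is taken (ties broken by fixed A<C<G<T order). Each
candidate passes through a fixed filter cascade, and a rejected candidate
records the *first* failing filter:

| order | filter | reason code | default |
|---|---|---|---|
| 1 | mismatch is not the strand-appropriate A>G | `not_A_to_I` | — |
| 2 | mean base quality below threshold | `low_quality` | Q25 |
| 3 | coverage below threshold | `low_coverage` | 10 reads |
| 4 | fewer than `min_edited_reads` or level below `min_edit_level` | `low_support` | 2 reads, 1% |
| 5 | level above `max_edit_level` (homoplasmy guard) | `homoplasmic_SNV` | 90% |

All minima are inclusive (`>=`), all maxima inclusive (`<=`). The three
filtering goals are the classical ones for editing callers: variants,
sequencing errors, and mapping-style artifacts; because alignment is
upstream of the pileup evidence, artifact control is represented by the
quality and coverage thresholds. `min_edit_level = 0.01` is deliberately
low: at typical mitochondrial coverage the two-read support floor is the
binding constraint, and a higher level floor would double-penalize deeply
covered samples.

Two cohort-level rules follow (`apply_cohort_filters()`): sites whose
variant-allele fraction is ≥ 0.9 in at least half of the covered samples
are reclassified `cohort_SNV` everywhere — this is what makes homoplasmic
variants (which are rejected per sample only when their VAF exceeds the
homoplasmy guard) disappear even when a sample's VAF dips below the
guard. "Covered samples" are those with an evidence record at the site;
call sets do not carry full pileups, and a homoplasmic variant produces a
record in every covered sample, so the rule behaves as intended. An
optional recurrence filter removes calls seen in fewer than 2 samples; it
is **off** by default because cross-subject recurrence is a credibility
observation, not a stated filter, in the analyses this package models.

## Normalization, QC and the signature

The ChrM scaling factor is a sample's total ChrM read count divided by the
cohort mean, a proxy for rRNA-depletion efficiency; factors average to 1
by construction. Samples whose factor falls outside the closed interval
[P5, P95] of the cohort distribution fail QC and are excluded from every
downstream statistic — but never from edit calling itself, so QC changes
which samples are compared, not what was measured. Three pinned choices
make the rule bit-reproducible:

* percentiles use linear interpolation between closest ranks (R quantile
  type 7) — on scaling factors 1..100 this gives P5 = 5.95 and
  P95 = 95.05, so exactly samples 6..95 (90 of 100) pass;
* boundary samples pass ("within the 5th to 95th percentile" read
  inclusively);
* factors are computed on **all** samples and not recomputed after
  exclusion (recomputation would shift the cohort mean; it exists as an
  off-by-default option `recompute_sf_after_qc`).

The signature is `raw_edits / chrm_sf`. Because "edit counts" can mean
distinct edited sites or read-level edit events, both modes exist.
`mt_dsrna_signature()` defaults to `sites` (the conservative reading), but
the pipeline and all parameter-recovery analyses use `edited_reads`: at
100× coverage and a 5% per-read edit rate the probability that a *site*
clears the two-read support floor is already ≈ 0.96, so distinct-site
counts saturate and cannot scale with a doubling of the underlying rate,
whereas read-weighted counts remain linear in it. The transcriptome-wide
analogue divides a genome-wide count by the library-size factor.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the statistical structure the
analysis assumes, at the pileup level (simulating reads would cost far
more and cover no more of the method):

* **Depth.** Per-sample mean ChrM depth is log-normal (median
  `depth_mean = 100`, log-SD `depth_sigma = 0.25`) — the heavy-tailed
  depletion-efficiency variation the percentile QC is designed to trim;
  per-position coverage is Poisson around it. With these values the 5–95%
  depth range spans roughly 0.66–1.5× the median, i.e. only clearly
  aberrant samples are trimmed.
* **Edit sites.** Editable sites are drawn at `edit_site_density = 15`
  per kb among in-gene positions whose transcript-strand base is A
  (~250 sites on the 16,569-nt chromosome — enough for stable
  recall/precision estimation). Edited-read counts are binomial with rate
  `base_edit_rate × group multiplier × sample propensity`, where the
  propensity is a log-normal per-sample random effect
  (`signature_sd = 0.3`). The propensity is what makes the *true*
  signature vary within a group — without it, normalization would cancel
  depth and leave nothing for expression or clinical panels to correlate
  with.
* **Confounders.** Homoplasmic variants (0.5/kb, alt fraction ≈ 1) and
  uniform sequencing error (0.1%) challenge the caller; a per-gene
  fraction of reads (18%) is flipped to the antisense orientation,
  mirroring the antisense share reported for mitochondrial rRNA in human
  brain data.
* **Expression and clinical tables.** A designated 40-gene panel couples
  to the standardized latent editing propensity through a Gaussian copula
  over negative-binomial margins at `latent_assoc_strength = 0.6` (a
  moderate, realistically attenuated transcriptomic effect); MMSE
  (negatively), Braak and CERAD (positively) couple to the same latent
  factor and shift monotonically with group; APOE ε4 frequency rises with
  group severity. The `mito_like` gene set half-overlaps the coupled
  panel so the hypergeometric overlap has signal.

`aging_scenario_defaults()` pins the study conditions for the aging
analyses: three age groups of 40 samples with editing multipliers
(1.0, 1.0, 2.0) — editing flat through midlife, doubled in the oldest
group.

What the generator does **not** emulate: polycistronic processing,
position-dependent coverage profiles, site-specific editing-rate
heterogeneity, correlated (non-uniform) error modes such as strand-biased
damage, and linkage between clinical covariates other than through the
latent factor. Passing tests therefore show that the chain recovers known
structure under realistic noise — not that it is robust to every artifact
of real libraries.

## Statistical toolkit

* **Welch ANOVA** is implemented from its standard definition (weights
  `n_i/s_i²`, fractional denominator df) and cross-checked in the tests
  against `stats::oneway.test` to 1e-8; for two groups it reduces to the
  square of Welch's t.
* **Brown–Forsythe ANOVA** (the means test, not the Levene spread test)
  uses the `Σ(1 − n_i/N)s_i²` denominator with Satterthwaite df; no
  installed package provides it, so it is validated through its algebraic
  identities (F = t² at k = 2; F = 0 under equal means) and null
  calibration.
* **Dunnett T3** computes pairwise Welch t statistics with
  Welch–Satterthwaite df and adjusts through the studentized maximum
  modulus distribution, evaluated by numerical integration of
  `E[(2Φ(q·u) − 1)^k]` over the scaled-chi density of `u` (relative
  tolerance 1e-9, well below the 1e-6 contract). At k = 1 it equals the
  unadjusted Welch p; adjusted p-values are clamped to `[p, 1]`. Šidák
  and Bonferroni are offered as documented fallbacks.
* **Correlation panels** use pairwise-complete observations with per-row
  n reported, the t transform with n−2 df for two-sided p, and BH or
  Bonferroni adjustment via `stats::p.adjust`. Rows with fewer than 3
  complete pairs are dropped, never reported.
* **Gene retention** requires count > 0 in strictly more than half of
  the included samples; the count floor is configurable because "has
  reads" is ambiguous at low counts.
* **The intersectional analysis** defaults to raw p < 0.05 as its
  significance rule (the adjusted-p rule is a flag); the rule and alpha
  are stamped into the output.
* **Hypergeometric overlap** is the exact upper-tail probability from
  `stats::phyper`, with the odds ratio of the implied 2×2 table; the test
  suite checks it against brute-force subset enumeration for every
  configuration with N ≤ 12.

## Numerical and design choices

* Internal coordinates are 1-based inclusive; BED's 0-based half-open
  convention is converted only at the I/O boundary. GFF3 carries the
  chromosome length (`##sequence-region`) and gene class; BED6 cannot, so
  its reader takes an explicit length and the round-trip contract for BED
  covers intervals/strand/name. Origin-wrapping genes are representable
  internally (start > end) but refused by both writers.
* Bins are anchored at position 1 with no circular wrap-around merging;
  position p falls in bin `floor((p−1)/bin_size)+1`, so 16,569 nt at 200
  nt gives 83 bins with a 169-nt final bin.
* Antisense fractions are computed from coverage strata, not from calls,
  because the antisense statistic concerns reads; zero-coverage genes are
  reported as missing, never as 0.
* Degenerate inputs: zero-variance groups abort by name; a constant
  vector is reported as degenerate by the normality screen rather than
  producing an undefined W; an all-zero scaling-factor cohort aborts.
* Determinism: a cohort is a pure function of its configuration
  (including the seed); pipeline manifests carry no timestamps, so
  identical runs are checksum-identical.

## Problem sizes used by the tests

Module tests run on a 2,000-nt toy chromosome (three genes preserving the
H/L structure) with 4–10 samples per group. The end-to-end validation
suite uses the full 16,569-nt chromosome: a 10-seed exactness suite
(9 samples each), a 30-sample cohort for F1, 20 replicates of the
3 × 40 aging design for parameter recovery, a 100-sample single-group
cohort for the planted three-way association, and two full pipeline runs
for determinism. These sizes keep the whole suite in the minutes range on
a single core while leaving every estimate comfortably inside its
tolerance.

## Known limitations

* The caller sees pileups, not alignments: it cannot model mapping
  artifacts beyond quality/coverage thresholds, and per-read phasing
  (hyper-editing clusters) is out of reach.
* Distinct-site counting saturates at high coverage (see above); the
  read-weighted mode is the right choice for effect-size recovery but is
  more sensitive to depth normalization errors.
* Relative expression normalizes by library-size factors only — no
  dispersion modeling or shrinkage, which a differential-expression
  framework would add.
* The cohort SNV rule's denominator is samples with an evidence record
  at the site; a variant covered in only a few samples could in principle
  evade it, though the per-sample homoplasmy guard still applies.
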