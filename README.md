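# mtdsrna

Quantification of mitochondrial double-stranded RNA (mt-dsRNA) signatures
from strand-aware RNA-seq pileup evidence.

Both strands of the mitochondrial chromosome (ChrM) are transcribed, and
complementary transcripts can hybridize into immunogenic double-stranded
RNA. Cytoplasmic dsRNA carries a measurable footprint: ADAR-mediated
A-to-I editing, read as A>G by sequencers. This package implements the
full quantification chain for that footprint, for transcriptomics
researchers studying mitochondrial RNA homeostasis in aging and
neurodegeneration:

* a strand-aware **A-to-I editing caller** over per-position pileup
  tables, with per-sample filters (quality, coverage, support, homoplasmy
  guard) and cohort-level variant/recurrence filters;
* **ChrM scaling-factor normalization** — `sf_i = reads_i / mean_j(reads_j)`
  — with 5th–95th percentile sample QC, yielding the per-sample signature

  `signature_i = edits_i / sf_i`

  (edits counted as distinct sites or as edit-supporting reads);
* the **editing landscape**: 200-nt bins along the circular chromosome,
  per-gene edit shares, per-gene antisense-read fractions;
* **group statistics**: Shapiro–Wilk screening, Welch and Brown–Forsythe
  heteroscedastic ANOVAs, Dunnett T3 post hoc comparisons (studentized
  maximum modulus), relative-expression ratios;
* an **association suite**: gene retention ("reads in more than half of
  the subjects"), Pearson correlation panels with BH/Bonferroni control,
  three-way intersectional analysis, exact hypergeometric gene-set
  overlap;
* a **synthetic cohort generator** with complete ground truth (editing
  rates, variants, depth variability, antisense reads, coupled expression
  and clinical tables), which is how every stage is validated.

## Worked example: the aging workflow

The `analysis/` scripts run the whole study on a simulated aging cohort
(three age groups × 40 samples, 16,569-nt chromosome, old-group editing
rate doubled):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_call_editing.R
Rscript analysis/03_signature_qc.R
Rscript analysis/04_landscape.R
Rscript analysis/05_group_comparison.R
Rscript analysis/06_association.R
```

Output of the run shipped in `results/` (seed 1):

```
Simulated 120 samples in 3 groups; 234 truth edit sites, 12 homoplasmic variants.
25653 accepted calls across 120 samples.
A>G share of all candidate mismatches: 0.241 (next class 0.075)
QC: 108 of 120 samples pass the 5th-95th percentile rule.
  young   mean signature   1008.9 (SEM 49.1, n = 39)
  middle  mean signature   1036.7 (SEM 64.4, n = 34)
  old     mean signature   1966.2 (SEM 109.0, n = 35)
83 bins of 200 nt; edits conserved: TRUE.
RNR2 antisense fraction: cohort mean 0.180 (n = 120 samples)
Welch ANOVA:          F = 33.17, df = (2, 63.56), p = 1.37e-10
Brown-Forsythe ANOVA: F = 48.21, df = (2, 71.00), p = 5.96e-14
Old/young signature ratio: 1.95 (injected multiplier: 2.0)
Triple intersection: 41 genes; 39/40 from the coupled panel.
Mito-panel overlap with signature-correlated genes: k = 21, p = 4.31e-08
```

Reading this: the caller's A>G class dominates the mismatch spectrum (the
editing fingerprint); the percentile rule trims the 12 depth-aberrant
samples; the normalized signature recovers the injected two-fold old-group
effect (ratio 1.95) with decisive omnibus tests; Dunnett T3 localizes the
effect to old-vs-young and old-vs-middle; the antisense fraction of the
RNR2 analog matches the injected 18%; and the three-way intersection of
genes correlated with MMSE, Braak and the signature recovers 39 of the 40
truly coupled genes.

Programmatic use mirrors the scripts:

```r
library(mtdsrna)
cohort   <- simulate_cohort(aging_scenario_defaults(seed = 1))
callsets <- apply_cohort_filters(
  lapply(cohort$pileups, call_sample, annotation = cohort$annotation)
)
chrm <- vapply(cohort$pileups, chrm_read_total, numeric(1))
sig  <- build_signature_table(
  callsets, chrm,
  groups = setNames(cohort$clinical$group, cohort$clinical$sample_id),
  counting_mode = "edited_reads"
)
group_comparison(sig$signature[sig$qc_pass], sig$group[sig$qc_pass])
```

`run_pipeline(run_config(sim_config = aging_scenario_defaults()), "out/")`
runs all six stages with a checksum manifest; it also accepts on-disk
inputs (BED6/GFF3 annotation, pileup TSVs, expression and clinical
tables) instead of a simulation.

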