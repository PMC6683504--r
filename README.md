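# rdscreen

Genomic correlates of recurrence in chemorefractory triple-negative breast
cancer (TNBC) residual disease.

About two thirds of patients with localized TNBC harbor residual disease (RD)
after neoadjuvant chemotherapy, and roughly half of them relapse within a few
years. `rdscreen` implements, as a tested and reusable pipeline, the
correlative analyses that relate somatic genomics of RD tumors to recurrence:

* **Copy-number state calling** on a 70-gene targeted panel against
  normal-derived per-assay reference ranges (mean ± k·SD of normal genomes,
  k = 3 by default to absorb FFPE variance). States:
  `EXTENSIVE_LOSS (< 0.5) < LOSS < NORMAL < GAIN < AMPLIFIED (> 4.99 copies)`.
* **Tumor-purity correction** of variant allele frequencies and copy numbers:
  `VAF* = min(VAF / ρ, 1)` and `CN* = max((CN − 2(1 − ρ)) / ρ, 0)` for tumor
  purity ρ, and **LOH inference** as corrected-VAF skew above the normal
  heterozygosity range (default 38–59%).
* **Graduated TP53 inactivation risk strata** per patient:
  *LOW* — no TP53 mutation, or only a subclonal one (corrected VAF < 25%)
  with no second hit; *HIGH* ("compound TP53") — a mutation plus a
  compounding event (LOH or 17p/TP53 copy loss); *MODERATE* — a clonal
  mutation alone.
* **Survival machinery** — Kaplan-Meier curves, log-rank tests, Cox
  proportional-hazards hazard ratios (Efron ties, optional covariate
  adjustment for age, nodal status and RCB class) — and paired/unpaired
  lymphocyte-depletion tests.
* **A two-stage copy-number recurrence screen**: per locus, ANOVA on
  purity-corrected copy number between recurred and non-recurred patients,
  then log-rank on disease-free survival for stage-1 survivors grouped by
  gain/loss status; a locus is positive only if it passes both stages.
* **Expression analyses**: RPKM, per-gene differential expression
  (log2(RPKM+1), BH-adjusted at 10% FDR), the transcriptional-amplification
  statistic (fraction of significant genes overexpressed in the focal group —
  the MYC-activity footprint), an 18q21 cytoband-region screen, conditional
  single-gene contrasts, and a panel-detection QC fraction.
* **Matched-pair evolution**: acquired/lost variants and
  amplification-evolution/extinction events between diagnosis and surgery.
* **A seeded synthetic-cohort generator** reproducing the cohort structure
  these analyses assume (TP53/PIK3CA mutation frequencies 88%/11%, TP53 copy
  loss in 29%, MYC/MCL1 amplification in 24%/21%, BRCA2 loss in 68%,
  SMAD4-region gains, purity 0.6–1.0, proportional-hazards survival keyed to
  the risk strata, global expression up-shift in compound-TP53 tumors,
  post-chemotherapy lymphocyte depletion) with ground-truth labels, so every
  stage is testable end to end without any external download.

## Worked example

```r
library(rdscreen)

cfg <- cohort_config(n_patients = 75, seed = 20)   # trial-scale cohort
sim <- generate_cohort(cfg)
sim
#> rd_sim (seed 20): 75 patients, 16 matched pairs, expression 387 genes
#>   true strata: LOW 18, MODERATE 14, HIGH 43

ranges <- build_reference_ranges(sim$normals)                 # per-assay CN ranges
het    <- build_reference_range(sim$het_normals)              # heterozygosity range
het
#> reference_range: mean 0.4814, sd 0.03236, k = 3 -> [0.3843, 0.5785]

called <- call_cohort(sim$cohort, ranges, het_range = het)
strata <- classify_tp53(collapse_patient_tp53(called))
table(strata$stratum)
#>      LOW MODERATE     HIGH
#>       18       13       44

survival_by_stratum(called, strata)
#> survival by TP53 risk stratum: n = LOW 18, MODERATE 13, HIGH 44
#>   DFS omnibus log-rank p = 0.04229; OS p = 0.00582
#>   HIGH vs rest DFS: HR = 2.18 (95% CI 1.17-4.08), p = 0.0146; n = 75 (44 exposed)

survival_by_copy_state(called, "TP53", "loss_vs_not")
#> survival_contrast (TP53, loss_vs_not): n = 22 vs 53
#>   DFS: HR = 1.99 (95% CI 1.09-3.65), p = 0.0256; n = 75 (22 exposed)
#>   OS:  HR = 1.97 (95% CI 1.08-3.59), p = 0.0278; n = 75 (22 exposed)
```

Reading the output: one simulated misclassification aside (44 called HIGH vs
43 planted — measurement noise is on by default), the three strata separate
survival in the planted order, and patients whose tumors lost a TP53 copy
(22 of 75 here) recur at roughly twice the hazard of those who did not.

The same cohort's expression side shows the transcriptional-amplification
footprint of compound TP53 loss — every significantly differential gene is
overexpressed in the compound group:

```r
grp <- factor(ifelse(strata$compound, "compound", "other"),
              levels = c("other", "compound"))
de <- differential_expression(sim$expression, grp)
transcriptional_amplification(de)
#> $n_significant  267
#> $n_up           267
#> $up_fraction    1
```

The two-stage recurrence screen at this trial-scale n (75) returns no
positive locus — as expected, it is powered for planted effects at larger n
(see the vignette); `cnv_recurrence_screen(called)` reports per-locus stage
p-values, directions and diagnostics either way.

A config-driven end-to-end run (simulate → call → stratify → survive →
screen → express, with a `manifest.json` recording seed, config hash, input
hashes and timings):

```r
run_pipeline(list(cohort = cfg, analysis = read_pipeline_config_defaults()),
             "out/")
```

or from the shell: `Rscript inst/scripts/rd_pipeline.R --config cfg.yaml --out out/`.

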