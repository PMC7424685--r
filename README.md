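# evgate

Automated enumeration and clinical-association analysis of **circulating
tumor cells (CTCs)** and large **tumor-derived extracellular vesicles
(tdEVs)** in four-channel immunofluorescence images (DNA/DAPI,
cytokeratin-PE, CD45-APC, HER2-FITC), for researchers working with
CellSearch-style liquid biopsies.

The package covers the full chain from pixels to patient-level statistics:

1. **Detection** — per-channel segmentation (Gaussian smoothing, triangle
   threshold with a robust noise floor, half-maximum refinement,
   8-connected labeling, strict "> 4 pixel" area rule), channel merging,
   and 10 features per channel per object (area, Crofton perimeter,
   eccentricity, perimeter/area, equivalent diameter, mean/max/SD/total
   intensity, DNA-overlap fraction).
2. **Linear gating** — a declarative gate engine (conjunctions of
   `channel.feature comparator value` clauses) with a shipped six-class
   library: CTC = nucleated, CD45−, > 4 µm, CK and/or HER2 positive with
   marker–DNA overlap ≥ 0.5; tdEV = anucleate, CD45−, 1–14 µm, CK and/or
   HER2 positive; each split into CK+HER2−, CK−HER2+, CK+HER2+.
3. **Cohort statistics** — subclass fractions, immunophenotype
   heterogeneity (number of classes present above a noise threshold;
   strictly > 10 counts for tdEVs), Venn partitions, Spearman/Wilcoxon
   paired comparisons, Mann-Whitney group comparisons (tie-aware exact
   enumeration at small n).
4. **Survival** — Kaplan-Meier, log-rank, univariable Cox on
   log10(count+1) (Efron ties, via the `survival` package), and a hazard
   ratio scan over all dichotomization cutoffs with a 10% minimum group
   size.
5. **HER2 tissue prediction** — ROC curves of %HER2+CK+ fractions (AUC =
   mid-rank Mann-Whitney statistic), DeLong structural-components
   comparison of the paired CTC and tdEV curves, the sensitivity ≈
   specificity operating threshold, and accuracy stratified by minimum
   total count (≥ 1, 5, 10, 20, 50, 100).

Because real cartridge images of published cohorts are not publicly
available, `evgate` ships ground-truthed **synthetic generators**:
`simulate_image()` (PSF-blurred objects of eight archetypes, including
leukocytes and sub-resolution debris) and `simulate_cohort()`
(zero-inflated negative-binomial counts coupled by a calibrated Gaussian
copula — 15-fold CK+HER2− tdEV excess, Spearman 0.84/0.55 CTC–tdEV
correlations — proportional-hazards survival, and a latent "≥ 7 %
HER2+CK+" tissue rule observed through logistic noise). Every analysis
stage is tested against this ground truth and against independent oracles.

## Worked example

```r
library(evgate)

## image -> detection -> gating
sim <- simulate_image(image_sim_config(seed = 7))
ft  <- detect(sim$stack)
count_classes(classify(ft))
#>  ctc_ck_her2neg  ctc_ckneg_her2     ctc_ck_her2 tdev_ck_her2neg tdev_ckneg_her2
#>               4               3               3              12               6
#>    tdev_ck_her2    unclassified
#>               6              10
```

The frame was simulated with exactly 4/3/3 CTCs and 12/6/6 tdEVs of the
three phenotypes; all 34 are recovered in the correct class. The 10
unclassified objects are the planted leukocytes (CD45+), and none of the
8 sub-resolution debris particles was detected.

```r
## synthetic cohort -> paired stats, Cox, ROC
co <- simulate_cohort(cohort_sim_config(n_patients = 200, seed = 7))$cohort
pc <- paired_compare(co$ctc_ck_her2neg, co$tdev_ck_her2neg)
round(pc$spearman_rho, 3)
#> [1] 0.857                      # CTC-tdEV correlation, CK+HER2- class

cox_univariable(co$tdev_ck_her2neg, co$os_days, co$event)
#> <evg_cox_fit> HR 1.389 (95% CI 1.152-1.673), p = 0.0005602, n = 200 (145 events)

fr  <- cohort_fractions(co, "tdev")
el  <- !is.na(fr$pct_ck_her2)
roc <- roc_curve(fr$pct_ck_her2[el], co$tissue_her2[el])
roc
#> <evg_roc> AUC 0.9909 (37 positive / 133 negative, 92 thresholds)
sens_eq_spec_threshold(roc)$threshold
#> [1] 6.25                       # recovers the generator's 7% tissue rule
```

The Cox hazard ratio is per unit log10(count + 1); the generator's true
log-HR on CK+HER2− tdEVs is 0.5 (HR 1.65), and at n = 200 the estimate
1.39 lies within its Wald CI of the truth.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "evgate", package = "evgate")` with subcommands
`simulate-images`, `simulate-cohort`, `detect`, `gate`, `cohort-stats`,
`survival`, `roc`, composable through CSV/TSV/TIFF file handoffs.

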