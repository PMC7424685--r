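---
title: "Methods: CTC/tdEV enumeration and clinical association analysis"
author: "evgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTC/tdEV enumeration and clinical association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`evgate` re-implements, as a tested pipeline on synthetic data, the analysis
chain used in CellSearch-style liquid-biopsy studies of circulating tumor
cells (CTCs) and tumor-derived extracellular vesicles (tdEVs):

1. **Detection** of all fluorescent objects in four-channel frames
   (DNA/DAPI, cytokeratin-PE, CD45-APC, HER2-FITC) with per-object feature
   extraction;
2. **Linear gating** of the feature table into six immunophenotype classes
   (CTC and tdEV, each split into CK+HER2&minus;, CK&minus;HER2+, CK+HER2+);
3. **Cohort statistics**: subclass fractions, paired CTC–tdEV comparisons,
   group comparisons by tissue status, immunophenotype heterogeneity;
4. **Survival analysis**: Kaplan-Meier curves, log-rank tests, univariable
   Cox regression on log-transformed counts, and a hazard-ratio scan over
   all dichotomization cutoffs;
5. **Tissue HER2 prediction**: ROC curves of %HER2+CK+ fractions, DeLong
   comparison of the paired CTC and tdEV curves, the
   sensitivity&nbsp;&asymp;&nbsp;specificity operating threshold, and accuracy
   stratified by minimum total count.

Because the cartridge images behind published cohorts of this kind are not
publicly deposited, the package ships first-class synthetic-data generators
(`simulate_image()`, `simulate_cohort()`) whose ground truth makes every
downstream stage testable end to end. All statements below about
performance (recall, recovery, calibration) are properties the test suite
and `scripts/acceptance.R` themselves compute on this synthetic data — not
claims about any real cohort.

## The imaging model and its parameters

`simulate_image()` renders each object as an ellipse (axis ratio 1–1.3,
random orientation) blurred by a Gaussian point-spread function
(`psf_sigma`, default 1 px), on a uniform background (default 40 counts)
with Gaussian read noise (default SD 8 counts), quantized to 16-bit. The
default pixel pitch is 0.64 µm/px, a typical thumbnail scale for this
assay class. The staining level drawn for an object (per archetype, per
channel) is normalized to equal the post-blur mean intensity over the
object's true pixel mask, so recorded truth and measured mean intensities
are directly comparable; the test suite verifies this to within read-noise
standard error.

Archetypes and their signatures:

| archetype | DNA | CK | CD45 | HER2 | diameter (µm) |
|---|---|---|---|---|---|
| `ctc_ck`, `ctc_her2`, `ctc_ckher2` | + | per name | − | per name | 8–16 |
| `tdev_ck`, `tdev_her2`, `tdev_ckher2` | − | per name | − | per name | 2–8 |
| `leukocyte` | + | − | + | − | 8–12 |
| `debris` | − | dim | − | − | 0.5–0.9 |

CTC diameters respect the "> 4 µm" class rule, tdEVs the 1–14 µm range.
The DNA signal of nucleated archetypes occupies a concentric nucleus
ellipse at 0.9 of the cell's linear size, so the cytokeratin–DNA overlap
fraction of a cell is well above the 0.5 gate. Debris is sub-resolution
(below one pixel) and dim (20 counts above background): physically, a
diffraction-limited imager renders *any* point source as a blob the size of
the PSF, so the only way an object can honestly occupy "4 pixels or fewer"
in the image is to stay below the detection threshold. The default debris
level is chosen so this holds robustly, and the segmentation's explicit
area rule (below) is exercised separately with planted pixel masks.

Placement is rejection sampling with a rim-to-rim clearance of
`min_margin_um` (2 µm); if an object cannot be placed within
`max_place_attempts`, the simulator fails with an explicit overcrowding
error rather than silently violating its own separation assumption.

What the generator does **not** emulate: EpCAM enrichment physics,
cartridge-scan mosaics and illumination gradients, leukocyte morphology,
autofluorescence textures, or touching/overlapping cells (objects are
placed with clearance; the watershed splitter exists but is off by
default). Passing tests therefore demonstrate correctness of the
*pipeline*, not robustness to every artifact of real cartridges.

## Detection

`segment_channel()` applies, per channel: median background subtraction,
Gaussian smoothing (σ = 1 px), a global triangle threshold with a robust
noise floor (`min_snr` = 10 median-absolute-deviations of the smoothed
image — without the floor, a channel containing no bright object would be
thresholded inside its own noise), a per-component **half-maximum
refinement** (pixels below 0.5 × the component's smoothed maximum are
trimmed), 8-connected labeling, and removal of components with area
**strictly ≤ 4 pixels**. The half-maximum step matters: the half-max
radius of a blurred disk equals the disk's true radius, so measured areas
track physical object sizes instead of growing with the PSF; the
detection test asserts recovered disk areas within ±15% of truth. The
original multiscale segmentation of the reference software is not
described in the available text; the stage is parameterized
(`detect_params()`) so alternatives can be swapped in.

`merge_channels()` unions the per-channel masks and partitions the union
into 8-connected objects, remembering which pixels each channel
contributed (the per-channel sub-masks). Pixel coordinates are 1-based
(row, col) matrix indices throughout, the R convention.

### The ten features

For each channel, `extract_features()` reports: area (µm²), Crofton
perimeter (µm), ellipse-fit eccentricity, perimeter-to-area ratio (1/µm),
equivalent circular diameter (µm), mean / max / SD / total intensity, and
the fraction of the channel sub-mask overlapping the DNA sub-mask. Union
geometry is reported under the `object.` prefix. Definitions (documented
here because the acceptance oracle re-implements them naively):

* **Perimeter** is the 4-direction Crofton estimate
  `P = (π/4)·(Nh/2 + Nv/2 + (Nd1+Nd2)/(2√2))`, where the `N` are
  foreground/background transition counts along horizontal, vertical and
  the two diagonal scan directions (image border counts as background).
  This is exact in expectation for smooth convex shapes (a digital disk of
  radius r yields 2πr).
* **Eccentricity** comes from the eigenvalues of the pixel-coordinate
  covariance matrix with the unit-square self-moment 1/12 added, so a
  one-pixel-wide line stays strictly below 1 and a symmetric disk is
  exactly 0.
* **Intensity statistics are measured over the object's union pixel set**,
  not the per-channel sub-mask. This is a deliberate design choice: gate
  clauses must be able to express *negativity* ("HER2 mean below
  threshold") for objects that have no segmented HER2 signal at all, and a
  clause on an absent feature fails by definition. Measuring intensity on
  the union makes every intensity feature defined for every object (a
  negative channel simply reads near background), while geometric features
  remain sub-mask properties and are reported absent (`NA`) — never zero —
  when the sub-mask is empty. The DNA-overlap fraction of an empty
  sub-mask is 0.

## Gating

Gates are named conjunctions of linear inequalities over feature columns,
written `channel.feature comparator value` in a plain-text config
(`inst/extdata/default_gates.txt`); `parse_gates()` and
`serialize_gates()` round-trip exactly and unknown features are rejected
at parse time with the list of valid names. The default library encodes
the printed class definitions qualitatively:

* **CTC**: DNA mean ≥ 120 (nucleated), CD45 mean < 120, equivalent
  diameter > 4 µm (strict), CK and/or HER2 mean ≥ 150, and the positive
  marker's DNA-overlap ≥ 0.5;
* **tdEV**: DNA mean < 120 (anucleate), CD45 mean < 120, equivalent
  diameter in [1, 14] µm (inclusive), CK and/or HER2 mean ≥ 150.

The numeric thresholds of the original study's gate table are not
reproduced in the available text, so these constants are calibrated once
against the synthetic imaging model (positivity ≈ background + 10 noise
SD) and are fully user-overridable — the engine, not the constants, is
the contract. The six gates are pairwise disjoint by construction (the
DNA axis separates compartments, the CK/HER2 axes the phenotypes), which
the suite verifies both on random tables and under the
`error_on_multimatch` policy. The default policy is first-match with CTC
gates ordered before tdEV gates. CD45-positive objects and CK−HER2−
objects can match no tumor gate and fall through to `unclassified`.

## Cohort statistics

* Fractions are percentages of the compartment total and are **undefined**
  (NA, with a diagnostic) when the total is zero — never 0/0 = 0.
* Heterogeneity counts the phenotype classes whose count strictly exceeds
  a presence threshold: 0 for CTCs (presence = at least one object) and 10
  for tdEVs (counts of 10 are noise; 11 is present). `venn_partition()`
  tallies patients over the 8 presence patterns.
* `paired_compare()` reports Spearman's rank correlation (mid-rank ties,
  asymptotic two-sided p) and a Wilcoxon signed-rank test. Zero
  differences use **Pratt's method** by default (ranked, then dropped from
  the statistic) because count pairs tie at zero often; the classical
  reduced-sample convention is available and the choice is a package
  decision, not a claim about the original analysis.
* `group_compare()` is a mid-rank Mann-Whitney U. The p-value is exact by
  full enumeration of group assignments (valid under ties) whenever
  `choose(n1+n2, n1) ≤ 2e5` — enumeration beyond that is computationally
  meaningless and the normal approximation with tie correction takes over.
  No continuity correction is applied (the suite cross-checks against the
  classical test with `correct = FALSE`).
* P-values are reported raw; no multiple-testing correction is applied
  anywhere, matching the descriptive character of the analysis.

## Survival

Kaplan-Meier, log-rank and Cox fits are delegated to the `survival`
package (`survfit`, `survdiff`, `coxph` with **Efron** tie handling) behind
the package's interface; the suite validates them against hand-computed
product-limit tables, an explicit partial-likelihood oracle, and
permutation-null uniformity. Counts enter Cox models as
**log10(count + 1)** — the +1 handles zeros and the base is documented
rather than assumed from the original analysis. `cutoff_scan()`
dichotomizes at every distinct observed count (`≥ c` = "unfavorable"),
excludes cutoffs leaving either group below 10% of the cohort, fits a
binary-covariate Cox model per cutoff, and summarizes the fraction of
admissible cutoffs with p < 0.05. With no events at all the log-rank
statistic is 0 and p = 1 by convention; a constant covariate or monotone
partial likelihood yields a *flagged* fit, never a silent number.

## ROC and tissue-status prediction

`roc_curve()` uses the "score ≥ threshold → positive" convention; tied
scores share one threshold and the trapezoid AUC equals the mid-rank
Mann-Whitney identity `U/(n_pos·n_neg)` to machine precision (an
acceptance invariant). `delong_compare()` implements the
structural-components estimator of `Var(AUC_a − AUC_b)` for paired
curves with a normal two-sided p-value; identical rankings return p = 1
with an explicit flag. `sens_eq_spec_threshold()` minimizes
|sensitivity − specificity| over all thresholds, breaking ties toward the
higher specificity and then the larger threshold (the original text does
not state a tie rule). `accuracy_by_min_count()` restricts to patients
whose compartment total reaches each minimum (1, 5, 10, 20, 50, 100) and
reports sensitivity/specificity/accuracy of the "%HER2+CK+ ≥ threshold"
rule together with the eligible n. The %HER2+CK+ score counts each object
once (double positives in the numerator, all three classes in the
denominator); whether the original analysis counted double positives
once or twice is not stated, and this choice is flagged in the
documentation.

## The cohort generator

`simulate_cohort()` draws the six subclass counts from zero-inflated
negative binomial (ZINB) marginals coupled by a Gaussian copula. Defaults
encode the cohort structure the analysis assumes: CK+HER2− tdEV counts are
a rounded **15-fold** multiple of the CK+HER2− CTC distribution (so means
*and* medians scale by the fold), target Spearman correlations are 0.84
for the CK+HER2− pair and 0.55 for the two HER2+ pairs, with a 0.3
baseline correlation between all other pairs (shared tumor burden).
Because discrete zero-inflated margins attenuate rank correlations, the
latent normal correlation of each targeted pair is **calibrated** by
deterministic bisection (fixed internal seed, common random numbers,
memoised per configuration) so the simulated counts actually attain the
target; the suite checks attainment within ±0.05 at n = 5000. An
infeasible target set (non-positive-semi-definite latent matrix) fails
with an explicit error.

Survival times follow an exponential proportional-hazards model on the
log10(count+1) covariates (default: log-HR 0.5 on CK+HER2− tdEVs, 0
elsewhere; baseline hazard 1/600 per day). Censoring is independent
uniform on [0, c_max], with c_max solved so the expected censored fraction
over the realized event times equals `censoring_rate` (default 0.3).
Tissue HER2 status is Bernoulli with
`P(positive) = plogis(slope · (pct_her2ck − 7))` on the %HER2+CK+ tdEV
fraction (slope 0.8/percentage point), i.e. a latent "≥ 7%" rule observed
through logistic noise; patients with zero compartment total contribute
pct = 0. All randomness flows from the single config seed; stage-local
seeds in the CLI derive from the global `--seed` by stable string hashing
(`derive_seed()`).

CTC marginal defaults (pi0, mu, size) are (0.10, 8, 0.6), (0.25, 3, 0.6)
and (0.20, 4, 0.6) for CK+HER2−, CK−HER2+ and CK+HER2+: heavily
overdispersed counts, most patients with at least one CTC, HER2+ classes
rarer — values chosen once as a realistic regime for a metastatic cohort,
not estimates of any published dataset.

## Numerical choices and degenerate inputs

* Triangle threshold on a constant image → no objects, not an error.
* Empty feature tables and empty gates' universes propagate as 0-row
  tables with full headers.
* `NA` features fail gate clauses (objects with absent features never
  pass a gate that references them).
* Exact Mann-Whitney enumeration bound 2e5; Wald CIs on the log-HR scale;
  DeLong with zero variance and zero difference → p = 1, flagged.
* Problem sizes used by the suite and acceptance script — 50 and 20
  frames of 256×256 px, cohorts of 100–5000 patients, 200 Cox
  replicates, 500 null cohorts, 10000 bootstrap replicates — were chosen
  as the smallest sizes at which the Monte-Carlo error of each check is
  comfortably below its tolerance.

## Known limitations

* The gate thresholds are calibrated to the synthetic imaging model; real
  cartridge data will need user-supplied thresholds (the config format
  exists for exactly that purpose).
* The detector is not designed for touching cells (watershed splitting is
  available but off by default, and untested against clumped truth).
* Headline numbers of any real cohort (AUCs, thresholds, hazard ratios,
  Venn percentages) are not reproducible from synthetic data and are not
  claimed; the pipeline reproduces the *methods*, with its own measured
  values reported by `scripts/acceptance.R`.
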