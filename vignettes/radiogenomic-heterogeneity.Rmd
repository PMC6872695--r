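---
title: "Methods: genetic and metabolic tumor heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic and metabolic tumor heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpet)
```

# The scientific problem

Tumors are heterogeneous at the genetic level (subclonal populations
carrying different somatic mutations) and at the phenotypic level
(spatially uneven glucose metabolism visible on FDG PET). hetpet
implements a radiogenomic analysis for head-and-neck squamous cell
carcinoma that quantifies both, asks whether they track each other, and
tests whether each — alone and combined — stratifies overall survival.

The pipeline has five stages, each usable on its own:

1. **Genetic heterogeneity.** The mutant-allele tumor heterogeneity
   (MATH) score per tumor, from a MAF-style somatic variant table.
2. **Metabolic features.** Six features from a segmented SUV volume:
   SUVmax, SUVpeak, MTV, TLG, first-order histogram entropy, and the
   coefficient of variation (COV), after trilinear resampling to a
   common grid.
3. **Association.** Spearman rank correlation of the genomic features
   (MATH, GlycoS) against the six PET features.
4. **Stratification.** Optimized dichotomization of each feature by the
   most-significant log-rank split, and a combined two-feature risk
   group (low only when low in *both* features).
5. **Survival models.** Kaplan–Meier curves, two-group log-rank tests,
   and Cox proportional-hazards models in three forms per genomic
   feature: unadjusted; adjusted for age, sex and stage; and mutually
   adjusted for the other genomic feature plus the clinical covariates.

# Models and conventions

## MATH

With per-variant allele fractions $v_1,\dots,v_n$ (alt reads over total
reads at each mutated locus),

$$\mathrm{MATH} = 100 \times \frac{1.4826 \cdot
\mathrm{median}_i\,|v_i - \mathrm{median}(v)|}{\mathrm{median}(v)}.$$

The 1.4826 factor is the usual normal-consistency scaling of the MAD
and matches the canonical MATH definition. All usable variants enter
the statistic — no clustering or outlier trimming is applied, and there
is no depth filter by default (`min_depth` is available). Variants need
a VAF in $(0, 1]$: read counts are used when present, a precomputed
`vaf` column otherwise. Samples with fewer than `min_variants`
(default 5; MATH on very few loci is unstable) are reported as excluded
rather than dropped. MATH is invariant under positive rescaling of the
VAFs and under variant order, and is zero exactly when the MAD is zero.

## PET features

Volumes carry voxel spacing in mm; world position of 0-based voxel
$(i,j,k)$ is $\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$.
Resampling is trilinear, with the output grid spanning the input's
physical extent and edge clamping beyond the outermost voxel centers;
masks are interpolated as 0/1 fields and re-binarized at 0.5, which
preserves small-tumor volumes better than nearest-neighbour. The
clinical harmonization default is (4.7, 4.7, 3.3) mm.

* **SUVmax** — hottest masked voxel.
* **SUVpeak** — mean over voxel centers within a 1 cm³ sphere (radius
  6.2035 mm) centered on the hottest masked voxel; the sphere is
  clipped to the volume but not to the mask (PERCIST-style convention;
  no standard definition exists, so this common one was adopted).
* **MTV** — foreground voxels × voxel volume, in mL.
* **TLG** — SUVmean × MTV, exactly (tested as an identity).
* **Entropy** — $-\sum_i p(i)\log_2(p(i)+\varepsilon)$ with
  $\varepsilon = 2\times 10^{-16}$, where $p(i)$ is the fraction of
  masked voxels in intensity bin $i$. Default: 64 equal-width bins over
  the masked min–max range (a common histogram setting in clinical
  texture software); `bin_range` switches to fixed absolute SUV bounds.
  Empty bins contribute zero; a constant ROI occupies one bin and
  scores numerically zero.
* **COV** — population SD of the masked SUVs over their mean. The
  population convention (divide by $N$) is the default because COV here
  describes the voxel-value distribution, not a sampling estimate;
  `type = "sample"` is available.

A subtlety worth knowing: with min–max-relative bins, entropy is
invariant to rescaling and measures only the *shape* of the
distribution relative to its own range, so a near-constant but noisy
ROI can score high. With fixed absolute bounds (`bin_range`), narrow
uptake distributions occupy few bins and score low — the clinically
intuitive behavior, and the mode the synthetic study uses (bounds
0–25 SUV). Analytic properties (constant ROI ≈ 0 bits; a 4/4 split
across two bins = 1 bit; uniform occupancy = $\log_2 n_\mathrm{bins}$)
hold in the default mode and are tested there.

## Survival statistics

The Kaplan–Meier estimator and the two-group log-rank test
(observed−expected with hypergeometric variance, 1 df) are implemented
in-package in vectorized form — the cutoff scan below calls the
log-rank kernel hundreds of times — and are cross-checked in the test
suite against `survival::survfit()` and `survival::survdiff()`. Ties at
a time point are handled with the standard convention that events
precede censorings. Cox models are delegated to `survival::coxph()`
with the Efron tie approximation (day-resolution data produce heavy
ties), Newton iteration to a $10^{-9}$ relative tolerance, Wald 95%
intervals, and a monotone-likelihood screen that flags separated
covariates. Stage enters as a reference-coded factor with levels
I < II < III < IV (the ordinal-numeric alternative is a one-line change
at the call site); sex as a factor. Records with missing model columns
are removed listwise with a logged count.

## Optimized cutoffs and combined groups

Candidates are the midpoints between consecutive distinct sorted
feature values; each candidate splits the cohort at
`value > cutoff = "high"`; the returned cutoff maximizes the log-rank
chi-square subject to both groups holding at least `min_group_frac`
(default 0.10 — the web tools popular for this give no constraint, but
extreme splits make degenerate tests) of the cohort. The selection
makes the naive minimum p-value optimistically biased; the result
carries the full scan and a prominent multiplicity note instead of a
correction, matching how such cutoffs are used (and misused) in the
literature. Dichotomization uses strict `>` for the high group, so a
value exactly at the cutoff is "low". The combined two-feature group is
"low" only when low in both inputs and "high" otherwise; it is
symmetric and monotone.

## Association

Spearman rho is the Pearson correlation of average ranks; p-values use
the two-sided t-approximation, with an exact permutation option for
$n < 10$. Cells of the 2 × 6 genomic × PET grid use pairwise-complete
observations and report their own $n$ (in real cohorts the imaging
subset is far smaller than the survival cohort).

# The synthetic cohort generator

Because the original data require controlled-access downloads and
expert tumor segmentation, every stage is exercised on a seeded
synthetic cohort with known ground truth. `cohort_spec()` fixes the
study conditions; identical specs give identical cohorts.

**Variant tables.** Each tumor draws a latent heterogeneity score
$h \in [0,1]$. Variants (Poisson mean 80 per tumor) form a clonal VAF
cluster at 0.45 (SD 0.01) plus up to 3 subclonal clusters whose number,
share of variants (65% at $h = 1$) and spread below the clonal peak
grow with $h$. Read depth is Poisson with mean 150 (a typical exome
coverage scale); alt counts are binomial. At $h = 0$ the realized MATH
reflects binomial sampling noise only (≈ 9 on average, below 10); MATH
rises monotonically with $h$ to ≈ 55.

**Phantoms.** Tumors are ellipsoids on a 1.5 mm isotropic grid with
volumes drawn lognormally (median 1.14 mL, clipped to 0.36–3.93 mL —
the small-tumor regime of interest). Uptake is a smooth base blob
(SUV 5–12, mild radial falloff) times multiplicative log-normal speckle
whose amplitude grows with $h$, plus $h$-driven secondary hot
subregions; background sits near SUV 0.8. Higher $h$ therefore widens
the intensity distribution: COV < 0.05 at $h = 0$ and entropy
increasing in $h$ (under absolute-bound binning).

**Feature-extraction grid.** The synthetic study extracts features at
(2, 2, 2) mm rather than the (4.7, 4.7, 3.3) mm clinical default: at
72.9 mm³ per voxel a 0.36 mL tumor retains about five voxels and
histogram features degenerate. Real multi-scanner harmonization
motivates the coarse clinical grid; a single-generator cohort does not
need it.

**Coupling.** The genomic and imaging latents are rank-coupled through
a bivariate normal copula. The target `coupling_rho` refers to the
*realized* features (MATH vs entropy); measurement noise attenuates the
latent coupling by a factor calibrated once at generator-design time
(rank correlation with the latent ≈ 0.94 for MATH, ≈ 0.75 for entropy,
product ≈ 0.71), so the latent correlation is `coupling_rho / 0.71` via
the exact Spearman→Pearson map $r = 2\sin(\pi\rho_s/6)$.

**Outcomes.** GlycoS (a glycolysis gene-set score consumed as a
scalar; its upstream enrichment computation is out of scope) is
simulated from the imaging latent plus centered log-volume plus noise,
mirroring its empirically strongest associations (volumetric features,
then entropy). Survival is exponential proportional hazards with linear
predictor
$\beta_\mathrm{MATH}\,\mathrm{MATH} + \beta_\mathrm{GlycoS}\,\mathrm{GlycoS}
+ \beta_\mathrm{entropy}\,\mathrm{entropy} + \text{stage effect}$
over centered covariates and baseline median survival 633 days. The
realized MATH and entropy — computed by the package's own extractors —
enter the hazard, so downstream fits can be compared to the true
coefficients. Censoring is independent exponential, with its rate
solved (by `uniroot`) so the expected censored fraction equals
`censor_rate`. Stage probabilities (0.10, 0.12, 0.25, 0.53) keep 78% of
patients in stages III/IV; sex is 73% male; age is normal (61, 12)
clipped to 20–90 — the demographic profile of the cohort being
emulated.

**Default effect sizes.** The defaults $\beta_\mathrm{MATH} = 0.03$
per MATH unit and $\beta_\mathrm{GlycoS} = 0.5$ per GlycoS unit were
chosen once by power analysis so that a single simulated cohort of
around 500 patients shows the qualitative pattern of interest — both
genomic features significant in mutually adjusted Cox models — with
high probability, rather than the coin-flip power that the smallest
clinically reported effects would give at that size.
$\beta_\mathrm{entropy}$ defaults to 0 (no direct imaging effect); the
combined-grouping analyses plant it explicitly. The
combined-vs-single-feature comparison is run in the regime where
combining is clinically interesting — a modest per-unit MATH effect
(log HR 0.013, the scale typically reported for MATH) with a strongly
prognostic entropy effect (0.6 per bit) — because when MATH alone is
overwhelming, no added feature can improve an already astronomically
small log-rank p, and the comparison is uninformative.

## What the generator does not emulate

Scanner physics (point-spread blur, reconstruction noise correlations),
DICOM-to-SUV conversion, sequencing error and copy-number distortion of
VAFs, purity variation, and expert segmentation variability. Passing
tests therefore demonstrate internal correctness and statistical
behavior of the methods under a controlled, known-truth data-generating
process — not performance on real TCGA/TCIA data.

# Numerical choices and degenerate inputs

* Zero read depth is an error for `compute_vaf()`; zero-VAF variants
  are unusable for MATH and excluded per variant.
* A constant ROI gives entropy ≈ 0 (single bin) and COV 0; an ROI that
  vanishes under coarse resampling raises a degenerate-ROI error.
* Resampling a constant volume is exact; a linear ramp is exact at
  interior voxel centers (edge voxels are clamped).
* `suv_peak()` breaks hot-voxel ties by first array index.
* The cutoff scan breaks chi-square ties at the lowest candidate; its
  invariance to monotone feature transforms is exercised in tests.
* The log-rank variance term skips event times with a risk set of one;
  a dataset with no events raises an undefined-test error.
* `cox_fit()` refuses constant covariates and models with more terms
  than events, and flags non-convergence and monotone likelihood.
* Pipeline runs on fewer than 20 patients fail validation before any
  fitting.

# Problem sizes

The test suite and the reproduction script use cohorts of 25–499
patients, 1000-replicate oracle sweeps, 2000-replicate null
simulations for test size, 200 replicates for planted-cutoff recovery,
and 100 replicates each for Cox coefficient recovery and the
combined-grouping comparison — sizes at which the Monte-Carlo error of
each check is comfortably below its tolerance.

# Known limitations

* The naive cutoff p-value is reported uncorrected (with a warning);
  maximally-selected-statistic corrections are out of scope.
* Entropy depends on the (unstandardized) bin settings; results are
  only comparable across tumors analyzed with identical binning.
* GlycoS is consumed, never computed.
* No purity/ploidy correction of VAFs and no subclone deconvolution:
  MATH is used exactly as defined.
* Proportionality diagnostics, time-varying covariates and competing
  risks are not implemented.
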