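# hetpet

Radiogenomic analysis of tumor heterogeneity for head-and-neck squamous
cell carcinoma (HNSC): does the *genetic* heterogeneity of a tumor
(subclonal diversity of its somatic mutations) track its *metabolic*
heterogeneity on FDG PET, and do the two stratify overall survival —
separately and combined?

hetpet is for biostatisticians and imaging researchers working with
matched variant tables, PET scans and clinical follow-up. It provides
each analysis stage as a pipeable, tibble-in/tibble-out function, plus
a seeded synthetic-cohort generator with known ground truth so the full
pipeline is testable without any external data.

## The quantities at the core

**MATH (mutant-allele tumor heterogeneity).** For a tumor's variant
allele fractions $v_1,\dots,v_n$,

$$\mathrm{MATH} = 100 \times \frac{1.4826\cdot\mathrm{MAD}(v)}{\mathrm{median}(v)},$$

with the normal-consistency MAD. A single clonal VAF cluster scores
near 0; subclonal structure inflates the score.

**Six PET features** of a segmented tumor after trilinear resampling to
a common grid: SUVmax, SUVpeak (1 cm³-sphere mean at the hottest
voxel), MTV (mL), TLG = SUVmean × MTV, first-order histogram entropy
$-\sum_i p(i)\log_2(p(i)+\varepsilon)$ with $\varepsilon=2\times10^{-16}$,
and COV = SD/SUVmean.

**Survival stratification.** Each feature is dichotomized at the
most-significant log-rank cutoff (the full scan is returned, with a
multiplicity warning — the naive minimum p is biased); a combined
two-feature group is "low" only when low in *both* features. Cox
proportional-hazards models (Efron ties) are fitted unadjusted,
adjusted for age/sex/stage, and mutually adjusted for the other genomic
feature.

## Worked example

```r
library(hetpet)

# a fully synthetic 60-patient cohort: variant tables, PET phantoms,
# GlycoS, clinical covariates, survival -- all keyed by patient_id
co <- gen_cohort(cohort_spec(n_patients = 60, seed = 7))

math_per_sample(co$variants) |> head(3)
#> # A tibble: 3 x 6
#>   sample_id n_variants median_vaf mad_vaf  math excluded
#>   <chr>          <int>      <dbl>   <dbl> <dbl> <lgl>
#> 1 P0001             66      0.316  0.190   60.2 FALSE
#> 2 P0002             72      0.436  0.0570  13.1 FALSE
#> 3 P0003             63      0.436  0.0555  12.7 FALSE
```

P0001's VAFs are widely dispersed around a low median — a heavily
subclonal tumor (MATH 60.2); P0002/P0003 are dominated by one clonal
cluster near VAF 0.44 (MATH ≈ 13).

```r
report <- run_pipeline(list(synthetic = cohort_spec(n_patients = 60, seed = 7)))
report
#> <analysis_report>
#>   patients analyzed: 60
#>   correlations: MATH~entropy rho = 0.54
#>   log-rank p: MATH = 0.0133 ; MATH+entropy = 0.861 ; MATH+COV = 0.854
#>   mutually adjusted MATH HR = 1.014 ( p = 0.264 )

dplyr::filter(report$correlations, feature_a == "math")
#> # A tibble: 6 x 5
#>   feature_a feature_b        n     rho      p_value
#> 1 math      suv_max         60  0.522  0.0000186
#> 2 math      suv_peak        60  0.0820 0.534
#> 3 math      mtv_ml          60 -0.0220 0.867
#> 4 math      tlg             60  0.0525 0.690
#> 5 math      entropy_bits    60  0.540  0.00000852
#> 6 math      cov             60  0.651  0.0000000180

glance(report$cutoffs$math)
#> # A tibble: 1 x 7
#>   feature_name cutoff chi_square p_value n_low n_high n_candidates
#> 1 math           40.3       6.12  0.0133    48     12           49
```

The generator couples the genomic and imaging heterogeneity latents, so
MATH correlates with the two heterogeneity features (entropy 0.54,
COV 0.65) but not with tumor volume (MTV −0.02), which is drawn
independently. MATH's optimized cutoff (40.3, selected from 49
candidate splits) separates survival at a naive log-rank p of 0.013 —
remember that this p is biased by the maximal selection; `report$cutoffs$math$scan`
holds the full scan. At n = 60 the default generator effects leave the
mutually adjusted MATH hazard ratio (1.014 per MATH unit) short of
significance; the reproduction script below runs the study-scale
cohort. Plots: `autoplot(report$correlations)`,
`autoplot(report$cutoffs$math)`,
`plot_km_groups(...)` for the red/blue high/low curves.

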