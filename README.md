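# tissuemrs

Metabolomic profiling of intact-tissue ¹H NMR spectra, built for studies
that quantify high-resolution magic angle spinning (HRMAS) spectra of
tissue samples into normalized spectral-region intensities and then carry a
frozen statistical profile from a training cohort to a testing cohort. The
motivating application is prostate tissue: histologically benign samples
from cancer-bearing prostates carry metabolic signatures (e.g. elevated
myo-inositol near 3.60–3.63 ppm) that track tumor grade, stage, and the
risk of biochemical recurrence after prostatectomy. The package is aimed at
spectroscopists and biostatisticians who need the full chain — spectral
deconvolution, region quantification, screening, cohort transfer, and
survival endpoints — as tested, reproducible code.

## What it computes

**Spectral model.** Each resonance is a pseudo-Voigt line, the additive
height-normalized Gaussian–Lorentzian mixture

```
f(x) = A · [ η · exp(−4 ln2 (x−c)²/w²) + (1−η) / (1 + 4 (x−c)²/w²) ],
```

with center `c` (ppm), height `A`, shared FWHM `w` and Gaussian fraction
`η ∈ [0,1]`. Spectra are deconvolved by bounded nonlinear least squares
(detected lines are clustered and fitted jointly with a local constant
offset), and region intensities are *analytic* integrals of the fitted
lines: `area = A·w·[η·(1/2)√(π/ln2) + (1−η)·π/2]`.

**Quantification.** Fitted peak areas are summed over 36 named ppm regions
inside 0.5–4.5 ppm (half-open `[low, high)` intervals; configurable; a
default literature-placed table ships with the package) and expressed as
percent of the total fitted intensity, excluding contamination ranges such
as lubricant gel. The combined 3.60–3.63 ppm region is the sum of its two
member regions.

**Screening.** Each region (or principal component) is tested against
clinical targets through a distribution-gated ladder — linear regression
for continuous targets; ANOVA or Kruskal–Wallis for multi-level factors;
Student/Welch t or Mann–Whitney for binary contrasts, gated by per-group
Shapiro–Wilk and Levene tests — with Bonferroni-corrected tiers
(`***` at `0.05/36 = 0.0013` for regions, `0.05/14 = 0.0035` for PCs,
thresholds truncated to four decimals). ANCOVA (age, PSA, prostate weight)
and a patient-random-intercept mixed model guard against confounding and
repeated-sampling artifacts.

**Profile transfer.** The training cohort fixes a correlation-based PCA
(means, SDs, loadings), a subset of components selected by two-class
t-tests, and a canonical (linear) discriminant scaled to unit pooled
within-class variance. All of it is composed into one coefficient per
region and applied *frozen* to the testing cohort — no testing statistic
ever updates the model. Subgroups are flagged by a mean-minus-one-SD
threshold; recurrence curves use the stored training-mean score cut.

**Endpoints.** Kaplan–Meier product-limit curves, two-group log-rank
tests, rank-based (Mann–Whitney) ROC AUC with best-threshold overall
accuracy, and least-squares regression of survival time on discriminant
score.

**Synthetic cohorts.** Because patient spectra cannot be redistributed,
`generate_cohort()` simulates the whole study: patient covariates with
realistic marginals, grade/stage labels, clustered repeat samples, planted
region effects, rendered spectra, and recurrence outcomes driven by a
planted discriminant score through an exponential hazard.

## Worked example

```r
library(tissuemrs)

coh <- generate_cohort(n_patients = 40, seed = 7)   # 93 tissue samples
X   <- quantify_cohort(coh$spectra)                 # 93 x 37 matrix
round(X[1:3, c("3.60", "3.63", "3.60-3.63", "0.93-0.96", "1.33")], 2)
#>         3.60 3.63 3.60-3.63 0.93-0.96 1.33
#> P001_S1 1.65 5.58      7.23      3.52 6.55
#> P001_S2 1.20 4.91      6.11      6.01 9.68
#> P001_S3 1.29 4.80      6.09      3.66 7.96

rec <- coh$records
tr  <- rec$cohort == "training" & rec$tissue_class == "Hb"
res <- screen_features(X[tr, ], rec[tr, ], "pgg_high")
res[res$feature %in% c("3.60", "3.63", "3.60-3.63"),
    c("feature", "test", "p_value", "tier")]
#>      feature         test  p_value tier
#> 31      3.60 mann-whitney 0.000738  ***
#> 32      3.63       t-test 0.009435    *
#> 37 3.60-3.63       t-test 0.000967  ***
```

Each row of `X` is one tissue sample's relative intensities (percent of
total fitted 0.5–4.5 ppm intensity), so `P001_S1` puts 7.23% of its signal
in the combined myo-inositol region. The screen shows the planted
high-grade elevation of 3.60 ppm clearing the Bonferroni threshold
(p < 0.0013, tier `***`) in this cohort.

`run_pipeline(run_config(seed = 0))` chains all stages — simulation,
quantification, screening, profile training, frozen transfer, Kaplan–Meier
and ROC endpoints — and writes TSV/JSON outputs plus a machine-readable
`summary.json`.

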