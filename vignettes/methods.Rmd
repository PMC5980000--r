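---
title: "Tissue NMR metabolomic profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue NMR metabolomic profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemrs)
```

This vignette is the package's own account of the science it implements:
the spectral model and its assumptions, the statistical pipeline, the
tunable parameters and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and where a design
was genuinely open and a choice had to be made.

## The spectral model

A one-dimensional ¹H tissue spectrum is stored as an ascending ppm grid
with one intensity per point (`mrs_spectrum()`); display on the
conventional descending NMR axis is purely presentational. Each resonance
is a pseudo-Voigt line: the *additive* height-normalized mixture of a
Gaussian and a Lorentzian that share the center `c` and the full width at
half maximum `w`,

$$f(x) = A\left[\eta\, e^{-4\ln 2\,(x-c)^2/w^2}
          + (1-\eta)\frac{1}{1+4(x-c)^2/w^2}\right].$$

Both components are unit height at the center and reach half maximum at
`c ± w/2` for every mixing fraction `η`, so `A` is always the peak height
and `w` always the FWHM. Commercial fitting software differs in its
Gaussian–Lorentzian mixing convention (additive versus multiplicative
versus exponent-interpolating); the additive convention used here is a
documented package choice, not a claim about any particular vendor.

The height (not area) parameterization keeps optimizer bounds simple and
stable; areas are recovered analytically,

$$\mathrm{area} = A\,w\left[\eta\,\tfrac12\sqrt{\pi/\ln 2}
                 + (1-\eta)\,\tfrac{\pi}{2}\right],$$

which is exact for the full line including the slowly decaying Lorentzian
tails. (Numerical quadrature over any truncated window systematically
underestimates a Lorentzian: over ±50 widths the tails still hold about
0.6% of the area. Tests therefore validate areas against adaptive
quadrature over the whole line.)

### Fitting

`fit_peaks()` is bounded nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`, analytic Jacobian, cost tolerance `1e-10`, at most 500
iterations). Centers are constrained to the fitted window, `η` to [0, 1].
Default initialization seeds centers at the tallest local maxima (ties
broken toward lower ppm), widths at 0.01 ppm — a typical intact-tissue
HRMAS linewidth — and `η = 0.5`. Non-convergence is reported in the
result, never silently.

`deconvolve_spectrum()` fits a whole spectrum: it detects local maxima
above a noise floor (the larger of `5e-4` of the spectrum maximum and six
times the point-noise estimate from the median absolute successive
difference), clusters detections closer than 0.12 ppm, and fits each
cluster jointly together with a constant offset. The joint fit matters:
overlapping multiplets (e.g. the choline head-group triplet of resonances
at 3.20/3.22/3.23 ppm, or the 3.51–3.65 ppm myo-inositol group) cannot be
fitted one region at a time, because the shoulder of a neighbor inside a
narrow window biases a single-component fit badly. The constant offset
absorbs what the cluster cannot see: the quasi-flat local background from
Lorentzian tails of distant intense lines. With these choices the
noiseless round trip (render → deconvolve → integrate) recovers region
intensities to a median error of about 0.001 percentage points.

## Quantification into 36 regions

Fitted peaks are assigned to regions by their center, using half-open
`[low, high)` intervals so adjacent regions partition cleanly — a peak
centered exactly on a boundary belongs to the upper region. A region's
intensity is the sum of the analytic areas of its peaks; each sample's
intensities are normalized to percent of the total fitted area over
0.5–4.5 ppm. The denominator uses fitted peak areas rather than the raw
trapezoidal integral, which makes the relative intensities exactly
invariant under global rescaling and insensitive to baseline noise.
Excluded contamination ranges (default: 3.65–3.75 ppm, a stand-in for
biopsy lubricant gel) contribute neither to any region nor to the
denominator.

The default `default_region_table()` has exactly 36 regions. Three are
anchored by the analyses this pipeline supports — "3.60" and "3.63"
(myo-inositol, with GPC/phosphocholine/valine contributions at 3.60 ppm),
whose sum is reported as the combined "3.60-3.63" region, and "0.93-0.96"
(mobile lipids) — and the rest are placed at commonly reported tissue
resonances (lactate 1.33, choline 3.20, phosphocholine 3.22, GPC 3.23,
glutamate 2.10/2.35, glutathione 2.55, spermine 3.10, pyruvate 2.37,
citrate 2.63, lipids 1.28, …). These bounds are literature-placed
stand-ins, not a reproduction of any laboratory's calibrated table; any
custom table can be supplied as TSV or JSON.

## The synthetic cohort generator

`generate_cohort()` defines the study conditions every downstream test
runs under. Per patient it draws covariates with marginals near the kind
of prostatectomy population this pipeline targets: age 58.5 ± 6.5 years
(clamped to 41–75), PSA lognormal moment-matched to mean 5.6 / SD 3.1
ng/ml (capped at 20), prostate weight normal with mean 47.0 g and SD
12.6 g (clamped to the plausible 20.8–140.8 g range; published summaries
of such cohorts report the weight's precision as a standard error near
1 g, which at ~158 patients implies a population SD of roughly 12–13 g),
grade-group frequencies 86:52:13:4:3 over PGG 1–5, stage frequencies
56:76:26 over IIab/IIc/III, and perineural invasion 97:61. Patients are
split alternately into training and testing cohorts (a patient-level
split; all of a patient's samples stay together), and each contributes 1–4
tissue samples.

Region intensities follow a linear model on the percent scale:

* baseline mean per region (values chosen so the anchored regions sit
  near the group means the analyses expect: 3.60 ≈ 1.5, combined
  3.60–3.63 ≈ 6.5, 0.93–0.96 ≈ 4.7 in the reference groups), with
  per-region SD of 18% of the mean (floor 0.08);
* additive group effects: +0.58/+0.42 on 3.60/3.63 for PGG ≥ 3 (about one
  SD on the combined region), +1.8 on 0.93–0.96 for pT = IIc;
* a planted per-patient standard-normal discriminant score shifting the
  choline-region trio and glutamate up and myo-inositol down by roughly
  one region-SD per unit score — six moderately informative regions, the
  kind of distributed signature a canonical discriminant is meant to find;
* a per-patient, per-region random intercept (default SD = 0.5 × region
  SD) producing the within-patient clustering that motivates the mixed
  model check. The intercept is region-specific on purpose: a shock
  proportional to the whole baseline profile would largely cancel under
  compositional normalization and plant almost no clustering;
* independent Gaussian sample noise at the region SD.

Intensities are floored at 0.02 and renormalized to percent; the rendered
spectrum realizes each region's value as the area of one pseudo-Voigt peak
(FWHM 0.01 ppm, η = 0.5) at the region midpoint. The generator records the
realized normalized intensities, so the quantification round trip has an
exact per-sample truth to compare against.

Recurrence is exponential: each patient's biochemical-recurrence time has
log-hazard proportional to the planted score (default link 1.3), with
administrative censoring at 180 months and a baseline rate set so about a
quarter of patients recur at link 0. The link default was set so the
*planted* score separates recurrent from non-recurrent patients with an
AUC near 0.8 — the separability regime in which a published
tissue-metabolomic recurrence discriminant operates — before any learning
noise; the learned discriminant, trained on ~10 matched pairs, scatters
below that ceiling, as it should. Death times are a thinned (25% of
events), delayed (mean 36 months) transform of recurrence times.

What the generator does **not** emulate: real multiplet structure and
J-coupling (one line per region), chemical-shift drift and misalignment,
baseline roll and phase error, vol%-composition effects on intensities,
non-Gaussian heavy-tailed biological variation, and informative censoring.
Passing tests therefore demonstrate the *statistical machinery* is
correct and calibrated under its assumed model — not that the biology of
any real cohort is reproduced.

## Screening: gates, tiers, confounders

`choose_test()` implements the gated ladder. The normality gate is a
per-group Shapiro–Wilk test at α = 0.05; the equal-variance gate for
pooled-versus-Welch t is Levene at 0.05. (These gate levels are the
package's choice; published descriptions of such pipelines state the
gates' existence but rarely their levels.) All tests are two-sided.
Significance tiers follow the three-star notation: `*` p < 0.05, `**`
p < 0.005, `***` past Bonferroni. The Bonferroni threshold is α/m
*truncated* — not rounded — to four decimals for reporting (0.05/36 =
0.001388… reports as 0.0013, 0.05/14 as 0.0035), with the raw value kept
internally; truncation is the convention that matches the three-star
thresholds as customarily printed.

Constant features report p = 1 with a degenerate flag: no variance, no
evidence. Missing metadata is handled by listwise deletion per test, with
the retained n reported. `ancova_adjust()` tests the group factor by the
nested-model F-test in `feature ~ group + age + PSA + weight` and refuses
covariate matrices with condition number above 1e10.
`repeated_measures_check()` fits a patient-random-intercept model
(`lmerTest`, Satterthwaite); when the variance component collapses to zero
or every patient has one sample, it falls back to aggregating samples to
patient means — which reproduces the ordinary test exactly in the
one-sample-per-patient case.

## The frozen profile and its transfer

PCA is computed on the correlation scale: training columns are z-scored by
training mean and SD, then decomposed by SVD. Transferring "means, SDs and
loading coefficients" to a testing cohort is only meaningful if
standardization happened in training — that is the rationale for
correlation rather than covariance PCA. Sign indeterminacy is resolved by
orienting each loading column so its largest-magnitude entry is positive.

For the recurrence discriminant, `select_pcs()` ranks retained components
by two-sided Student t-tests between event and event-free cases and keeps
the k = 5 smallest (ties toward the lower index) — five components being
the default because that is the scale at which such discriminants are
typically built from ~14 retained PCs. `fit_canonical()` is the two-class
canonical direction `w ∝ S_pooled⁻¹ (μ₁ − μ₀)`, scaled to unit pooled
within-class variance, oriented so the event class scores higher, and
offset so the grand mean score is zero. With scores centered at zero by
construction, the recurrence-curve split threshold *is* the training mean
score; it is stored in the model and never recomputed on testing data. A
ridge of 1e-8 of the mean diagonal is added only if the pooled covariance
is numerically singular, and is logged.

`compose_region_coefficients()` folds standardization, loadings and
canonical weights into one coefficient per region,
`coef_r = Σ_k w_k L_{rk} / sd_r`, so that
`score = Σ_r coef_r (x_r − mean_r) + offset` reproduces the
PCA-then-discriminant scores to machine precision — these composed
coefficients are the transferable form of the profile. The whole model
serializes to a versioned JSON document; applying it never mutates it
(verified by byte comparison in tests).

The mean-minus-SD threshold (`msd_threshold()`) flags values *strictly*
below `mean − 1·SD` of a stated reference set. On a standard normal
reference the flagged fraction converges to Φ(−1) ≈ 15.9%. A constant
reference degrades gracefully: threshold at the mean, nothing flagged,
with a warning.

The PSA combination is a two-feature linear discriminant on
(canonical score, PSA) with the same conventions — the combination method
is a package choice; published reports of such combinations rarely state
the functional form.

## Endpoints

Kaplan–Meier estimation and the two-group log-rank test wrap the
`survival` package (events before censorings at tied times); Greenwood
standard errors are stored with each curve even though displays rarely
show bands — they are cheap and useful. ROC AUC uses the rank
(Mann–Whitney) formulation with midrank tie handling, validated in tests
against brute-force concordant-pair counting; "overall accuracy" is
defined as the best achievable (TP+TN)/n over all score thresholds,
because the customary headline accuracy of such discriminants is a
best-operating-point figure and no prespecified cut is available.
Score-versus-survival uses ordinary least squares with the Pearson
correlation and its two-sided p.

## Numerical choices and degenerate inputs

* Optimizer tolerances 1e-10 (cost and parameters), 500 iterations;
  analytic Jacobian throughout.
* Half-open region membership; boundary peaks go to the upper region.
* Ties in peak seeding: equal-height maxima resolved toward lower ppm.
* Zero-variance regions are dropped from PCA with a warning; constant
  screening features are flagged, not tested.
* Degenerate discriminants (identical class means) are errors, not
  silent zeros.
* Empty cohorts quantify to an empty matrix without error; unconverged
  samples are flagged and the pipeline continues.
* All randomness flows from explicit integer seeds; the cohort is a pure
  function of (configuration, seed).

## Problem sizes used by the tests

The test suite and the acceptance script run the pipeline at the scale the
package documents as its default study design: 160 patients across both
cohorts (~400 tissue samples) for end-to-end runs, an 80-patient cohort
for the rendering round trip, 500 replicates for the null-calibration of
the family-wise `***` rate, and 100 replicates for the power checks
(planted one-SD effect at n = 200; hazard ratio 3 at 60 per arm). These
sizes were chosen to match the cohort scale the design emulates while
keeping every simulation comfortably reproducible on a laptop.

## Known limitations

* The default region table and the excluded lubricant range are
  literature-placed stand-ins; real studies must supply their calibrated
  table.
* One pseudo-Voigt line per region in the generator means region
  integration is easier than on real multiplet-rich spectra; fit-quality
  conclusions transfer only qualitatively.
* The canonical discriminant is trained on matched pairs (~10 per
  cohort), so its testing-cohort performance has large sampling
  variance — an honest property of the design it implements, visible in
  the seed-to-seed spread of the acceptance numbers.
* No Cox modeling, no FDR control (Bonferroni only), no cross-validation:
  the design is a single frozen train→test split by construction.
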