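---
title: "Methods: from bead fluorescence to responder biology in microtumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bead fluorescence to responder biology in microtumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmtools)
```

pdmtools implements the computational side of a patient-derived-microtumor
(PDM) profiling study in breast cancer: bead-array western blot signal
processing, cytotoxicity-based drug-responder classification, brightfield
stain quantification, and the downstream cohort statistics. This vignette
explains the models and procedures, the parameters that matter, the
synthetic-data generator that stands in for patient data, and the design
choices taken where the underlying methodology left room.

## Bead-array western blot signal processing

In the assay, each protein lane is cut into 96 strips of equal width, each
strip eluted onto a distinct bead colour, and the beads probed with an
antibody; the readout is one median fluorescence value per bead colour, i.e.
per molecular-weight fraction. The pipeline reconstructs the "virtual lane"
(`reconstruct_lane()`) by mapping fraction indices onto apparent molecular
weight through a strictly monotone calibration table. Gel migration is close
to linear in log(MW), so the default calibration
(`default_mw_calibration()`) is log-spaced from 260 down to 10 kDa.
Calibration is supplied as a table; fitting it from a protein ladder is out
of scope.

A protein appears as a peak around its expected MW. `integrate_peak()`
quantifies it in three steps:

1. **Peak location** — the maximum within the search window
   `expected MW ± window half-width`; ties break towards the fraction
   closest to the expected MW (deterministic).
2. **Local background** — a straight line anchored at the mean intensity of
   the two fractions flanking each window edge. This is the simplest model
   that is *exactly* invariant to constant and linearly drifting baselines,
   which is the property the downstream statistics rely on. (A rolling-
   minimum background was considered and rejected: it is biased low under
   noise and not exactly linear-invariant.)
3. **Integration** — trapezoidal integral of the background-subtracted
   intensities over the window, on the fraction grid (unit spacing), with
   negative contributions clamped at zero and the result floored at zero.
   The unit is fluorescence × fraction, the AFI.

The default window half-width is 15% of the expected MW (proportional
windows track the log-spaced axis), widened to cover at least two fractions
on either side. Note that a 15% window spans roughly ±2.7 peak standard
deviations for a typical peak width of 1.5 fractions, so ~1.5% of the peak
mass is truncated; supply an explicit `window_kda` (the synthetic generator
emits ±4.5 sd windows) when sub-percent accuracy matters.

The matrix stages enforce a one-way **scale tag** ordering — `raw_afi` →
`total_normalized` → `log2` / `median_centered` — so no stage can be re-run
on its own output:

* `normalize_total_protein()` multiplies each sample column by
  (cohort median total protein) / (sample total); the median rescaling keeps
  values on the raw AFI scale and makes equal loading a no-op.
* `impute_weak_signals()` sets cells that are zero, missing, or flagged
  below limit to "lower detection limit minus one", where the limit is the
  smallest strictly positive value of that analyte across the cohort. The
  limit is data-defined and per-analyte because antibodies differ widely in
  brightness; whether the original instrument defined it differently is not
  knowable from the outside. Imputed values (and afterwards all values) are
  floored at 1 so the log2 transform is defined and non-negative.
* `log2_transform()` / `median_center_log2()` produce the two analysis
  scales: plain log2 values for between-sample mean comparisons and
  correlations, and per-analyte median-centered log2 values (median over a
  recorded scope — all samples, or the PDMs only) for volcano, clustering
  and panel analyses. After centering, the per-analyte median over the scope
  is zero to within 1e-9 by construction.

## Drug-responder classification

Cytotoxicity plates carry 3–5 replicate wells per condition, measured as RFU
(signal proportional to cell death) at 24/48/72 h, with vehicle controls and
optional medium-only blanks. `fold_changes()` subtracts the blank mean
(matched by sample, drug and timepoint when present), clamps corrected
readings at 1e-6 of the vehicle mean (readings below background would
otherwise produce negative or undefined fold changes), and divides by the
vehicle mean of the same timepoint. Vehicle wells get their own fold
changes, which average exactly 1 per timepoint.

Outliers are removed by the Iglewicz–Hoaglin modified Z-score
`M = 0.6745 (x − median)/MAD` at the recommended cut-off 3.5, applied within
one (sample, drug, condition, timepoint) cell — the smallest exchangeable
unit. When the MAD collapses to zero the mean-absolute-deviation fallback
`M = (x − median)/(1.253314 MeanAD)` is used; if both scales are zero
nothing can be an outlier. Two caveats are worth knowing. First, the
median/MAD pair breaks down at 50% contamination: with five replicate wells,
a cell containing three or more corrupted wells will protect the corrupted
majority, so recall of injected ×5 artifacts is capped near 95% when the
per-measurement contamination rate reaches 10%; at the 5% rate used in the
package's own validation runs (a realistic artifact prevalence for plate
readers) expected recall is ≈ 98.5%. Second, trimming clean cells slightly
shrinks the residual variance of the subsequent model fit, which makes the
per-timepoint tests mildly anti-conservative (see below).

`fit_treatment_model()` fits, per sample × drug,

```
fold_change ~ condition * timepoint + (1 | well)
```

by REML (lme4), with condition and timepoint categorical and a random
intercept per replicate well — the repeated-measure unit across the time
series, the only random structure this design supports. Per-timepoint
treatment − vehicle contrasts use model-based standard errors and residual
degrees of freedom with *no* multiplicity adjustment (Fisher's uncorrected
LSD, as the method prescribes). When the well variance estimates to zero the
fit sits on the boundary and coincides with ordinary least squares (flagged
`reml (degenerate to ols)`); if the fit fails outright, per-timepoint Welch
t-tests are used and flagged.

`classify_response()` labels a sample a **responder** when at least one
timepoint shows p < 0.05 *and* a positive effect — the assay signal is
proportional to cell death, so a significant decrease is not a response.
Both the "any timepoint" rule and the direction requirement are exposed as
arguments. Because three uncorrected looks are taken and outlier trimming
shrinks the variance estimate, the null call rate of this procedure is not
5% but of the order of 12–15% — a property of the published procedure
itself, which users should keep in mind when interpreting small responder
counts. An alternative mode (`against = "unity"`) tests the treatment fold
changes against the constant 1 instead of the vehicle wells.

## Stain quantification

`color_deconvolve()` implements Beer–Lambert unmixing: per pixel,
`OD_c = −log10(max(I_c, 1)/I0_c)` and concentrations are the optical
densities expressed in the basis of the stain matrix (rows = unit-norm stain
OD vectors; with two stains the third basis vector is the normalized cross
product and its map collects residual density). The inversion is exact on
noise-free forward-model images; near-collinear stain matrices (condition
number ≥ 1e6) are rejected. Published constants ship for hematoxylin, eosin
and DAB (`stain_preset()`); the Movat collagen stain has no published
vector, so `fit_stain_vector()` estimates one as the mean unit OD vector of
user-marked pure-stain pixels — the interactive step of the original
workflow made explicit and reproducible.

`area_fraction()` scores the percentage of pixels (optionally within a
selection mask) strictly above a threshold. The original analyses used
manual thresholds in an interactive tool; the default here is Otsu's
criterion computed on the empirical histogram of the concentration map (256
bins over the observed range), and the threshold actually applied is always
recorded in the result. A fixed numeric threshold reproduces the manual
workflow when needed. Live/dead viability uses voxel thresholding instead of
proprietary 3D surface reconstruction; the downstream quantity — channel
intensity sum per µm³ of model volume (`viability_normalize()`) — is
unchanged.

## Cohort statistics

* `pearson_pairs()` — matched PDM/PTT Pearson correlations at three levels:
  per-analyte means across tissues (computed on *uncentered* log2 values;
  centering would strip the between-analyte variation the quantity measures),
  per protein across pairs, and per pair across analytes. p-values use the t
  transform; coefficients with fewer than 3 points are omitted with a
  warning.
* `welch_volcano()` — per-analyte unpaired Welch t-tests on log2 values with
  the two-stage adaptive FDR of Benjamini, Krieger & Yekutieli; significant
  means q below the FDR level (0.05, i.e. −log10(q) > 1.3) *and*
  |log2 FC| ≥ 1. The tests are unpaired, matching the original analysis,
  even though the cohort is matched; a paired mode exists behind the
  `paired` flag.
* `bky_fdr()` — both stages of the two-stage procedure run at the level
  q/(1+q), per the procedure's original definition; stage 1 estimates the
  number of true nulls from its rejection count and stage 2 rescales by
  m/m̂0. Because the procedure defines a rejection set rather than q-values,
  the reported q-value is the smallest level at which the test is rejected,
  found by bisection (40 iterations, resolution ~1e-12).
* `mw_u_test()` / `signed_rank_test()` — exact for small tie-free samples,
  tie-corrected normal approximation otherwise (mid-ranks).
* `anova_holm_sidak()` — ANOVA with all pairwise contrasts on the pooled
  residual variance, Holm–Šídák step-down adjusted
  (`1 − (1 − p_(i))^(m−i+1)` with running maximum).
* `hcl_cluster()` — agglomerative clustering with complete or average
  linkage on euclidean (default, matching the displayed value scale) or
  1 − correlation distance; `hclust`'s deterministic tie-breaking gives
  reproducible trees.
* `logistic_response_model()` — simple logistic regression of responder
  status on one analyte's centered log2 signal; "one unit" therefore means a
  2-fold protein change (a per-SD mode is available). Odds ratio, Wald 95%
  CI and p, and a likelihood-ratio p against the intercept-only model are
  reported. Complete or quasi-separation (non-convergence, |β| > 15 or
  SE > 10) is flagged and no finite CI is reported — unstable Wald
  intervals under separation are misleading and deliberately withheld.
* `panel_compare()` — pools every (panel analyte, sample) centered value
  into its sample's response group and applies an unpaired Mann–Whitney U
  test (plus per-analyte tests), checking the expected direction: resistance
  panels higher in non-responders, sensitivity panels higher in responders.
  Panel membership is a configuration input, not a computed quantity.

## The synthetic cohort generator

No patient data ship with the package; `simulate_digiwest_cohort()`,
`simulate_cytotox_plate()`, `simulate_stain_image()` and
`simulate_viability()` generate every input the pipeline consumes, with
ground truth attached, under a single integer seed (identical configs are
bit-identical; the session RNG is left untouched).

The profiling generator's defaults are the study conditions: 20 matched
PDM/PTT pairs, 142 analytes, and a target per-protein correlation of 0.44
(the cohort's median). Latent log2 abundances follow a shared-component
model — pair members share `z ~ N(0, ρ)` plus independent `N(0, 1−ρ)`
deviations on a per-analyte mean with SD 1 — so the per-protein correlation
across pairs approaches the target; abundances are lognormal on the linear
scale, keeping them positive under multiplicative noise. Eight analytes act
as immune-cell markers and are attenuated by 1.5 log2 units in the PDM
members (microtumors carry few infiltrating immune cells); additional
subtype- or tissue-specific effects are configurable. Each lane carries one
Gaussian peak (SD 1.5 fractions) at the analyte's expected MW with area =
latent abundance × loading factor, over a constant baseline (20) with 5%
multiplicative noise; per-sample total protein has a 20% CV. The noise
magnitudes are plausible for a bead-array readout but are not instrument
measurements — they were chosen once for realism, and the property tests
are designed to be stable under them.

The cytotoxicity generator draws vehicle wells around a baseline RFU with
lognormal noise, scales treated wells of true responders by a factor growing
linearly over the time series up to `effect_size` at 72 h, injects ×5
multiplicative outliers at a configurable per-measurement rate, and includes
blank wells. The viability generator draws model volumes uniformly and
normalized intensities lognormally around the configured live/dead ratio.
The stain-image generator synthesizes Beer–Lambert images with spatially
disjoint stain blocks at the stated area fractions plus additive Gaussian
pixel noise.

What the generator deliberately does **not** emulate: multi-band/isoform
antibodies (one peak per lane), antibody cross-reactivity, spatial texture
or morphology in images (stain regions are disjoint blocks), plate drift
across instruments, and missingness mechanisms other than weak signal.
Passing tests therefore demonstrate correctness of the computations under
the stated statistical structure — not robustness to every artifact of real
instruments.

## Validation problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) runs
the responder null at 500 simulated samples, responder recovery at 150
samples (effect size 3, 5% noise, 5% outliers), FDR rejection-set checks on
1000 random p-value vectors, logistic recovery on 500 replicates of n = 100,
and the profiling cohort at the full 20 × 142 default. These sizes give
Monte-Carlo error comfortably below the tolerances being checked.

## Known limitations

* The responder procedure's per-sample null rate (~12–15%, see above) is a
  property of uncorrected multi-timepoint looks; panels or ORs built on few
  samples inherit that softness.
* AFI accuracy depends on the window actually covering the peak; analytes
  whose true migration deviates from the expected MW by more than the window
  half-width are quantified as background.
* The two-stage FDR q-values are procedure-derived (smallest rejecting
  level) and need not be monotone in p across different input vectors.
* Logistic fits on small responder groups readily separate; flagged fits
  report no CI by design.
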