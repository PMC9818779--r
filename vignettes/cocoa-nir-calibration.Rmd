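---
title: "Calibrating cocoa bean quality traits from NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cocoa bean quality traits from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoanir)
```

## The problem

Commercial cocoa beans are traded on quality attributes -- fat, protein,
dry matter (DM), ash, total phenolic content (TPC), fermentation index
(FI), pH and titratable acidity (TA) -- that are conventionally measured by
slow, destructive wet chemistry. Near-infrared (NIR) spectroscopy offers a
rapid, non-destructive alternative: overtone and combination vibrations of
C--H, O--H and N--H bonds between roughly 850 and 2500 nm carry
quantitative information about the major constituents, and a multivariate
calibration maps a bean's absorbance spectrum to each trait.

`cocoanir` implements the full calibration workflow for this setting: two
instrument geometries (a benchtop monochromator at 850--2500 nm every
0.5 nm and a portable device at 900--1680 nm every 2 nm, on both whole
beans and de-husked ground powder), spectral preprocessing, three
calibration engines, cross-validated evaluation with outlier culling,
forward interval-PLS wavelength selection, the arithmetic of the
wet-chemistry reference assays, and a seeded synthetic spectra generator so
that every stage is testable without instrument data.

## Data model

A `spectral_dataset` holds the absorbance matrix (samples x wavelengths,
log(1/R) units), the strictly increasing wavelength grid, unique sample
ids, a reference table of laboratory values, the instrument profile and the
preparation (`whole` or `ground`). Spectra are stored as absorbance even
though acquisition is in reflectance mode; `read_spectra_csv(...,
reflectance = TRUE)` converts at ingest via `A = log10(1/R)`, because all
band interpretation downstream is in absorption terms. Missing reference
values are allowed per constituent: a sample lacking, say, a TPC value is
excluded from the TPC calibration only, which is why the retained N varies
by constituent in the reports.

## Preprocessing

A *math treatment* is a scatter correction plus a four-digit derivative
code `d,g,s1,s2` (derivative order, gap in points, two smoothing widths in
points), written exactly as practitioners write it: `0,0,1,1`, `1,4,4,1`,
`2,5,5,1`.

* **SNV** centers each spectrum and scales it to unit sample SD.
* **SNV_DT** follows SNV with subtraction of the least-squares quadratic in
  wavelength and then re-standardizes to unit SD. The final rescaling is a
  deliberate convention: it preserves the SNV property after the baseline is
  removed and makes the composite exactly idempotent, which in turn makes the
  treatment safe to reason about in tests. Without it, a second application
  would rescale the spectrum by the residual SD.
* **MSC** regresses each spectrum on a reference spectrum and inverts the
  fitted affine map. The reference is the mean spectrum of the calibration
  set -- the canonical choice -- and is frozen into the fitted model so that
  later predictions reuse the calibration reference rather than the new
  batch's mean.

The gap-segment derivative applies the central difference
`x[i + g] - x[i - g]` `d` times, then two centered moving averages. The
codes under-specify the stencil, so one convention is fixed and documented:
central differences with edge truncation (no padding), and even smoothing
widths use the window `[i - s/2, i + s/2 - 1]`. Every operation reports the
retained wavelength sub-grid explicitly, so model coefficients always align
with real wavelengths. Scatter correction is applied before the derivative;
the reverse order is also seen in practice, but one order had to be fixed
and scatter-first matches the way the corrections are derived (they model
raw, not differentiated, spectra).

## Calibration engines

All engines center the spectra columns and the response; spectra are never
variance-scaled globally (the NIR convention -- band intensities are
informative). Prediction is always `y_mean + (x - x_mean) %*% b`.

* `fit_pls()` -- NIPALS PLS1 with per-factor deflation of X and y.
* `fit_mpls()` -- "modified PLS" in the Shenk--Westerhaus sense: identical
  to NIPALS except that after each factor's deflation the residual columns
  are standardized by their residual SDs before the next factor is
  extracted. The accumulated scalings are folded back into a single
  regression vector, so prediction needs no sequential transformation.
  Columns whose residual SD collapses below 1e-12 have their scale frozen
  at 1 rather than erroring. This definition was an open choice -- the name
  "modified PLS" is used without definition in the applied literature --
  and the per-factor residual standardization is the meaning documented for
  the commercial software that popularized it.
* `fit_pcr()` -- regression on the first k principal-component scores.

Factor counts are capped at `min(16, n - 6)` to prevent overfit at
calibration sizes near 50, and selected by 5-fold cross-validation with a
parsimony rule: the smallest k whose SECV is within 2% of the minimum.
Loadings are exported unit-norm with the largest-magnitude element made
positive, so serialized models are reproducible across platforms.

One empirical note, visible in the test suite: on raw synthetic spectra
with i.i.d. noise, MPLS cross-validates measurably worse than PLS at equal
k, because standardizing residual columns amplifies channels that carry no
signal. On scatter-corrected spectra, where channel scales are comparable,
the two engines agree within a few percent. The engine comparison test is
therefore run on treated spectra; both behaviours are properties of the
algorithms, not implementation artifacts (the MPLS path is verified to
machine precision against a literal sequential implementation).

## Evaluation

`compute_metrics()` uses SEC with calibration degrees of freedom
`N - 1 - k`, SECV with `N - 1`, R-squared as `1 - SSE/SST` clamped to
[0, 1] (not a squared correlation), and RPD = reference SD / SECV. The
interpretation bands follow the published cut-offs: R2cv at or above 0.91
is excellent, 0.82--0.91 good, 0.66--0.82 approximate, below 0.66 poor
(values in the unstated gaps 0.81--0.82 and 0.90--0.91 resolve to the
lower band); RPD above 2.5 is adequate for analytical use, below 1.5
unsatisfactory.

Outliers are culled by the T-statistic rule: samples whose cross-validated
prediction differs from the reference by more than 2.5 residual SDs are
dropped, the model refit, and the rule applied once more (two passes at
most). Whether culling happened before or inside the final cross-validation
was not specified in the workflow this package systematizes; here the
pipeline culls on CV residuals and then reruns a final CV on the retained
set, which is stated explicitly so reports are comparable.

`grid_search()` runs the full 3 scatter x 3 derivative-code grid per
constituent and picks the SECV-minimizing cell; `run_pipeline()` does this
for all eight traits and emits report, grid, loading and manifest files.
The default cross-validation seed (20221220) is an arbitrary fixed
constant so every report is bit-reproducible.

`ipls_forward()` splits the grid into 30 contiguous intervals (remainder
points to the last interval: the 391-point portable grid gives 29 intervals
of 13 points and one of 14), fits one cross-validated model per interval,
and selects the RMSECV minimizer. The forward continuation -- greedily
adding the interval that most reduces RMSECV until no addition improves it
-- is standard forward-mode practice; `steps = "one"` preserves the
minimal single-step selection.

## Wet-chemistry module

Only the arithmetic of the reference assays is implemented (the ovens,
digesters and extractors are out of scope): FI = A460/A530 with the strict
FI > 1 well-fermented rule; protein = 6.25 x Kjeldahl nitrogen;
Folin--Ciocalteu TPC through a gallic-acid standard line and the assay's
dilution geometry (0.05 g defatted powder in 10 mL extract, 0.1 mL aliquot
in a 4.6 mL assay mixture), the single place that geometry is encoded;
TA = M x V x (extract/aliquot) x (100/powder), which is 4V at the assay
defaults, with percent acetic acid (x 60.05/1000) as a secondary unit; DM
and moisture as exact complements; shell percent from de-husking weights;
and descriptive statistics (SD with n - 1, CV = 100 SD/mean). TPC is
reported per as-weighed defatted powder; a dry-mass correction of the
extract basis would be a second-order refinement the source assays do not
specify.

## The synthetic generator

`synthetic_spec()` defines a study: n = 56 samples by default, constituent
distributions equal to the published descriptive table (means, SDs,
truncation at the observed min/max), and spectra built as Beer--Lambert
mixtures of Gaussian component bands plus a fixed gentle baseline and
0.002 AU i.i.d. noise (ground mode). Whole-bean mode adds per-sample
multiplicative scatter (SD 0.15), additive offsets (SD 0.05), a wavelength
slope, a smooth broadband interference component uncorrelated with
composition (emulating shell reflection), and doubled noise.

Band centers follow standard assignments (lipid C--H at 1210/1725/1744/
2320 nm, water O--H at 1450/1930 nm, protein N--H/amide at 1500/2057/
2130 nm, a phenolic band at 1420 nm, carbohydrate at 2100 nm). Beyond
those five components the library adds deliberately weak bands for acids,
pH, ash and FI. This is a generator design decision: traits with no
spectral signal at all would be unpredictable in *both* modes, so the
clean-versus-degraded contrast that the whole-bean experiment is about
could not be expressed for them. Intensities were chosen once so that the
clean-mode difficulty ordering matches what practitioners see -- fat,
protein and DM strong (R2cv above 0.9), pH/TA/ash intermediate, TPC and FI
weak -- and then frozen. They are configuration values, not claims about
real extinction coefficients.

Correlations: fat--TPC -0.3 (fat dilutes the non-fat solids where
polyphenols concentrate), FI--TPC -0.4 (fermentation consumes
anthocyanin-related phenolics), pH--TA -0.7 (acids). Each constituent's
standard-normal stream has its own derived seed, so adding a constituent
leaves the others' draws unchanged.

What passing tests on this generator do show: the pipeline recovers known
linear composition-to-spectrum maps through realistic preprocessing,
scatter corrections recover scatter-corrupted data exactly, and the
whole-bean degradation reproduces the qualitative ground-beats-whole
finding. What they do not show: performance on real beans, whose particle
physics, moisture-dependent band shifts and correlated instrument noise
the linear generator does not emulate. The published R2cv values for real
samples are therefore not reproduction targets; only internally derivable
quantities (RPD identities, unit conversions) are checked against printed
numbers.

## Problem sizes and runtime choices

The bundled study size is n = 56 samples. Unit tests run on 8--30-sample
subsets of the same generator; the end-to-end recovery checks and the
acceptance script use the full n = 56 on the 3301-point benchtop grid,
where the complete 9-cell grid search over all eight constituents in both
modes takes a couple of minutes on one core. Preprocessing and the NIPALS
factor loop are vectorized matrix operations; the per-spectrum functions
(`snv()`, `msc()`, `gap_derivative()`, ...) are the documented reference
forms and the matrix paths are tested to agree with them to machine
precision.

## Known limitations

* The generator is linear; nonlinear particle-size effects are represented
  only through the affine scatter terms that SNV/MSC can remove.
* MPLS follows one published definition of residual standardization;
  other implementations may differ in detail, so coefficient-level
  comparisons across software are not meaningful (prediction-level ones
  are).
* The interval-PLS continuation uses greedy forward selection; it does not
  revisit earlier choices.
* Serialization stores the final regression vector, not the per-factor
  path, so a reloaded model predicts identically but cannot be re-truncated
  to fewer factors.
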