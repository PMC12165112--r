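---
title: "Methods: single-EV TIRF quantification and cohort classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-EV TIRF quantification and cohort classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtirf)
```

## The measurement model

An antibody-functionalised biochip captures extracellular vesicles (EVs)
from serum or plasma; molecular beacons report a target mRNA and labelled
antibodies report a surface protein. Under TIRF illumination only the
surface-proximal layer fluoresces, so each probe-positive captured vesicle
appears as a diffraction-limited spot. A well is imaged as an array of
fields (100 in the reference protocol, each covering 80 × 80 µm), every
clinical sample is measured in two wells, and the assay readout is the
Total Fluorescence Intensity (TFI): the summed net spot intensity over all
fields of a well, averaged over the sample's wells.

Because the chip is operated in capture saturation (EV input 10–100-fold
above surface capacity), TFI reflects the per-vesicle marker load of the
captured subpopulation rather than the particle concentration of the
specimen.

## Image quantification

`quantify_field()` chains four steps; each is exposed separately.

**Denoising.** `denoise_field()` computes an undecimated à-trous wavelet
decomposition with the separable B3-spline kernel (1,4,6,4,1)/16 — the
standard multiscale transform for fluorescence spot detection — over 3
scales by default. Detail coefficients below `threshold_k = 3` times the
level-wise robust scale (median absolute deviation about zero) are zeroed
and the field is reconstructed. The pixel noise SD is estimated from the
finest detail plane, dividing its MAD estimate by the plane's analytic
white-noise response (computed once by decomposing a unit impulse); on pure
Gaussian noise this recovers the true SD well within 15%.

**Detection.** `detect_spots()` thresholds the denoised image at
`detect_k = 3` noise SDs above a robust local background and segments the
exceedances into 8-connected components. The background is the à-trous
coarse plane re-estimated with sigma-clipping (bright pixels replaced by
the running background before re-smoothing), which stops spot flux from
inflating the background beneath the spot. For noise-free images the
threshold would degenerate to the background plane itself, so a small
relative prominence floor (0.5% of the peak background-subtracted
intensity) keeps it strictly positive; with realistic noise the floor is
inactive. A consequence worth knowing: in noiseless data, spots fainter
than ~0.5% of the brightest spot in the same field fall below the floor,
so oracle-style tests use a moderate amplitude spread.

**Photometry.** `measure_spots()` always measures the *raw* image —
detection masks come from the denoised image, but wavelet shrinkage would
bias intensities, so it never touches the measurement. For each mask,
`mean_in` is the mean raw intensity over the mask and `mean_surround` the
mean over a surrounding annulus (1 px guard gap, 2 px width, Chebyshev
metric), excluding pixels of any other spot and pixels outside the field;
`net_intensity = (mean_in − mean_surround) × pixel_count`. The published
description of this step subtracts in the opposite order, which would make
every signal negative; the only physically meaningful sign (in-spot minus
surround) is implemented. Subtracting the surround *mean* scaled by the
area makes every net intensity exactly invariant to a uniform background
offset, which the tests verify to below 1e-6 relative.

**Filtering.** `filter_spots()` keeps spots with area in
`[min_area_px, max_area_px]` (defaults 2–50 px at 0.15625 µm/px) and
positive net intensity. Negative-net spots are noise fluctuations; keeping
them could make TFI negative. The reference assay states that a spot-size
cutoff was used without giving values, so both bounds are configuration.

With these defaults, a noiseless well is quantified at the exact true spot
count and at 98–99% of the injected amplitude (a 3σ detection contour
carries 98.9% of a Gaussian spot's mass), and detection at SNR 10 achieves
≥ 98% recall and precision against the generator's ground truth.

## Calibration and LOD

`fit_calibration()` regresses log10 mean TFI on log10 spiked concentration
by OLS over the concentrations at or above the limit of detection, using
replicate means (three replicates in the reference calibration) as
responses. Because spiked series sit on a healthy-donor matrix signal, the
blank mean is subtracted before the log transform by default. The LOD rule
is the conventional one for dilution series — the lowest tested
concentration whose mean response exceeds blank mean + 3·SD — adopted
because the assay reports LODs without stating its rule.
`tfi_to_equivalents()` inverts the fitted line and flags conversions
outside the fitted range as extrapolated. Saturation of the capture
surface is modelled (and simulated) as a Langmuir roll-off
`C_eff = C·K/(C+K)`; fitting should exclude saturated top points via
`fit_range`, and the round-trip tests confirm the slope is then recovered
within ±0.05.

## Cutoffs, subtype calls, diagnostic panels

All decision rules use *strict* inequality (a value exactly at a cutoff is
negative), applied uniformly.

* **Whisker cutoff** (transcription factors): the largest control (HRS)
  value within the Tukey fences Q1 − 1.5·IQR and Q3 + 1.5·IQR. Quartiles
  use linear interpolation (R type 7) by default; the convention is
  configurable because box-plot software differs and the reference assay
  does not state one.
* **Subtype call**: ratios r = TFI/cutoff for ASCL1, NEUROD1, POU2F3; the
  positive set is every factor with r > 1; the primary label is the factor
  with the largest ratio, ties breaking in the fixed order A > N > P, and
  an empty positive set is SCLC-I. How multi-positive samples should be
  resolved is not specified by the assay's description; largest-ratio with
  a fixed tie-break is deterministic and keeps the full positive set in
  the output.
* **spec100 cutoff** (DLL3 markers): the control maximum — the smallest
  threshold with zero control positives under the strict rule, hence
  specificity exactly 100% on the deriving controls by construction. This
  is an in-sample guarantee, not an estimate of out-of-sample specificity.
* **Dual DLL3 call**: H/L per marker, categories HH/HL/LH/LL, positive
  unless LL.
* **Panel combination**: how the reference analysis fused panels into one
  ROC is not stated. The default `max_log_ratio` scores a sample by the
  largest log2 TFI/cutoff ratio over the panel — the continuous analogue
  of the any-marker-high rule, threshold-free and monotone-invariant — and
  a maximum-likelihood logistic combination is available for comparison,
  falling back with a warning under separation.

`roc_auc()` computes the AUC by the tie-corrected rank formula (ties count
one half), which is identical to the trapezoidal area and satisfies
AUC·n₁·n₀ = U; `mann_whitney()` enumerates all label assignments exactly
for total n ≤ 12 (at most 924 arrangements) and otherwise uses the
tie-corrected normal approximation without continuity correction, which
holds the type-I error at 0.05 ± 0.02 in the package's null simulations.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth; it emulates the *structure* the analysis assumes, not any
patient dataset.

* **Fields**: a Poisson number of spots per field, uniform positions (a
  minimum-separation option supports non-overlapping designs), log-normal
  integrated amplitudes, a pixel-integrated isotropic Gaussian PSF
  (σ = 1.3 px), flat background, optional Poisson shot noise and Gaussian
  read noise. Pixel-integrated rendering makes the noiseless pixel sum
  equal the injected amplitude to rounding, which is what the oracle tests
  lean on. Seeds are split into named substreams so adding fields never
  perturbs earlier draws, and every output is bit-reproducible from
  (config, seed).
* **Spike-in series**: expected TFI = baseline + 10^intercept · C_eff^slope
  with Langmuir C_eff, log-normal replicate noise, Gaussian baseline.
* **Cohorts**: per-sample log10 TFI vectors are multivariate normal
  (log-normal TFI — natural for a sum of positive spot intensities
  spanning decades; the assay states no distribution), with an
  exchangeable correlation of 0.2 across markers by default. SCLC samples
  draw a latent subtype with prevalences 0.539/0.197/0.211/0.053 and
  receive +0.8 log10 on their defining transcription factor, A/N subtypes
  additionally +0.5 on exosomal DLL3 mRNA. Within-group SD defaults to
  0.25 log10 units; group mean shifts for the DLL3 markers (+0.10
  exosomal mRNA; +0.05 limited-stage and +0.15 extensive-stage protein)
  were set so the one-marker binormal AUCs Φ(Δμ/(σ√2)) fall in the ranges
  reported for this class of assay — clear mRNA separation, weak protein
  separation that grows with stage. These defaults are qualitative: no
  patient-level TFI table is public, so they are chosen once as plausible
  study conditions and are not tuned to reproduce any published figure.

What passing tests show — and do not show. The generator's fields have a
single PSF width, flat background and uncorrelated noise; real TIRF data
add flat-field structure, drift, out-of-focus haze and camera artefacts
(EMCCD gain noise is explicitly out of scope). Cohorts are exactly
log-normal with homogeneous within-group variance. Green tests therefore
demonstrate algorithmic correctness under the stated model, not clinical
performance.

## Numerical choices and problem sizes

* Quartile convention type 7; boundary values are non-outliers (closed
  fences).
* Wavelet noise factors are computed once per level count and cached.
* Connected components are labelled by deterministic minimum-label
  propagation; component ids follow raster order.
* Spots whose annulus is entirely excluded (crowding, image edge) are
  dropped and counted, not imputed.
* An exactly constant field denoises to itself with noise SD 0, and empty
  wells give TFI 0 with no spots.
* Test and demonstration sizes: oracle wells use 128 px fields at
  80 µm/128 so that 100-field wells and 20-well batches remain quick on a
  laptop; statistical checks use n = 1000–2000 per group, 1000-replicate
  null simulations, and 5-cohort averages for closed-form AUC
  comparisons. These sizes put Monte Carlo error well inside each test's
  tolerance band.

## Known limitations

* No drift or flat-field correction, colocalization, or photobleaching
  step counting; vendor microscopy formats are not read (multi-page TIFF
  only, 16-bit with a JSON sidecar on output).
* The calibration module fits a single log-log line (no 4PL/5PL), and
  uncertainty is limited to OLS machinery.
* AUCs are point estimates (no DeLong intervals); survival analysis and
  YAP1/SCLC-Y subtyping are out of scope.
* The spec100 specificity guarantee is in-sample; a fresh control cohort
  will generally show specificity below 100%.
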