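# evtirf

Single-vesicle TIRF quantification and EV-based liquid-biopsy
classification for small cell lung cancer (SCLC).

Antibody-sorted extracellular-vesicle (EV) biochips read out tumour markers
by imaging individually captured vesicles with total internal reflection
fluorescence (TIRF) microscopy: each captured vesicle carrying the probed
mRNA (molecular-beacon signal) or surface protein (labelled-antibody
signal) appears as a diffraction-limited bright spot. `evtirf` implements
the complete computational side of such an assay for R users — from raw
field images to patient-level diagnostic calls:

1. **Image quantification** (`denoise_field()`, `detect_spots()`,
   `measure_spots()`, `filter_spots()`, `well_tfi()`, `sample_tfi()`) —
   undecimated à-trous B3-spline wavelet denoising, thresholding at
   *k*·σ̂ above a robust local background, 8-connected segmentation,
   annulus-based spot photometry on the raw image, and spot-size filtering.
   The net intensity of a spot is
   `(mean_in − mean_surround) × area`, and a well's **Total Fluorescence
   Intensity** (TFI) is the sum over all retained spots in its fields
   (100 per well in the reference protocol, two wells per sample).
2. **Calibration** (`estimate_lod()`, `fit_calibration()`,
   `tfi_to_equivalents()`) — log–log OLS of TFI against spike-in EV
   concentration, a blank-mean + 3·SD limit of detection, and inversion of
   the curve into EV-equivalents per mL.
3. **Cutoffs and classification** (`derive_cutoffs()`, `assign_subtype()`,
   `dual_marker_call()`, `combined_score()`, `roc_auc()`,
   `mann_whitney()`, `classify_cohort()`) — Tukey-whisker cutoffs from
   high-risk-smoker (HRS) controls for the subtype transcription factors
   ASCL1/NEUROD1/POU2F3 (sample subtype = largest TFI/cutoff ratio above
   1, else SCLC-I), 100%-specificity cutoffs for the DLL3 exosomal-mRNA /
   tumour-EV-protein dual marker, multi-marker panel scores, and
   tie-corrected ROC/AUC and Mann–Whitney statistics.
4. **Synthetic data** (`simulate_field()`, `simulate_well()`,
   `simulate_spikein_series()`, `simulate_cohort()`) — TIRF fields with
   known per-spot ground truth, spike-in dilution series with Langmuir
   capture saturation, and multi-marker cohorts with latent subtypes, so
   every stage is testable end to end.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Quantify a simulated well and check it against the generator's truth:

```r
library(evtirf)

cfg <- field_sim_config(image_size_px = 128, pixel_size_um = 80 / 128,
                        spot_count_mean = 10, amplitude_log10_sd = 0.25,
                        background_level = 50, min_separation_px = 14)
well <- simulate_well(cfg, n_fields = 20, seed = 42)
res  <- well_tfi(well$fields, quant_config(min_area_px = 1, max_area_px = Inf))
res
#> # A tibble: 1 × 5
#>   well_id marker      tfi n_fields n_spots
#>   <chr>   <chr>     <dbl>    <int>   <int>
#> 1 well1   unknown 224264.       20     208
well$true_tfi
#> [1] 226877.6
```

The recovered TFI is 98.8% of the injected amplitude — the small deficit is
the PSF mass outside the detection masks (a 3σ mask carries 98.9% of a
Gaussian spot).

Fit a spike-in calibration and classify a synthetic cohort:

```r
ser <- simulate_spikein_series(spike_series_config(), seed = 1)
fit_calibration(ser)
#> <calibration_fit>
#>   log10(TFI - blank) = -3.0428 + 1.0090 * log10(C)   (r^2 = 0.9999)
#>   LOD = 1e+06 particles/mL; fit over 5 concentrations [1e+06, 1e+10]

cohort <- simulate_cohort(cohort_sim_config(), seed = 1)
report <- classify_cohort(cohort)
report
#> <cohort_report>
#>   76 SCLC samples subtyped vs 45-sample HRS control
#>   subtype frequencies: A 60.5%, N 15.8%, P 15.8%, I 7.9%
#>   panel AUCs:
#>     DLL3_exo_mRNA      LS_vs_HRS    AUC 0.939
#>     DLL3_exo_mRNA      ES_vs_HRS    AUC 0.896
#>     DLL3_tEV_mProtein  LS_vs_HRS    AUC 0.473
#>     DLL3_tEV_mProtein  ES_vs_HRS    AUC 0.679
#>     dual_DLL3          LS_vs_HRS    AUC 0.895
#>     ...
#>     full_classifier    ES_vs_HRS    AUC 0.951
```

The printed frequencies are the subtype calls of this one 76-patient
synthetic draw; `glance(report)` returns the full panel-by-comparison
performance table and `autoplot(report)` draws the subtype ratio heatmap.

A thin command-line front end over the same functions ships in
`inst/cli/evtirf.R` (`simulate-fields`, `simulate-cohort`, `quantify`,
`calibrate`, `cutoffs`, `classify`, `run`).

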