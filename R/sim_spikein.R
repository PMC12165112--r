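#' Configuration for a simulated spike-in calibration series
#'
#' Models the TFI response to a dilution series of tumour-cell-derived EVs
#' spiked into a healthy-donor EV matrix: log-log linear in the
#' sub-saturation regime with a Langmuir roll-off at high concentration
#' (the chip has finite capture capacity), sitting on a healthy-donor
#' baseline signal.
#'
#' Expected TFI at concentration C (particles/mL) is
#' `baseline + 10^intercept * (C * K / (C + K))^slope`, with `K = Inf`
#' disabling saturation. Replicate noise is log-normal on the spike
#' component; the baseline is drawn per replicate as
#' `Normal(baseline_tfi_mean, baseline_tfi_sd)` truncated at 0.
#'
#' @param concentrations Strictly positive, ascending particles-per-mL grid.
#' @param response_slope Log-log slope (default 1).
#' @param response_intercept_log10 Log10 TFI at 1 particle/mL, sub-saturation.
#' @param saturation_k Langmuir half-capacity concentration; `Inf` disables.
#' @param baseline_tfi_mean,baseline_tfi_sd Healthy-donor baseline TFI.
#' @param replicates Replicates per concentration (default 3).
#' @param rep_noise_log10_sd Log10 sd of replicate noise on the spike signal.
#' @param n_blanks Blank (zero-spike) replicates (default 3).
#'
#' @return A `spike_series_config` list.
#' @export
spike_series_config <- function(concentrations = 10^seq(6, 10, by = 1),
                                response_slope = 1,
                                response_intercept_log10 = -3,
                                saturation_k = Inf,
                                baseline_tfi_mean = 100,
                                baseline_tfi_sd = 10,
                                replicates = 3L,
                                rep_noise_log10_sd = 0.05,
                                n_blanks = 3L) {
  if (length(concentrations) < 1L) {
    config_error("`concentrations` must be non-empty")
  }
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    config_error("`concentrations` must be strictly positive and ascending")
  }
  assert_scalar_num(response_slope, "response_slope")
  assert_scalar_num(response_intercept_log10, "response_intercept_log10")
  assert_scalar_num(saturation_k, "saturation_k", lower = 0, allow_inf = TRUE)
  assert_scalar_num(baseline_tfi_mean, "baseline_tfi_mean", lower = 0)
  assert_scalar_num(baseline_tfi_sd, "baseline_tfi_sd", lower = 0)
  if (replicates < 1L) config_error("`replicates` must be >= 1")
  assert_scalar_num(rep_noise_log10_sd, "rep_noise_log10_sd", lower = 0)
  structure(
    list(concentrations = as.numeric(concentrations),
         response_slope = response_slope,
         response_intercept_log10 = response_intercept_log10,
         saturation_k = saturation_k,
         baseline_tfi_mean = baseline_tfi_mean,
         baseline_tfi_sd = baseline_tfi_sd,
         replicates = as.integer(replicates),
         rep_noise_log10_sd = rep_noise_log10_sd,
         n_blanks = as.integer(n_blanks)),
    class = "spike_series_config"
  )
}

# Noiseless expected spike signal (baseline excluded).
expected_spike_tfi <- function(cfg, conc) {
  c_eff <- if (is.finite(cfg$saturation_k)) {
    conc * cfg$saturation_k / (conc + cfg$saturation_k)
  } else {
    conc
  }
  10^cfg$response_intercept_log10 * c_eff^cfg$response_slope
}

#' Simulate a spike-in calibration series
#'
#' @param cfg A [spike_series_config()].
#' @param seed Integer seed.
#'
#' @return A tibble with columns `concentration` (0 for blanks),
#'   `replicate`, `tfi`.
#' @export
simulate_spikein_series <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "spike_series_config"))
  with_seed(derive_seed(seed, "spikein"), {
    blanks <- pmax(rnorm(cfg$n_blanks, cfg$baseline_tfi_mean,
                         cfg$baseline_tfi_sd), 0)
    rows <- tidyr::expand_grid(concentration = cfg$concentrations,
                               replicate = seq_len(cfg$replicates))
    spike <- expected_spike_tfi(cfg, rows$concentration) *
      10^rnorm(nrow(rows), 0, cfg$rep_noise_log10_sd)
    base <- pmax(rnorm(nrow(rows), cfg$baseline_tfi_mean,
                       cfg$baseline_tfi_sd), 0)
    bind_rows(
      tibble(concentration = 0, replicate = seq_len(cfg$n_blanks),
             tfi = blanks),
      mutate(rows, tfi = base + spike)
    )
  })
}
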