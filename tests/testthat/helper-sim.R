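# Shared fixtures: small, fast simulation configs and a truth matcher.

# Compact noiseless field: 128 px covering an 80 um field, widely separated
# spots, moderate amplitude spread so every spot clears the adaptive
# detection floor.
oracle_field_config <- function(...) {
  args <- list(
    image_size_px = 128L, pixel_size_um = 80 / 128,
    spot_count_mean = 12, amplitude_log10_mean = 3,
    amplitude_log10_sd = 0.25, background_level = 50,
    min_separation_px = 14
  )
  args[names(list(...))] <- list(...)
  do.call(field_sim_config, args)
}

# SNR-10 noisy field: peak amplitude = 10 * read noise sd.
snr10_field_config <- function(read_noise_sd = 8, ...) {
  peak_amp <- 10 * read_noise_sd * 2 * pi * 1.3^2
  args <- list(
    image_size_px = 256L, spot_count_mean = 30,
    amplitude_log10_mean = log10(peak_amp), amplitude_log10_sd = 0,
    background_level = 100, read_noise_sd = read_noise_sd,
    min_separation_px = 8
  )
  args[names(list(...))] <- list(...)
  do.call(field_sim_config, args)
}

# Greedy nearest match of detected spots to ground truth within tol px;
# returns counts for recall/precision.
match_spots <- function(truth, detected, tol_px = 2) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(detected))) {
    d <- sqrt((truth$x_px - detected$x_px[i])^2 +
              (truth$y_px - detected$y_px[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_px) {
      used[j] <- TRUE; tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!used),
       recall = tp / nrow(truth), precision = tp / max(tp + fp, 1L))
}

# Cohort config with no group separation and no subtype shifts (null case).
null_cohort_config <- function(n, markers = c("M1", "M2")) {
  mu <- matrix(4, 3, length(markers),
               dimnames = list(c("HRS", "LS", "ES"), markers))
  cohort_sim_config(
    n_per_group = c(HRS = n, LS = n, ES = 0L), markers = markers,
    log10_tfi_mean = mu, log10_tfi_sd = 0.3,
    subtype_shift_log10 = list(A = numeric(0), N = numeric(0),
                               P = numeric(0), I = numeric(0)),
    inter_marker_corr = 0
  )
}
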