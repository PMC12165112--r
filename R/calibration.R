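#' Limit of detection of a calibration series
#'
#' The LOD is the lowest tested spike concentration whose replicate-mean TFI
#' exceeds the blank mean plus three blank standard deviations — the
#' conventional 3-sigma rule for a spike-in dilution series.
#'
#' @param series Calibration tibble with columns `concentration` (0 marks
#'   blank replicates), `replicate`, `tfi` (see [simulate_spikein_series()]).
#'
#' @return The LOD in particles per mL. If no tested concentration clears
#'   the blank criterion, `Inf` is returned (above tested range).
#' @export
estimate_lod <- function(series) {
  blanks <- series$tfi[series$concentration == 0]
  if (length(blanks) < 2L) {
    input_error("need at least 2 blank replicates for the LOD")
  }
  crit <- mean(blanks) + 3 * stats::sd(blanks)
  means <- series %>%
    filter(.data$concentration > 0) %>%
    group_by(.data$concentration) %>%
    summarise(mean_tfi = mean(.data$tfi), .groups = "drop") %>%
    arrange(.data$concentration)
  ok <- means$mean_tfi > crit
  if (!any(ok)) return(Inf)
  means$concentration[which(ok)[1L]]
}

#' Fit a log-log calibration curve
#'
#' Ordinary least squares of `log10(TFI)` (optionally after subtracting the
#' blank mean, since spiked series sit on a healthy-donor background) on
#' `log10(concentration)`, using replicate means as responses over the
#' concentrations at or above the LOD.
#'
#' @param series Calibration tibble (see [estimate_lod()]).
#' @param subtract_baseline Subtract the blank-mean TFI before the log
#'   transform (default `TRUE`).
#' @param fit_range Optional numeric vector of concentrations to fit on;
#'   defaults to every tested concentration at or above the LOD. Use this to
#'   exclude a saturated top point.
#'
#' @return A `calibration_fit` object with elements `slope`, `intercept`,
#'   `r_squared`, `lod`, `fit_range`, `blank_mean`, `blank_sd`,
#'   `subtract_baseline`, `n_points`.
#' @export
fit_calibration <- function(series, subtract_baseline = TRUE,
                            fit_range = NULL) {
  assert_flag(subtract_baseline, "subtract_baseline")
  blanks <- series$tfi[series$concentration == 0]
  if (length(blanks) < 2L) {
    input_error("need at least 2 blank replicates")
  }
  blank_mean <- mean(blanks); blank_sd <- stats::sd(blanks)
  lod <- estimate_lod(series)
  means <- series %>%
    filter(.data$concentration > 0) %>%
    group_by(.data$concentration) %>%
    summarise(mean_tfi = mean(.data$tfi), .groups = "drop") %>%
    arrange(.data$concentration)
  if (is.null(fit_range)) {
    fit_range <- means$concentration[means$concentration >= lod]
  }
  pts <- means %>% filter(.data$concentration %in% fit_range)
  resp <- if (subtract_baseline) pts$mean_tfi - blank_mean else pts$mean_tfi
  bad <- resp <= 0
  if (any(bad)) {
    warn(sprintf(
      "fit_calibration: dropping %d point(s) with non-positive %sTFI",
      sum(bad), if (subtract_baseline) "baseline-subtracted " else ""))
    pts <- pts[!bad, , drop = FALSE]; resp <- resp[!bad]
  }
  if (nrow(pts) < 2L) {
    abort("fewer than 2 usable calibration points at or above the LOD",
          class = "evtirf_fit_error")
  }
  fit <- lm(log10(resp) ~ log10(pts$concentration))
  # r^2 computed directly so an exactly linear series does not warn
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log10(resp) - mean(log10(resp)))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = max(0, min(1, r2)), lod = lod,
         fit_range = pts$concentration, blank_mean = blank_mean,
         blank_sd = blank_sd, subtract_baseline = subtract_baseline,
         n_points = nrow(pts)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  log10(TFI%s) = %.4f + %.4f * log10(C)   (r^2 = %.4f)\n",
              if (x$subtract_baseline) " - blank" else "",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  LOD = %s particles/mL; fit over %d concentrations [%s, %s]\n",
              format(x$lod), x$n_points, format(min(x$fit_range)),
              format(max(x$fit_range))))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_calibration
#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         lod = x$lod, blank_mean = x$blank_mean, blank_sd = x$blank_sd,
         n_points = x$n_points)
}

#' Convert TFI values to spike-equivalent concentrations
#'
#' Inverts the fitted calibration line:
#' `C = 10^((log10(TFI_adj) - intercept) / slope)`, flagging conversions that
#' fall outside the fitted concentration range as extrapolated.
#'
#' @param fit A [fit_calibration()] result.
#' @param tfi Numeric vector of TFI values.
#'
#' @return A tibble with `tfi`, `equivalents` (particles/mL) and
#'   `extrapolated`.
#' @export
tfi_to_equivalents <- function(fit, tfi) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) {
    abort("cannot invert a calibration with zero slope",
          class = "evtirf_conversion_error")
  }
  adj <- if (fit$subtract_baseline) tfi - fit$blank_mean else tfi
  if (any(adj <= 0)) {
    input_error("TFI must exceed the blank mean for conversion")
  }
  eq <- 10^((log10(adj) - fit$intercept) / fit$slope)
  tibble(tfi = tfi, equivalents = eq,
         extrapolated = eq < min(fit$fit_range) | eq > max(fit$fit_range))
}
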