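#' Tukey box-plot fences
#'
#' Quartiles by linear interpolation (R's default type-7 convention unless
#' overridden), fences at 1.5 interquartile ranges beyond the quartiles, and
#' the subset of values within the fences (non-outliers).
#'
#' @param values Numeric vector, at least 4 values.
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7).
#'
#' @return A list: `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`,
#'   `non_outliers`.
#' @export
tukey_fences <- function(values, quantile_type = 7L) {
  if (length(values) < 4L) {
    input_error("need at least 4 values for Tukey fences")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    input_error("`values` must be finite")
  }
  q <- quantile(values, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - 1.5 * iqr
  upper <- q[2L] + 1.5 * iqr
  list(q1 = q[1L], q3 = q[2L], iqr = iqr,
       lower_fence = lower, upper_fence = upper,
       non_outliers = values[values >= lower & values <= upper])
}

#' Whisker-based control cutoff
#'
#' The decision cutoff used for the subtype transcription factors: the
#' highest control (HRS) TFI after excluding box-plot outliers, i.e. the
#' maximum of the values within the Tukey fences.
#'
#' @inheritParams tukey_fences
#' @return The cutoff (a single number).
#' @export
derive_cutoff_whisker <- function(values, quantile_type = 7L) {
  max(tukey_fences(values, quantile_type)$non_outliers)
}

#' 100%-specificity control cutoff
#'
#' The decision cutoff used for the DLL3 diagnostic markers: the smallest
#' threshold with zero positives among the deriving controls under the
#' strict rule (positive iff value > cutoff), i.e. the control maximum.
#' By construction the specificity at this cutoff is exactly 1 on the
#' controls it was derived from.
#'
#' @param values Numeric vector of control TFIs (non-empty).
#' @return The cutoff (a single number).
#' @export
derive_cutoff_spec100 <- function(values) {
  if (length(values) < 1L) input_error("`values` must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) {
    input_error("`values` must be finite")
  }
  max(values)
}

#' Derive the full per-marker cutoff set from a cohort's controls
#'
#' Whisker cutoffs for the transcription-factor markers and
#' 100%-specificity cutoffs for the diagnostic markers, both computed on the
#' control group.
#'
#' @param cohort Cohort tibble (`sample_id`, `group`, marker columns).
#' @param whisker_markers Markers cut by [derive_cutoff_whisker()].
#' @param spec100_markers Markers cut by [derive_cutoff_spec100()].
#' @param control_group Group label of the controls (default `"HRS"`).
#' @param quantile_type Quartile convention for the whisker rule.
#'
#' @return A tibble with `marker`, `cutoff`, `method`, `control_group`,
#'   `n_controls`.
#' @export
derive_cutoffs <- function(cohort,
                           whisker_markers = c("ASCL1", "NEUROD1", "POU2F3"),
                           spec100_markers = c("DLL3_exo_mRNA",
                                               "DLL3_tEV_mProtein"),
                           control_group = "HRS",
                           quantile_type = 7L) {
  if (!all(c("group", whisker_markers, spec100_markers) %in% names(cohort))) {
    input_error("cohort is missing required columns")
  }
  controls <- dplyr::filter(cohort, .data$group == control_group)
  if (nrow(controls) == 0L) {
    input_error(sprintf("no samples in control group '%s'", control_group))
  }
  bind_rows(
    purrr::map(whisker_markers, function(mk) {
      tibble(marker = mk,
             cutoff = derive_cutoff_whisker(controls[[mk]], quantile_type),
             method = "whisker_max", control_group = control_group,
             n_controls = nrow(controls))
    }),
    purrr::map(spec100_markers, function(mk) {
      tibble(marker = mk, cutoff = derive_cutoff_spec100(controls[[mk]]),
             method = "spec100", control_group = control_group,
             n_controls = nrow(controls))
    })
  )
}
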