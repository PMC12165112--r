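#' Quantification settings for the TIRF pipeline
#'
#' Bundles every tunable of the image-analysis chain
#' (denoise -> detect -> measure -> filter) with the package defaults.
#' The reference protocol leaves most of these unstated, so they are all
#' exposed here.
#'
#' @param levels Wavelet scales for denoising.
#' @param threshold_k Wavelet hard-threshold multiplier.
#' @param detect_k Detection threshold in noise-sd units.
#' @param connectivity Connected-component connectivity (8 or 4).
#' @param min_area_px,max_area_px Spot-size cutoff in pixels.
#' @param annulus_gap_px,annulus_width_px Local-background annulus geometry.
#' @param min_prominence Absolute detection floor; `NULL` for the adaptive
#'   default (see [detect_spots()]).
#' @param cv_limit Between-well coefficient-of-variation QC limit used by
#'   [sample_tfi()].
#'
#' @return A `quant_config` list.
#' @export
quant_config <- function(levels = 3L, threshold_k = 3, detect_k = 3,
                         connectivity = 8L, min_area_px = 2L,
                         max_area_px = 50L, annulus_gap_px = 1L,
                         annulus_width_px = 2L, min_prominence = NULL,
                         cv_limit = 0.5) {
  structure(
    list(levels = as.integer(levels), threshold_k = threshold_k,
         detect_k = detect_k, connectivity = as.integer(connectivity),
         min_area_px = min_area_px, max_area_px = max_area_px,
         annulus_gap_px = annulus_gap_px, annulus_width_px = annulus_width_px,
         min_prominence = min_prominence, cv_limit = cv_limit),
    class = "quant_config"
  )
}

#' Quantify one field: denoise, detect, measure, filter
#'
#' @param field A raw [tirf_field()].
#' @param config A [quant_config()].
#' @return Retained spot tibble for the field (see [measure_spots()]).
#' @export
quantify_field <- function(field, config = quant_config()) {
  den <- denoise_field(field, levels = config$levels,
                       threshold_k = config$threshold_k)
  masks <- detect_spots(den$field, den$noise_sd, detect_k = config$detect_k,
                        connectivity = config$connectivity,
                        min_prominence = config$min_prominence)
  rec <- measure_spots(field, masks,
                       annulus_gap_px = config$annulus_gap_px,
                       annulus_width_px = config$annulus_width_px)
  filter_spots(rec, config$min_area_px, config$max_area_px)
}

#' Total fluorescence intensity of a well
#'
#' Runs the quantification chain on every field of a well and sums the net
#' intensities of all retained spots: the well's Total Fluorescence
#' Intensity (TFI). In the reference protocol a well is 100 TIRF fields.
#'
#' @param fields List of raw [tirf_field()] objects (one well).
#' @param config A [quant_config()].
#' @param well_id Identifier recorded in the output.
#'
#' @return A one-row tibble: `well_id`, `marker`, `tfi`, `n_fields`,
#'   `n_spots`, with the full per-spot table in attribute `spots`.
#' @export
well_tfi <- function(fields, config = quant_config(), well_id = "well1") {
  if (length(fields) < 1L) input_error("need at least one field")
  stopifnot(all(vapply(fields, is_tirf_field, logical(1))))
  channels <- unique(vapply(fields, function(f) f$channel, character(1)))
  if (length(channels) > 1L) {
    input_error(sprintf("mixed channels in one well: %s",
                        paste(channels, collapse = ", ")))
  }
  spots <- purrr::map(fields, quantify_field, config = config) %>% bind_rows()
  out <- tibble(
    well_id = well_id, marker = channels,
    tfi = if (nrow(spots)) sum(spots$net_intensity) else 0,
    n_fields = length(fields), n_spots = nrow(spots)
  )
  attr(out, "spots") <- spots
  out
}

#' Per-sample TFI from replicate wells
#'
#' Each clinical sample is measured in two wells on a biochip; the sample
#' TFI is the arithmetic mean of the well TFIs. A QC flag is raised when the
#' between-well coefficient of variation exceeds `cv_limit`.
#'
#' @param wells Tibble of well rows (from [well_tfi()]) or a numeric vector
#'   of well TFIs.
#' @param sample_id,group Sample identifier and group label
#'   (`HRS`, `LS`, `ES`, `HD`, `cell_line` or `unknown`).
#' @param marker Marker label; taken from `wells` when it is a tibble.
#' @param cv_limit QC limit on the between-well CV (default 0.5).
#'
#' @return A one-row tibble: `sample_id`, `marker`, `group`, `n_wells`,
#'   `tfi`, `cv`, `qc_flag`.
#' @export
sample_tfi <- function(wells, sample_id, group = "unknown", marker = NULL,
                       cv_limit = 0.5) {
  if (is.data.frame(wells)) {
    if (nrow(wells) < 1L) input_error("`wells` is empty")
    marker <- marker %||% unique(wells$marker)
    if (length(marker) > 1L) input_error("wells span multiple markers")
    vals <- wells$tfi
  } else {
    vals <- as.numeric(wells)
    if (length(vals) < 1L) input_error("`wells` is empty")
    marker <- marker %||% "unknown"
  }
  m <- mean(vals)
  cv <- if (length(vals) > 1L && m > 0) stats::sd(vals) / m else NA_real_
  tibble(
    sample_id = sample_id, marker = marker, group = group,
    n_wells = length(vals), tfi = m, cv = cv,
    qc_flag = !is.na(cv) && cv > cv_limit
  )
}
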