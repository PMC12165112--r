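#' TIRF field container
#'
#' A `tirf_field` holds one fluorescence field: a rectangular pixel grid in
#' arbitrary fluorescence units plus its geometry metadata. Fields are what
#' the quantification stage ([denoise_field()], [detect_spots()],
#' [measure_spots()]) consumes; a well is simply a list of fields.
#'
#' @param pixels Numeric matrix of finite, non-negative pixel intensities.
#' @param pixel_size_um Physical pixel pitch in micrometres.
#' @param field_index Zero-based index of the field within its well.
#' @param channel Marker label for the imaging channel (e.g. `"DLL3_exo_mRNA"`).
#'
#' @return An object of class `tirf_field`.
#' @export
tirf_field <- function(pixels, pixel_size_um = 0.15625, field_index = 0L,
                       channel = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    input_error("`pixels` must be a non-empty numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    input_error("`pixels` contains non-finite values")
  }
  if (any(pixels < 0)) {
    input_error("`pixels` contains negative intensities")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         field_index = as.integer(field_index), channel = as.character(channel)),
    class = "tirf_field"
  )
}

#' @export
print.tirf_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tirf_field> %d x %d px (%.4g um/px), channel %s, field %d\n",
              d[1], d[2], x$pixel_size_um, x$channel, x$field_index))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.tirf_field <- function(x) dim(x$pixels)

is_tirf_field <- function(x) inherits(x, "tirf_field")
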