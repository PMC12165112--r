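# File interchange: multi-page TIFF field stacks with JSON sidecars,
# cohort CSV tables, and YAML/JSON run configuration.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a list of TIRF fields as a multi-page TIFF stack
#'
#' Pixels are stored as 16-bit unsigned integers after an affine rescaling;
#' the scale and offset, the pixel geometry, the channel and (optionally)
#' the simulation ground truth are recorded in a JSON sidecar next to the
#' stack so that [read_field_stack()] restores intensities.
#'
#' @param fields List of [tirf_field()] objects.
#' @param path Output TIFF path.
#' @param truth Optional ground-truth object (e.g. the `spots` tibble from
#'   [simulate_well()]); stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_field_stack <- function(fields, path, truth = NULL) {
  stopifnot(all(vapply(fields, is_tirf_field, logical(1))))
  lo <- min(vapply(fields, function(f) min(f$pixels), double(1)))
  hi <- max(vapply(fields, function(f) max(f$pixels), double(1)))
  scale <- if (hi > lo) (hi - lo) / 65535 else 1
  pages <- purrr::map(fields, function(f) {
    m <- round((f$pixels - lo) / scale)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    offset = lo, scale = scale,
    pixel_size_um = fields[[1L]]$pixel_size_um,
    channel = fields[[1L]]$channel,
    n_fields = length(fields)
  )
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack of TIRF fields
#'
#' @param path TIFF path written by [write_field_stack()] or any 8/16-bit
#'   integer or 32-bit float multi-page TIFF.
#' @param pages Optional integer vector of 1-based page numbers to keep
#'   (order preserved).
#' @param pixel_size_um Pixel pitch, used when no sidecar is present.
#' @param channel Channel label, used when no sidecar is present.
#' @return A list of [tirf_field()] objects.
#' @export
read_field_stack <- function(path, pages = NULL, pixel_size_um = 0.15625,
                             channel = "unknown") {
  if (!file.exists(path)) {
    abort(sprintf("cannot read TIFF stack: %s", path),
          class = "evtirf_io_error")
  }
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (!is.null(pages)) {
    if (any(pages < 1L) || any(pages > length(raw))) {
      abort(sprintf("page out of range in %s (stack has %d pages)",
                    path, length(raw)),
            class = "evtirf_io_error")
    }
    raw <- raw[pages]
    idx <- as.integer(pages) - 1L
  } else {
    idx <- seq_along(raw) - 1L
  }
  purrr::map2(raw, idx, function(m, i) {
    if (!is.null(meta)) {
      m <- m * 65535 * meta$scale + meta$offset
      tirf_field(m, meta$pixel_size_um, i, meta$channel)
    } else {
      tirf_field(m, pixel_size_um, i, channel)
    }
  })
}

#' Read / write a cohort TFI table as CSV
#'
#' The interchange format is one row per sample: `sample_id`, `group`,
#' optionally `latent_subtype` (synthetic cohorts), and one TFI column per
#' marker.
#'
#' @param path CSV path.
#' @return `read_cohort_csv()` returns the cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read cohort CSV: %s", path),
          class = "evtirf_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    input_error("cohort CSV must have sample_id and group columns")
  }
  as_tibble(df)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read / write run configuration (YAML or JSON by extension)
#'
#' @param path Config path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config()` returns the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read config: %s", path),
          class = "evtirf_io_error")
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
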