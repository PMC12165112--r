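#' Run the full analysis pipeline on a cohort table or well manifest
#'
#' Ties the stages into one reproducible run. Input is either a cohort TFI
#' table (CSV or tibble) that goes straight to cutoff derivation and
#' classification, or a well manifest (CSV or tibble with columns
#' `sample_id`, `group`, `marker`, `well_id`, `path` and optionally
#' `pages`, a semicolon-separated page list) whose TIFF stacks are first
#' quantified into per-sample TFIs. All artifacts are written under
#' `out_dir`: the cutoff set and performance metrics as JSON, per-sample
#' calls and scores as CSV, and a summary JSON embedding the exact
#' configuration used. Identical config and inputs give identical outputs.
#'
#' @param input Cohort tibble/CSV path, or manifest tibble/CSV path with
#'   `manifest = TRUE`.
#' @param out_dir Output directory (created if needed).
#' @param config Named list of stage settings; recognised entries are
#'   `quant` (arguments to [quant_config()]), `classify` (arguments to
#'   [classify_cohort()]) and `seed`.
#' @param manifest Set `TRUE` when `input` is a well manifest.
#'
#' @return The `cohort_report`, invisibly; side effect is the report bundle
#'   in `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, config = list(), manifest = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- do.call(quant_config, config$quant %||% list())
  if (manifest) {
    man <- if (is.character(input)) read_cohort_manifest(input) else
      as_tibble(input)
    cohort <- quantify_manifest(man, qc)
    write_cohort_csv(cohort, file.path(out_dir, "cohort_tfi.csv"))
  } else {
    cohort <- if (is.character(input)) read_cohort_csv(input) else
      as_tibble(input)
  }
  report <- do.call(classify_cohort,
                    c(list(cohort = cohort), config$classify %||% list()))
  utils::write.csv(report$cutoffs, file.path(out_dir, "cutoffs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    setNames(as.list(report$cutoffs$cutoff), report$cutoffs$marker),
    file.path(out_dir, "cutoffs.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(tidy(report), file.path(out_dir, "sample_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(report$scores, file.path(out_dir, "panel_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$performance, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = config,
         n_samples = nrow(cohort),
         groups = as.list(table(cohort$group)),
         subtype_prevalence = report$subtype_prevalence,
         performance = report$performance),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(report)
}

#' Read a well manifest CSV
#'
#' @param path CSV with columns `sample_id`, `group`, `marker`, `well_id`,
#'   `path`, optional `pages` ("1;2;3").
#' @return Manifest tibble.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read manifest: %s", path),
          class = "evtirf_io_error")
  }
  man <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "group", "marker", "well_id", "path")
  if (!all(need %in% names(man))) {
    input_error(sprintf("manifest is missing column(s): %s",
                        paste(setdiff(need, names(man)), collapse = ", ")))
  }
  if (anyDuplicated(man[c("sample_id", "marker", "well_id")])) {
    input_error("(sample_id, marker, well_id) must be unique in the manifest")
  }
  man
}

# Quantify every well in a manifest and pivot to a samples x markers table.
quantify_manifest <- function(man, qc = quant_config()) {
  wells <- purrr::pmap(man, function(sample_id, group, marker, well_id,
                                     path, pages = NA, ...) {
    pg <- if (!is.na(pages) && nzchar(pages)) {
      as.integer(strsplit(as.character(pages), ";")[[1L]])
    } else {
      NULL
    }
    fields <- read_field_stack(path, pages = pg, channel = marker)
    w <- well_tfi(fields, qc, well_id = well_id)
    mutate(w, sample_id = sample_id, group = group, marker = marker)
  }) %>% bind_rows()
  samples <- wells %>%
    group_by(.data$sample_id, .data$group, .data$marker) %>%
    summarise(tfi = mean(.data$tfi), .groups = "drop")
  tidyr::pivot_wider(samples, names_from = "marker", values_from = "tfi")
}
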