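default_marker_sets <- function() {
  list(
    DLL3_exo_mRNA      = "DLL3_exo_mRNA",
    DLL3_tEV_mProtein  = "DLL3_tEV_mProtein",
    dual_DLL3          = c("DLL3_exo_mRNA", "DLL3_tEV_mProtein"),
    dual_plus_ASCL1    = c("DLL3_exo_mRNA", "DLL3_tEV_mProtein", "ASCL1"),
    dual_plus_NEUROD1  = c("DLL3_exo_mRNA", "DLL3_tEV_mProtein", "NEUROD1"),
    dual_plus_POU2F3   = c("DLL3_exo_mRNA", "DLL3_tEV_mProtein", "POU2F3"),
    full_classifier    = c("DLL3_exo_mRNA", "DLL3_tEV_mProtein",
                           "ASCL1", "POU2F3")
  )
}

#' Run the full cohort classification analysis
#'
#' Orchestrates everything downstream of TFI quantification: derives
#' whisker cutoffs (transcription factors) and 100%-specificity cutoffs
#' (DLL3 markers) from the control group, assigns molecular subtypes and
#' dual DLL3 calls to every sample, scores the configured marker panels,
#' and computes per-panel ROC/AUC and Mann-Whitney statistics for each SCLC
#' group against the controls. Fully deterministic given the table.
#'
#' @param cohort Cohort tibble (`sample_id`, `group`, marker columns; groups
#'   must include the control group and at least one SCLC group).
#' @param marker_sets Named list of marker panels to score and evaluate.
#' @param method Combination method for panels (see [combined_score()]).
#' @param control_group Control group label (default `"HRS"`).
#' @param case_groups SCLC group labels (default `c("LS", "ES")`); groups
#'   absent from the cohort are skipped.
#' @param quantile_type Quartile convention for the whisker cutoffs.
#'
#' @return A `cohort_report`: list with `cutoffs`, `subtype_calls`,
#'   `dual_calls`, `subtype_prevalence`, `ratio_matrix` (heatmap-ready
#'   long tibble of TFI/cutoff ratios for SCLC samples), `scores`,
#'   `performance` (per panel x comparison AUC, Mann-Whitney p, confusion
#'   metrics under the any-marker-above-cutoff rule) and `roc_curves`.
#' @export
classify_cohort <- function(cohort,
                            marker_sets = default_marker_sets(),
                            method = "max_log_ratio",
                            control_group = "HRS",
                            case_groups = c("LS", "ES"),
                            quantile_type = 7L) {
  tf_markers <- c("ASCL1", "NEUROD1", "POU2F3")
  dll3_markers <- c("DLL3_exo_mRNA", "DLL3_tEV_mProtein")
  needed <- c("sample_id", "group", tf_markers, dll3_markers)
  if (!all(needed %in% names(cohort))) {
    input_error(sprintf("cohort is missing column(s): %s",
                        paste(setdiff(needed, names(cohort)),
                              collapse = ", ")))
  }
  case_groups <- intersect(case_groups, unique(cohort$group))
  if (!control_group %in% cohort$group || length(case_groups) == 0L) {
    input_error("cohort must contain the control group and >=1 case group")
  }
  cutoffs <- derive_cutoffs(cohort, tf_markers, dll3_markers,
                            control_group, quantile_type)
  sclc <- dplyr::filter(cohort, .data$group %in% case_groups)
  subtype_calls <- assign_subtype(sclc, cutoffs, tf_markers)
  dual_calls <- dual_marker_call(cohort, cutoffs, dll3_markers) %>%
    left_join(select(cohort, "sample_id", "group"), by = "sample_id")
  prevalence <- subtype_calls %>%
    count(.data$subtype, name = "n") %>%
    tidyr::complete(subtype = c("A", "N", "P", "I"),
                    fill = list(n = 0L)) %>%
    mutate(frequency = .data$n / sum(.data$n)) %>%
    arrange(match(.data$subtype, c("A", "N", "P", "I")))
  ratio_matrix <- subtype_calls %>%
    select("sample_id", dplyr::starts_with("ratio_")) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "marker",
                        names_prefix = "ratio_", values_to = "ratio") %>%
    left_join(select(cohort, "sample_id", "group"), by = "sample_id")
  scores <- purrr::imap(marker_sets, function(mks, nm) {
    combined_score(cohort, mks, cutoffs, method = method,
                   control_group = control_group) %>%
      mutate(panel = nm, .before = 1L)
  }) %>% bind_rows()
  perf_rows <- list(); curves <- list()
  for (nm in names(marker_sets)) {
    sc <- dplyr::filter(scores, .data$panel == nm)
    for (cg in case_groups) {
      sub <- dplyr::filter(sc, .data$group %in% c(control_group, cg))
      y <- as.integer(sub$group == cg)
      roc <- roc_auc(sub$score, y)
      mw <- mann_whitney(sub$score[y == 1L], sub$score[y == 0L],
                         mode = "normal")
      cm <- confusion_metrics(as.integer(sub$score > 0), y)
      key <- paste(nm, cg, sep = ".")
      curves[[key]] <- roc
      perf_rows[[key]] <- tibble(
        panel = nm, comparison = paste0(cg, "_vs_", control_group),
        auc = roc$auc, n_cases = roc$n_cases, n_controls = roc$n_controls,
        mw_p = mw$p_value, sensitivity = cm$sensitivity,
        specificity = cm$specificity, accuracy = cm$accuracy
      )
    }
  }
  structure(
    list(cutoffs = cutoffs, subtype_calls = subtype_calls,
         dual_calls = dual_calls, subtype_prevalence = prevalence,
         ratio_matrix = ratio_matrix, scores = scores,
         performance = bind_rows(perf_rows), roc_curves = curves,
         control_group = control_group, case_groups = case_groups,
         method = method),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  %d SCLC samples subtyped vs %d-sample %s control\n",
              nrow(x$subtype_calls), x$cutoffs$n_controls[1L],
              x$control_group))
  cat("  subtype frequencies:",
      paste(sprintf("%s %.1f%%", x$subtype_prevalence$subtype,
                    100 * x$subtype_prevalence$frequency), collapse = ", "),
      "\n")
  cat("  panel AUCs:\n")
  p <- x$performance
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-18s %-12s AUC %.3f\n", p$panel[i], p$comparison[i],
                p$auc[i]))
  }
  invisible(x)
}

#' @rdname classify_cohort
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  left_join(x$subtype_calls,
            select(x$dual_calls, "sample_id", "category", "positive"),
            by = "sample_id")
}

#' @rdname classify_cohort
#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) x$performance
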