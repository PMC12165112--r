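#' Assign SCLC molecular subtypes from transcription-factor TFI ratios
#'
#' Each sample's TFI for ASCL1, NEUROD1 and POU2F3 is divided by the
#' corresponding control-derived cutoff. A factor is called positive when
#' its ratio strictly exceeds 1; the primary subtype is the factor with the
#' largest ratio among the positives (ties broken in the fixed order
#' A > N > P), and samples positive for none are called SCLC-I
#' (inflammatory, all three factors low).
#'
#' @param cohort Cohort tibble with the three transcription-factor columns.
#' @param cutoffs Cutoff tibble from [derive_cutoffs()] (needs rows for
#'   `ASCL1`, `NEUROD1`, `POU2F3`).
#' @param markers Names of the three factor columns, in A, N, P order.
#'
#' @return A tibble with `sample_id`, per-factor ratio columns
#'   (`ratio_ASCL1`, ...), `positive_set` (comma-separated subset of
#'   `A,N,P`) and `subtype` (`A`, `N`, `P` or `I`).
#' @export
assign_subtype <- function(cohort, cutoffs,
                           markers = c("ASCL1", "NEUROD1", "POU2F3")) {
  if (!all(markers %in% names(cohort))) {
    input_error(sprintf("cohort is missing marker column(s): %s",
                        paste(setdiff(markers, names(cohort)),
                              collapse = ", ")))
  }
  cut_vec <- setNames(cutoffs$cutoff[match(markers, cutoffs$marker)], markers)
  if (anyNA(cut_vec)) {
    input_error("cutoffs must cover ASCL1, NEUROD1 and POU2F3")
  }
  letters_anp <- c("A", "N", "P")
  ratios <- purrr::map(markers, function(mk) cohort[[mk]] / cut_vec[[mk]])
  names(ratios) <- paste0("ratio_", markers)
  rmat <- do.call(cbind, ratios)
  pos <- rmat > 1
  subtype <- vapply(seq_len(nrow(rmat)), function(i) {
    p <- which(pos[i, ])
    if (length(p) == 0L) return("I")
    # largest ratio wins; which.max takes the first maximum, and columns are
    # in A, N, P order, so ties resolve A > N > P
    letters_anp[p[which.max(rmat[i, p])]]
  }, character(1))
  positive_set <- vapply(seq_len(nrow(rmat)), function(i) {
    paste(letters_anp[pos[i, ]], collapse = ",")
  }, character(1))
  bind_cols(
    tibble(sample_id = cohort$sample_id),
    as_tibble(rmat),
    tibble(positive_set = positive_set, subtype = subtype)
  )
}

#' Dual DLL3 marker call
#'
#' Classifies each sample as H or L on exosomal DLL3 mRNA and on
#' tumour-EV DLL3 membrane protein (H iff TFI strictly exceeds the marker's
#' cutoff), yielding the four categories `HH`, `HL`, `LH`, `LL`; a sample is
#' called positive unless it is `LL`.
#'
#' @param cohort Cohort tibble with the two DLL3 marker columns.
#' @param cutoffs Cutoff tibble covering both markers.
#' @param markers The mRNA and protein column names, in that order.
#'
#' @return A tibble with `sample_id`, `mrna_high`, `protein_high`,
#'   `category` and `positive`.
#' @export
dual_marker_call <- function(cohort, cutoffs,
                             markers = c("DLL3_exo_mRNA",
                                         "DLL3_tEV_mProtein")) {
  if (!all(markers %in% names(cohort))) {
    input_error(sprintf("cohort is missing marker column(s): %s",
                        paste(setdiff(markers, names(cohort)),
                              collapse = ", ")))
  }
  cut_vec <- setNames(cutoffs$cutoff[match(markers, cutoffs$marker)], markers)
  if (anyNA(cut_vec)) input_error("cutoffs must cover both DLL3 markers")
  mrna_high <- cohort[[markers[1L]]] > cut_vec[[1L]]
  prot_high <- cohort[[markers[2L]]] > cut_vec[[2L]]
  tibble(
    sample_id = cohort$sample_id,
    mrna_high = mrna_high, protein_high = prot_high,
    category = paste0(ifelse(mrna_high, "H", "L"),
                      ifelse(prot_high, "H", "L")),
    positive = mrna_high | prot_high
  )
}
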