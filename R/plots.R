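# ggplot2 views of the main result types.

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve with its LOD
#'
#' @param fit A [fit_calibration()] result.
#' @param series The calibration tibble the fit came from.
#' @return A ggplot.
#' @export
plot_calibration <- function(fit, series) {
  pts <- series %>%
    filter(.data$concentration > 0) %>%
    group_by(.data$concentration) %>%
    summarise(mean_tfi = mean(.data$tfi), sd_tfi = stats::sd(.data$tfi),
              .groups = "drop") %>%
    mutate(adj = if (fit$subtract_baseline) {
      .data$mean_tfi - fit$blank_mean
    } else {
      .data$mean_tfi
    })
  line <- tibble(
    concentration = 10^seq(log10(min(fit$fit_range)),
                           log10(max(fit$fit_range)), length.out = 50)
  ) %>%
    mutate(adj = 10^(fit$intercept + fit$slope * log10(.data$concentration)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration,
                                    y = .data$adj)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = fit$lod, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Spiked EV concentration (particles/mL)",
                  y = if (fit$subtract_baseline) {
                    "TFI - blank mean"
                  } else {
                    "TFI"
                  },
                  title = sprintf("slope %.3f, r^2 %.3f, LOD %s",
                                  fit$slope, fit$r_squared,
                                  format(fit$lod))) +
    ggplot2::theme_minimal()
}

#' Subtype ratio heatmap of a classified cohort
#'
#' Log2 TFI-to-cutoff ratios of the three transcription factors across SCLC
#' samples, ordered by called subtype.
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  ord <- object$subtype_calls %>%
    arrange(match(.data$subtype, c("A", "N", "P", "I"))) %>%
    pull(.data$sample_id)
  dat <- object$ratio_matrix %>%
    mutate(sample_id = factor(.data$sample_id, levels = ord),
           log2_ratio = log2(pmax(.data$ratio, 1e-6)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$marker,
                                    fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "log2(TFI/cutoff)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Display a TIRF field as an intensity raster
#'
#' @param object A [tirf_field()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.tirf_field <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("field %d (%s)", object$field_index,
                                  object$channel)) +
    ggplot2::theme_minimal()
}
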