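# Rank statistics: ROC/AUC via the Mann-Whitney U relation, exact small-n
# permutation p-values, and 2x2 classification metrics.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (length(u) > 2L) input_error("labels must have two classes")
    return(as.integer(labels == u[length(u)]))
  }
  if (!all(labels %in% c(0, 1))) input_error("numeric labels must be 0/1")
  as.integer(labels)
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all distinct score thresholds and the
#' AUC by the tie-corrected rank (Mann-Whitney) formula, counting ties as
#' one half. The rank AUC equals the trapezoidal area under the empirical
#' curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case). Character/factor labels are
#'   coded with the alphabetically larger level as case.
#'
#' @return A `roc_result`: list with `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) input_error("length mismatch")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) input_error("both classes must be present")
  r <- rank(scores)
  u <- sum(r[y == 1L]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y == 1L] >= t), double(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0L] < t), double(1))
  structure(
    list(curve = tibble(threshold = thr, sensitivity = sens,
                        specificity = spec),
         auc = auc, n_cases = n1, n_controls = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Mann-Whitney U test
#'
#' `U` counts the case-control pairs won by `x` with ties worth one half.
#' For small samples (total n <= 12 in `"auto"` mode) the two-sided p-value
#' is exact, by full enumeration of all label assignments; otherwise the
#' tie-corrected normal approximation is used without continuity correction.
#' `U / (n_x * n_y)` is the empirical AUC of `x` over `y`.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#'
#' @return A one-row tibble: `u`, `p_value`, `auc`, `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    input_error("both samples must be non-empty")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  use_exact <- mode == "exact" || (mode == "auto" && n <= 12L)
  if (use_exact) {
    combos <- utils::combn(n, nx)
    u_all <- apply(combos, 2L, function(ii) {
      sum(r[ii]) - nx * (nx + 1) / 2
    })
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(v)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  tibble(u = u_obs, p_value = min(p, 1), auc = u_obs / (nx * ny),
         method = method)
}

#' Sensitivity, specificity and accuracy of binary calls
#'
#' @param calls Binary predicted calls (1/TRUE = positive).
#' @param labels Binary truth (1/TRUE = case).
#'
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(calls, labels) {
  cl <- as_binary_labels(calls); y <- as_binary_labels(labels)
  if (length(cl) != length(y)) input_error("length mismatch")
  if (all(y == 1L) || all(y == 0L)) {
    input_error("both classes must be present in `labels`")
  }
  tp <- sum(cl == 1L & y == 1L); fp <- sum(cl == 1L & y == 0L)
  tn <- sum(cl == 0L & y == 0L); fn <- sum(cl == 0L & y == 1L)
  tibble(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(y), tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Combined multi-marker classifier score
#'
#' Two ways to fuse a marker panel into one score per sample.
#' `"max_log_ratio"` (default, threshold-free) scores each sample by the
#' largest log2 TFI-to-cutoff ratio over the panel — the continuous
#' counterpart of calling a sample positive when any marker exceeds its
#' cutoff. `"logistic"` fits a maximum-likelihood logistic regression on the
#' log10 TFIs and scores by the linear predictor; if the classes are
#' separable (fitted probabilities degenerate) it falls back to
#' `"max_log_ratio"` with a warning.
#'
#' @param cohort Cohort tibble with `sample_id`, `group` and marker columns.
#' @param markers Marker panel to combine.
#' @param cutoffs Cutoff tibble covering `markers` (needed for
#'   `"max_log_ratio"`).
#' @param method `"max_log_ratio"` or `"logistic"`.
#' @param control_group Group treated as the negative class (default HRS).
#'
#' @return A tibble with `sample_id`, `group`, `score`, `method`.
#' @export
combined_score <- function(cohort, markers, cutoffs = NULL,
                           method = c("max_log_ratio", "logistic"),
                           control_group = "HRS") {
  method <- match.arg(method)
  if (!all(markers %in% names(cohort))) {
    input_error(sprintf("cohort is missing marker column(s): %s",
                        paste(setdiff(markers, names(cohort)),
                              collapse = ", ")))
  }
  if (method == "logistic") {
    y <- as.integer(cohort$group != control_group)
    if (all(y == 0L) || all(y == 1L)) {
      input_error("logistic combination needs both classes present")
    }
    X <- as.data.frame(lapply(cohort[markers], log10))
    names(X) <- markers
    dat <- cbind(data.frame(.y = y), X)
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (separated) {
      warn("logistic separation detected; falling back to max_log_ratio")
      method <- "max_log_ratio"
    } else {
      return(tibble(sample_id = cohort$sample_id, group = cohort$group,
                    score = unname(predict(fit, type = "link")),
                    method = "logistic"))
    }
  }
  if (is.null(cutoffs)) input_error("max_log_ratio needs `cutoffs`")
  cut_vec <- setNames(cutoffs$cutoff[match(markers, cutoffs$marker)], markers)
  if (anyNA(cut_vec)) input_error("cutoffs must cover all requested markers")
  rat <- purrr::map(markers, function(mk) log2(cohort[[mk]] / cut_vec[[mk]]))
  score <- do.call(pmax, rat)
  tibble(sample_id = cohort$sample_id, group = cohort$group,
         score = score, method = "max_log_ratio")
}
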