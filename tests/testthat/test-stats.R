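test_that("AUC equals 1 for perfect separation and 0.5 for all ties", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "evtirf_input_error")
})

test_that("rank AUC equals the trapezoidal area and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    # trapezoid over the empirical curve
    fpr <- 1 - r$curve$specificity; tpr <- r$curve$sensitivity
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<")))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("AUC x n1 x n2 equals the Mann-Whitney U statistic, with ties", {
  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    x <- sample(1:10, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * (i %% 2))
    y <- sample(1:10, n0, replace = TRUE) + rnorm(n0, 0, 0.01 * (i %% 2))
    auc <- roc_auc(c(x, y), rep(c(1, 0), c(n1, n0)))$auc
    u <- mann_whitney(x, y, mode = "normal")$u
    expect_equal(auc * n1 * n0, u, tolerance = 1e-9)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(3 * scores + 7, labels)$auc, a0, tolerance = 1e-12)
})

test_that("sensitivity is non-increasing as the threshold rises", {
  set.seed(41)
  r <- roc_auc(sample(1:6, 30, replace = TRUE), rbinom(30, 1, 0.5))
  ord <- order(r$curve$threshold)
  expect_true(all(diff(r$curve$sensitivity[ord]) <= 1e-12))
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 3)
  # identical multisets: U = n^2/2, p = 1
  res2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(res2$u, 4.5)
  expect_equal(res2$p_value, 1)
  # W statistic agrees with the base implementation (tie-free case)
  x <- c(1.2, 3.4, 2.2); y <- c(4.5, 0.1, 6.6, 5.5)
  expect_equal(mann_whitney(x, y)$u,
               unname(suppressWarnings(wilcox.test(x, y))$statistic))
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "evtirf_input_error")
})

test_that("the normal-mode test controls type-I error near 0.05", {
  set.seed(51)
  rejections <- 0L
  for (i in 1:1000) {
    x <- rnorm(20); y <- rnorm(20)
    if (mann_whitney(x, y, mode = "normal")$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lt(abs(rejections / 1000 - 0.05), 0.02)
})

test_that("confusion metrics reproduce the 2x2 arithmetic", {
  expect_equal(confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               tibble::tibble(sensitivity = 1, specificity = 1, accuracy = 1,
                              tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  allneg <- confusion_metrics(rep(0, 20), rep(c(1, 0), each = 10))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$accuracy, 0.5)
  m <- confusion_metrics(rep(c(1, 0, 0, 1), c(8, 2, 9, 1)),
                         rep(c(1, 0), c(10, 10)))
  expect_equal(unlist(m[1:3]),
               c(sensitivity = 0.8, specificity = 0.9, accuracy = 0.85))
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)),
               class = "evtirf_input_error")
})

test_that("combined max-log-ratio scores preserve single-marker ranking", {
  coh <- simulate_cohort(cohort_sim_config(
    n_per_group = c(HRS = 30L, LS = 30L, ES = 0L)), seed = 13)
  cuts <- derive_cutoffs(coh)
  sc <- combined_score(coh, "DLL3_exo_mRNA", cuts)
  expect_equal(order(sc$score), order(coh$DLL3_exo_mRNA))
  y <- as.integer(coh$group != "HRS")
  expect_equal(roc_auc(sc$score, y)$auc,
               roc_auc(coh$DLL3_exo_mRNA, y)$auc, tolerance = 1e-12)
  # exceeding any one cutoff makes the combined score positive
  sc2 <- combined_score(coh, c("DLL3_exo_mRNA", "DLL3_tEV_mProtein"), cuts)
  over <- coh$DLL3_exo_mRNA > cuts$cutoff[cuts$marker == "DLL3_exo_mRNA"] |
    coh$DLL3_tEV_mProtein > cuts$cutoff[cuts$marker == "DLL3_tEV_mProtein"]
  expect_equal(sc2$score > 0, over)
})

test_that("adding an uninformative marker does not destroy separation", {
  mu <- matrix(4, 3, 2, dimnames = list(c("HRS", "LS", "ES"),
                                        c("flat", "signal")))
  mu["LS", "signal"] <- 4.6
  cfg <- cohort_sim_config(
    n_per_group = c(HRS = 1000L, LS = 1000L, ES = 0L),
    markers = c("flat", "signal"), log10_tfi_mean = mu,
    log10_tfi_sd = 0.3,
    subtype_shift_log10 = list(A = numeric(0), N = numeric(0),
                               P = numeric(0), I = numeric(0)),
    inter_marker_corr = 0)
  coh <- simulate_cohort(cfg, seed = 17)
  cuts <- dplyr::bind_rows(
    tibble::tibble(marker = "flat",
                   cutoff = derive_cutoff_spec100(
                     coh$flat[coh$group == "HRS"]),
                   method = "spec100", control_group = "HRS",
                   n_controls = 1000L),
    tibble::tibble(marker = "signal",
                   cutoff = derive_cutoff_spec100(
                     coh$signal[coh$group == "HRS"]),
                   method = "spec100", control_group = "HRS",
                   n_controls = 1000L))
  y <- as.integer(coh$group == "LS")
  auc_flat <- roc_auc(combined_score(coh, "flat", cuts)$score, y)$auc
  auc_comb <- roc_auc(combined_score(coh, c("flat", "signal"), cuts)$score,
                      y)$auc
  expect_gte(auc_comb, auc_flat - 0.02)
})

test_that("logistic combination scores separate and fall back on separation", {
  coh <- simulate_cohort(cohort_sim_config(
    n_per_group = c(HRS = 80L, LS = 80L, ES = 0L)), seed = 19)
  sc <- combined_score(coh, c("DLL3_exo_mRNA", "ASCL1"), method = "logistic")
  expect_equal(unique(sc$method), "logistic")
  y <- as.integer(coh$group == "LS")
  expect_gt(roc_auc(sc$score, y)$auc, 0.5)
  # perfectly separable classes trigger the documented fallback
  sep <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    group = rep(c("HRS", "LS"), each = 10),
    M = c(10^rnorm(10, 3, 0.1), 10^rnorm(10, 6, 0.1)))
  cuts <- tibble::tibble(marker = "M", cutoff = max(sep$M[sep$group == "HRS"]),
                         method = "spec100", control_group = "HRS",
                         n_controls = 10L)
  expect_warning(
    out <- combined_score(sep, "M", cuts, method = "logistic"),
    "separation")
  expect_equal(unique(out$method), "max_log_ratio")
})
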