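default_markers <- c("ASCL1", "NEUROD1", "POU2F3",
                     "DLL3_exo_mRNA", "DLL3_tEV_mProtein")

default_log10_means <- function(markers) {
  base <- c(ASCL1 = 3.3, NEUROD1 = 3.8, POU2F3 = 4.4,
            DLL3_exo_mRNA = 4.4, DLL3_tEV_mProtein = 5.0)
  shift_ls <- c(ASCL1 = 0, NEUROD1 = 0, POU2F3 = 0,
                DLL3_exo_mRNA = 0.10, DLL3_tEV_mProtein = 0.05)
  shift_es <- c(ASCL1 = 0, NEUROD1 = 0, POU2F3 = 0,
                DLL3_exo_mRNA = 0.10, DLL3_tEV_mProtein = 0.15)
  m <- rbind(HRS = base[markers],
             LS = (base + shift_ls)[markers],
             ES = (base + shift_es)[markers])
  colnames(m) <- markers
  m
}

default_subtype_shifts <- function() {
  list(A = c(ASCL1 = 0.8, DLL3_exo_mRNA = 0.5),
       N = c(NEUROD1 = 0.8, DLL3_exo_mRNA = 0.5),
       P = c(POU2F3 = 0.8),
       I = numeric(0))
}

#' Configuration for a simulated multi-marker cohort
#'
#' Generates cohorts with the statistical structure the downstream analysis
#' assumes: per-sample log10 TFI vectors are multivariate normal (log-normal
#' TFI) with group- and marker-specific means, a shared correlation on the
#' log scale, and — for SCLC samples — a latent molecular subtype drawn from
#' the stated prevalences whose defining transcription-factor marker (and,
#' for the A/N subtypes, exosomal DLL3 mRNA) is shifted upward.
#'
#' Default group means are chosen so that the one-marker binormal AUCs of the
#' DLL3 markers fall in the range reported for the assay (exosomal mRNA
#' clearly separating, vesicle-surface protein only weakly, more so in
#' extensive stage); the defaults are qualitative and are not claimed to
#' reproduce any patient table.
#'
#' @param n_per_group Named integer vector over groups `HRS`, `LS`, `ES`.
#' @param markers Ordered marker names.
#' @param log10_tfi_mean Group-by-marker matrix of log10 TFI means (rownames
#'   groups, colnames markers).
#' @param log10_tfi_sd Group-by-marker matrix of log10 TFI sds, or a single
#'   number recycled (default 0.25).
#' @param subtype_prevalence Named probability vector over `A`, `N`, `P`, `I`
#'   (defaults 0.539 / 0.197 / 0.211 / 0.053).
#' @param subtype_shift_log10 Named list: subtype -> named numeric vector of
#'   additive log10 shifts per marker, applied to SCLC samples only.
#' @param inter_marker_corr Marker correlation matrix on the log scale, or a
#'   single off-diagonal value for an exchangeable structure (default 0.2).
#'
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_per_group = c(HRS = 45L, LS = 38L, ES = 38L),
                              markers = default_markers,
                              log10_tfi_mean = NULL,
                              log10_tfi_sd = 0.25,
                              subtype_prevalence =
                                c(A = 0.539, N = 0.197, P = 0.211, I = 0.053),
                              subtype_shift_log10 = default_subtype_shifts(),
                              inter_marker_corr = 0.2) {
  groups <- c("HRS", "LS", "ES")
  if (!all(groups %in% names(n_per_group))) {
    config_error("`n_per_group` must name HRS, LS and ES")
  }
  m <- length(markers)
  if (is.null(log10_tfi_mean)) log10_tfi_mean <- default_log10_means(markers)
  if (!is.matrix(log10_tfi_mean) ||
      !all(groups %in% rownames(log10_tfi_mean)) ||
      !all(markers %in% colnames(log10_tfi_mean))) {
    config_error("`log10_tfi_mean` must be a group x marker matrix")
  }
  if (length(log10_tfi_sd) == 1L) {
    log10_tfi_sd <- matrix(log10_tfi_sd, 3L, m,
                           dimnames = list(groups, markers))
  }
  if (any(log10_tfi_sd < 0)) config_error("sds must be >= 0")
  if (abs(sum(subtype_prevalence) - 1) > 1e-9) {
    config_error("`subtype_prevalence` must sum to 1")
  }
  if (!all(c("A", "N", "P", "I") %in% names(subtype_prevalence))) {
    config_error("`subtype_prevalence` must name A, N, P, I")
  }
  if (length(inter_marker_corr) == 1L) {
    inter_marker_corr <- matrix(inter_marker_corr, m, m,
                                dimnames = list(markers, markers))
    diag(inter_marker_corr) <- 1
  }
  if (!isSymmetric(unname(inter_marker_corr)) ||
      min(eigen(inter_marker_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    config_error("`inter_marker_corr` must be symmetric positive semi-definite")
  }
  structure(
    list(n_per_group = n_per_group[groups], markers = markers,
         log10_tfi_mean = log10_tfi_mean[groups, markers, drop = FALSE],
         log10_tfi_sd = log10_tfi_sd[groups, markers, drop = FALSE],
         subtype_prevalence = subtype_prevalence[c("A", "N", "P", "I")],
         subtype_shift_log10 = subtype_shift_log10,
         inter_marker_corr = inter_marker_corr),
    class = "cohort_sim_config"
  )
}

#' Simulate a multi-marker cohort with latent truth
#'
#' Draws every sample's marker TFI vector from the model described in
#' [cohort_sim_config()]. High-risk-smoker (HRS) controls carry no subtype
#' and no shift; each SCLC sample (groups LS and ES) receives a latent
#' subtype and the corresponding marker shifts. The latent truth is stored
#' alongside the observed TFIs so downstream calls can be scored.
#'
#' @param cfg A [cohort_sim_config()].
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id`, `group`, `latent_subtype` (`NA` for
#'   HRS) and one TFI column per marker.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  markers <- cfg$markers
  m <- length(markers)
  L <- chol(cfg$inter_marker_corr)
  subtypes <- names(cfg$subtype_prevalence)
  with_seed(derive_seed(seed, "cohort"), {
    rows <- purrr::map(names(cfg$n_per_group), function(g) {
      n <- cfg$n_per_group[[g]]
      if (n < 1L) return(NULL)
      z <- matrix(rnorm(n * m), n, m) %*% L
      lt <- sweep(sweep(z, 2L, cfg$log10_tfi_sd[g, markers], `*`),
                  2L, cfg$log10_tfi_mean[g, markers], `+`)
      if (g == "HRS") {
        st <- rep(NA_character_, n)
      } else {
        st <- sample(subtypes, n, replace = TRUE,
                     prob = cfg$subtype_prevalence)
        for (s in subtypes) {
          sh <- cfg$subtype_shift_log10[[s]]
          sh <- sh[names(sh) %in% markers]
          if (length(sh)) {
            ii <- which(st == s)
            for (mk in names(sh)) {
              lt[ii, match(mk, markers)] <-
                lt[ii, match(mk, markers)] + sh[[mk]]
            }
          }
        }
      }
      tfi <- 10^lt
      colnames(tfi) <- markers
      bind_cols(
        tibble(sample_id = sprintf("%s_%03d", g, seq_len(n)),
               group = g, latent_subtype = st),
        as_tibble(tfi)
      )
    })
    bind_rows(rows)
  })
}
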