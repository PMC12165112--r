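# Undecimated a-trous wavelet machinery (B3-spline kernel), the standard
# multiscale transform for fluorescence spot work.

b3_kernel <- c(1, 4, 6, 4, 1) / 16

# Mirror (whole-sample reflection) index vector of length n shifted by `off`.
mirror_idx <- function(n, off) {
  idx <- seq_len(n) + off
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  pmin(pmax(idx, 1L), n)
}

# Separable B3 smoothing with taps dilated by `step` (a-trous scheme).
atrous_smooth <- function(img, step) {
  offs <- c(-2L, -1L, 0L, 1L, 2L) * step
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    tmp <- tmp + b3_kernel[k] * img[mirror_idx(nr, offs[k]), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    out <- out + b3_kernel[k] * tmp[, mirror_idx(nc, offs[k]), drop = FALSE]
  }
  out
}

# Full decomposition: details[[j]] = c_{j-1} - c_j, plus the coarse plane.
atrous_decompose <- function(img, levels) {
  details <- vector("list", levels)
  c_prev <- img
  for (j in seq_len(levels)) {
    c_next <- atrous_smooth(c_prev, 2L^(j - 1L))
    details[[j]] <- c_prev - c_next
    c_prev <- c_next
  }
  list(details = details, coarse = c_prev)
}

# L2 norm of the equivalent detail filter per level: white noise of sd 1
# yields detail coefficients of sd `factor[j]`. Computed once by decomposing
# a unit impulse; cached in the package namespace.
.atrous_cache <- new.env(parent = emptyenv())

atrous_noise_factors <- function(levels) {
  key <- as.character(levels)
  if (!is.null(.atrous_cache[[key]])) return(.atrous_cache[[key]])
  n <- 2L^(levels + 3L)
  delta <- matrix(0, n, n)
  delta[n %/% 2L, n %/% 2L] <- 1
  dec <- atrous_decompose(delta, levels)
  f <- vapply(dec$details, function(w) sqrt(sum(w^2)), double(1))
  .atrous_cache[[key]] <- f
  f
}

#' Wavelet denoising of a TIRF field
#'
#' Performs an undecimated a-trous B3-spline wavelet decomposition, zeroes
#' detail coefficients smaller in magnitude than `threshold_k` times the
#' level-wise robust (median-absolute-deviation) coefficient scale, and
#' reconstructs the field. The returned `noise_sd` is the pixel noise
#' standard deviation inferred from the finest detail plane (MAD estimate
#' divided by the analytic white-noise response of that plane), which is what
#' the downstream detection threshold is expressed in.
#'
#' @param field A [tirf_field()].
#' @param levels Number of wavelet scales (default 3).
#' @param threshold_k Hard-threshold multiplier on the per-level robust
#'   coefficient scale (default 3).
#'
#' @return A list with `field` (denoised [tirf_field()]), `noise_sd`
#'   (estimated pixel noise sd of the input) and `coarse` (the residual
#'   smooth background plane).
#' @export
denoise_field <- function(field, levels = 3L, threshold_k = 3) {
  stopifnot(is_tirf_field(field))
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1) {
    input_error("`levels` must be a positive integer")
  }
  levels <- as.integer(levels)
  assert_scalar_num(threshold_k, "threshold_k", lower = 0)
  img <- field$pixels
  dec <- atrous_decompose(img, levels)
  factors <- atrous_noise_factors(levels)
  sigma1 <- stats::mad(as.vector(dec$details[[1L]]), center = 0)
  noise_sd <- sigma1 / factors[1L]
  rec <- dec$coarse
  for (j in seq_len(levels)) {
    w <- dec$details[[j]]
    sig_j <- stats::mad(as.vector(w), center = 0)
    if (sig_j > 0) w[abs(w) < threshold_k * sig_j] <- 0
    rec <- rec + w
  }
  rec <- pmax(rec, 0)
  out <- field
  out$pixels <- rec
  list(field = out, noise_sd = noise_sd, coarse = dec$coarse)
}
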