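#' Configuration for simulated TIRF fields
#'
#' Describes the imaging model used by [simulate_field()] and
#' [simulate_well()]: diffraction-limited spots rendered as pixel-integrated
#' isotropic Gaussians on a flat background, with optional Poisson shot noise
#' on the expected counts and additive Gaussian read noise. The default
#' geometry (512 px at 0.15625 um/px) reproduces an 80 x 80 um field.
#'
#' @param image_size_px Integer length-1 or -2 vector, field size in pixels.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param psf_sigma_px Standard deviation of the Gaussian point-spread
#'   function, in pixels.
#' @param spot_count_mean Poisson mean of the number of spots per field;
#'   each spot is one captured vesicle (or probe-bound vesicle).
#' @param amplitude_log10_mean,amplitude_log10_sd Mean and sd of log10
#'   integrated spot brightness (arbitrary fluorescence units).
#' @param background_level Flat background intensity added to every pixel.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise;
#'   0 disables it.
#' @param shot_noise If `TRUE`, pixel values are Poisson draws with the
#'   noiseless image as the expectation.
#' @param min_separation_px Minimum centre-to-centre distance between spots
#'   (rejection sampling); 0 places spots uniformly at random.
#' @param border_margin_px Spots are kept at least this far from the image
#'   border so their PSF mass is not truncated.
#' @param channel Marker label attached to generated fields.
#'
#' @return A `field_sim_config` list, validated.
#' @export
field_sim_config <- function(image_size_px = c(512L, 512L),
                             pixel_size_um = 0.15625,
                             psf_sigma_px = 1.3,
                             spot_count_mean = 30,
                             amplitude_log10_mean = 3,
                             amplitude_log10_sd = 0.4,
                             background_level = 100,
                             read_noise_sd = 0,
                             shot_noise = FALSE,
                             min_separation_px = 0,
                             border_margin_px = ceiling(5 * psf_sigma_px),
                             channel = "unknown") {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  if (length(image_size_px) != 2L || any(image_size_px < 1) ||
      any(image_size_px != as.integer(image_size_px))) {
    config_error("`image_size_px` must be one or two positive integers")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  assert_scalar_num(psf_sigma_px, "psf_sigma_px", lower = 1e-6)
  assert_scalar_num(spot_count_mean, "spot_count_mean", lower = 0)
  assert_scalar_num(amplitude_log10_mean, "amplitude_log10_mean")
  assert_scalar_num(amplitude_log10_sd, "amplitude_log10_sd", lower = 0)
  assert_scalar_num(background_level, "background_level", lower = 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  assert_flag(shot_noise, "shot_noise")
  assert_scalar_num(min_separation_px, "min_separation_px", lower = 0)
  assert_scalar_num(border_margin_px, "border_margin_px", lower = 0)
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
         spot_count_mean = spot_count_mean,
         amplitude_log10_mean = amplitude_log10_mean,
         amplitude_log10_sd = amplitude_log10_sd,
         background_level = background_level,
         read_noise_sd = read_noise_sd, shot_noise = shot_noise,
         min_separation_px = min_separation_px,
         border_margin_px = border_margin_px,
         channel = as.character(channel)),
    class = "field_sim_config"
  )
}

# Pixel-integrated isotropic Gaussian: the PSF mass falling in each pixel is
# the product of 1-D normal CDF differences, so the rendered spot sums to its
# integrated amplitude (up to window truncation at ~7 sigma).
render_spot <- function(img, x, y, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(7 * sigma)
  rows <- max(1L, floor(y - r)):min(nr, ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(nc, ceiling(x + r))
  wy <- pnorm(rows + 0.5, mean = y, sd = sigma) -
        pnorm(rows - 0.5, mean = y, sd = sigma)
  wx <- pnorm(cols + 0.5, mean = x, sd = sigma) -
        pnorm(cols - 0.5, mean = x, sd = sigma)
  img[rows, cols] <- img[rows, cols] + amplitude * (wy %o% wx)
  img
}

place_spots <- function(n, nr, nc, margin, min_sep) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  lo_x <- 1 + margin; hi_x <- nc - margin
  lo_y <- 1 + margin; hi_y <- nr - margin
  if (hi_x <= lo_x || hi_y <= lo_y) {
    config_error("image too small for the requested border margin")
  }
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
    if (min_sep <= 0 || length(xs) == 0L ||
        min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 200L * n + 1000L) {
      config_error("could not place spots at the requested minimum separation")
    }
  }
  cbind(x = xs, y = ys)
}

#' Simulate one TIRF field with known ground truth
#'
#' Draws a Poisson number of spots, places them uniformly (optionally with a
#' minimum separation), assigns log-normal integrated amplitudes, renders the
#' noiseless image, and applies the configured noise model. The same
#' `(cfg, seed)` pair always reproduces the identical field bit for bit.
#'
#' @param cfg A [field_sim_config()].
#' @param seed Integer seed for this field.
#' @param field_index Zero-based field index recorded in the output.
#'
#' @return A list with elements `field` (a [tirf_field()]), `spots` (a tibble
#'   with `x_px`, `y_px`, `amplitude` per injected spot) and `true_tfi`
#'   (sum of the injected amplitudes).
#' @export
simulate_field <- function(cfg, seed = 1L, field_index = 0L) {
  stopifnot(inherits(cfg, "field_sim_config"))
  with_seed(seed, {
    nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
    n_spots <- rpois(1L, cfg$spot_count_mean)
    pos <- place_spots(n_spots, nr, nc, cfg$border_margin_px,
                       cfg$min_separation_px)
    amps <- 10^rnorm(n_spots, cfg$amplitude_log10_mean, cfg$amplitude_log10_sd)
    img <- matrix(cfg$background_level, nr, nc)
    for (i in seq_len(n_spots)) {
      img <- render_spot(img, pos[i, "x"], pos[i, "y"], amps[i],
                         cfg$psf_sigma_px)
    }
    if (cfg$shot_noise) {
      img <- matrix(as.double(rpois(length(img), pmax(img, 0))), nr, nc)
    }
    if (cfg$read_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, cfg$read_noise_sd)
    }
    img <- pmax(img, 0)
    list(
      field = tirf_field(img, cfg$pixel_size_um, field_index, cfg$channel),
      spots = tibble(x_px = unname(pos[, "x"]), y_px = unname(pos[, "y"]),
                     amplitude = amps),
      true_tfi = sum(amps)
    )
  })
}

#' Simulate a full well of TIRF fields
#'
#' A well is imaged as an array of fields (100 in the reference protocol).
#' Each field gets its own seed derived from the master seed, so the draws
#' for field *i* do not depend on how many fields follow it.
#'
#' @param cfg A [field_sim_config()].
#' @param n_fields Number of fields per well (default 100).
#' @param seed Master integer seed for the well.
#'
#' @return A list with `fields` (list of [tirf_field()]), `spots` (tibble of
#'   all injected spots with `field_index`), `truth` (per-field tibble with
#'   `field_index`, `n_spots`, `true_tfi`), `true_tfi` (well total) and
#'   `field_seeds` (the derived per-field seeds).
#' @export
simulate_well <- function(cfg, n_fields = 100L, seed = 1L) {
  stopifnot(inherits(cfg, "field_sim_config"))
  if (!is.numeric(n_fields) || length(n_fields) != 1L || n_fields < 1) {
    config_error("`n_fields` must be a positive integer")
  }
  n_fields <- as.integer(n_fields)
  field_seeds <- vapply(seq_len(n_fields) - 1L,
                        function(i) derive_seed(seed, "field", i), integer(1))
  sims <- purrr::map(seq_len(n_fields), function(i) {
    simulate_field(cfg, seed = field_seeds[i], field_index = i - 1L)
  })
  spots <- purrr::map2(sims, seq_len(n_fields) - 1L, function(s, idx) {
    dplyr::mutate(s$spots, field_index = idx, .before = 1L)
  }) %>% bind_rows()
  truth <- tibble(
    field_index = seq_len(n_fields) - 1L,
    n_spots = vapply(sims, function(s) nrow(s$spots), integer(1)),
    true_tfi = vapply(sims, function(s) s$true_tfi, double(1))
  )
  list(fields = purrr::map(sims, "field"), spots = spots, truth = truth,
       true_tfi = sum(truth$true_tfi), field_seeds = field_seeds)
}
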