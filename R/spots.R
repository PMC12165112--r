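# Spot detection and photometry on TIRF fields.

# Robust local background: the a-trous coarse plane re-estimated with bright
# pixels (candidate spots) replaced by the current background, so spot flux
# does not inflate the background under the spot (sigma-clipped smoothing).
estimate_background <- function(img, noise_sd, levels = 3L, iters = 3L) {
  bg <- atrous_decompose(img, levels)$coarse
  for (i in seq_len(iters)) {
    resid <- img - bg
    s <- max(noise_sd, stats::mad(as.vector(resid), center = 0),
             1e-3 * max(resid, 0))
    if (s <= 0) break
    clipped <- img
    hot <- resid > 3 * s
    if (!any(hot)) break
    clipped[hot] <- bg[hot]
    bg <- atrous_decompose(clipped, levels)$coarse
  }
  bg
}

# Shift a matrix by (dr, dc) padding with `fill`.
shift_pad <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Connected-component labels by iterative minimum-label propagation.
# Deterministic; labels renumbered 1..k in raster order of first pixel.
label_components <- function(mask, connectivity = 8L) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  offs <- if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    input_error("`connectivity` must be 4 or 8")
  }
  L <- matrix(Inf, nrow(mask), ncol(mask))
  L[mask] <- which(mask)
  repeat {
    L2 <- L
    for (o in offs) L2 <- pmin(L2, shift_pad(L, o[1], o[2], Inf))
    L2[!mask] <- Inf
    if (identical(L2[mask], L[mask])) break
    L <- L2
  }
  # after convergence every component carries its minimum linear index;
  # renumber 1..k in raster order of that representative pixel
  lab <- matrix(0L, nrow(mask), ncol(mask))
  uu <- sort(unique(as.vector(L[mask])))
  lab[mask] <- match(L[mask], uu)
  lab
}

#' Detect bright spots in a denoised TIRF field
#'
#' Pixels whose denoised intensity exceeds a robust local background estimate
#' by more than `detect_k * noise_sd` are segmented into connected components
#' (8-connectivity by default); each component becomes one candidate spot
#' mask. For noise-free images (`noise_sd` near 0) a small relative
#' prominence floor keeps the threshold strictly above the background plane.
#'
#' @param denoised A denoised [tirf_field()] (see [denoise_field()]).
#' @param noise_sd Pixel noise standard deviation (from [denoise_field()]).
#' @param detect_k Detection threshold in noise-sd units (default 3).
#' @param connectivity 8 (default) or 4.
#' @param background Optional background matrix; if `NULL` it is estimated by
#'   sigma-clipped a-trous smoothing of the denoised image.
#' @param min_prominence Absolute intensity floor for the threshold; default
#'   `1e-4` of the peak background-subtracted intensity, which only matters
#'   when `noise_sd` is (near) zero.
#'
#' @return A list of spot masks. Each mask is a two-column integer matrix of
#'   (row, col) pixel coordinates with attributes `centroid` (intensity-
#'   weighted x, y in pixel units) and `peak`. The list carries the
#'   `background` matrix and detection `threshold` as attributes.
#' @export
detect_spots <- function(denoised, noise_sd, detect_k = 3, connectivity = 8L,
                         background = NULL, min_prominence = NULL) {
  stopifnot(is_tirf_field(denoised))
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(detect_k, "detect_k", lower = 0)
  img <- denoised$pixels
  if (is.null(background)) {
    background <- estimate_background(img, noise_sd)
  }
  if (!is.matrix(background) || !all(dim(background) == dim(img))) {
    input_error("`background` must match the image dimensions")
  }
  resid <- img - background
  if (is.null(min_prominence)) {
    # keeps the threshold above the residual error of the background plane
    # (bounded by its sigma-clip level) when noise_sd is ~0
    min_prominence <- 5e-3 * max(resid, 0)
  }
  thr <- max(detect_k * noise_sd, min_prominence)
  mask <- resid > thr
  out <- list()
  if (any(mask)) {
    lab <- label_components(mask, as.integer(connectivity))
    k <- max(lab)
    idx <- which(mask, arr.ind = TRUE)
    comp <- lab[mask]
    ord <- order(comp)
    idx <- idx[ord, , drop = FALSE]
    comp <- comp[ord]
    splits <- split(seq_len(nrow(idx)), comp)
    out <- purrr::map(splits, function(ii) {
      px <- idx[ii, , drop = FALSE]
      w <- resid[px]
      w <- pmax(w, 0)
      if (sum(w) <= 0) w <- rep(1, length(w))
      m <- cbind(row = as.integer(px[, 1]), col = as.integer(px[, 2]))
      attr(m, "centroid") <- c(x = sum(px[, 2] * w) / sum(w),
                               y = sum(px[, 1] * w) / sum(w))
      attr(m, "peak") <- max(img[px])
      m
    })
    names(out) <- NULL
  }
  attr(out, "background") <- background
  attr(out, "threshold") <- thr
  out
}

#' Measure spot photometry on the raw image
#'
#' For each detected mask, computes the mean raw intensity inside the spot
#' and in a surrounding annulus (a `annulus_gap_px`-wide guard ring is
#' skipped, then `annulus_width_px` pixels are averaged), excluding pixels
#' that belong to any other spot and pixels outside the image. The net
#' intensity of a spot is `(mean_in - mean_surround) * pixel_count`, so a
#' uniform background offset cancels exactly. Measurement always uses the
#' raw image, not the denoised one, to avoid shrinkage bias in TFI.
#'
#' @param raw The raw [tirf_field()] the masks were detected in.
#' @param masks Spot masks from [detect_spots()].
#' @param annulus_gap_px Guard gap between spot and annulus (default 1).
#' @param annulus_width_px Annulus width in pixels (default 2).
#'
#' @return A tibble with one row per measurable spot: `field_index`,
#'   `spot_id`, `x_px`, `y_px`, `pixel_count`, `mean_in`, `mean_surround`,
#'   `net_intensity`. Spots whose annulus is entirely excluded are dropped;
#'   the count is available as attribute `n_dropped`.
#' @export
measure_spots <- function(raw, masks, annulus_gap_px = 1L,
                          annulus_width_px = 2L) {
  stopifnot(is_tirf_field(raw))
  assert_scalar_num(annulus_gap_px, "annulus_gap_px", lower = 0)
  assert_scalar_num(annulus_width_px, "annulus_width_px", lower = 1)
  img <- raw$pixels
  nr <- nrow(img); nc <- ncol(img)
  all_spot_lin <- unique(unlist(purrr::map(masks, function(m) {
    (m[, "col"] - 1L) * nr + m[, "row"]
  })))
  gap <- as.integer(annulus_gap_px); wid <- as.integer(annulus_width_px)
  r_out <- gap + wid
  ring_offsets <- {
    g <- expand.grid(dr = -r_out:r_out, dc = -r_out:r_out)
    ch <- pmax(abs(g$dr), abs(g$dc))
    g[ch > gap & ch <= r_out, , drop = FALSE]
  }
  n_dropped <- 0L
  rows <- purrr::imap(masks, function(m, i) {
    cen <- attr(m, "centroid")
    npx <- nrow(m)
    lin_in <- (m[, "col"] - 1L) * nr + m[, "row"]
    rr <- rep(m[, "row"], each = nrow(ring_offsets)) + ring_offsets$dr
    cc <- rep(m[, "col"], each = nrow(ring_offsets)) + ring_offsets$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    lin_ring <- unique((cc[ok] - 1L) * nr + rr[ok])
    lin_ring <- setdiff(lin_ring, c(lin_in, all_spot_lin))
    # also drop pixels within the guard gap of this mask
    if (gap > 0L) {
      gg <- expand.grid(dr = -gap:gap, dc = -gap:gap)
      rr2 <- rep(m[, "row"], each = nrow(gg)) + gg$dr
      cc2 <- rep(m[, "col"], each = nrow(gg)) + gg$dc
      ok2 <- rr2 >= 1L & rr2 <= nr & cc2 >= 1L & cc2 <= nc
      lin_gap <- unique((cc2[ok2] - 1L) * nr + rr2[ok2])
      lin_ring <- setdiff(lin_ring, lin_gap)
    }
    if (length(lin_ring) == 0L) return(NULL)
    mean_in <- mean(img[lin_in])
    mean_surround <- mean(img[lin_ring])
    tibble(
      field_index = raw$field_index, spot_id = i,
      x_px = unname(cen["x"]), y_px = unname(cen["y"]),
      pixel_count = npx, mean_in = mean_in, mean_surround = mean_surround,
      net_intensity = (mean_in - mean_surround) * npx
    )
  })
  dropped <- vapply(rows, is.null, logical(1))
  n_dropped <- sum(dropped)
  if (n_dropped > 0L) {
    inform(sprintf("measure_spots: dropped %d spot(s) with empty annulus",
                   n_dropped))
  }
  out <- bind_rows(rows[!dropped])
  if (nrow(out) == 0L) {
    out <- tibble(field_index = integer(0), spot_id = integer(0),
                  x_px = double(0), y_px = double(0), pixel_count = integer(0),
                  mean_in = double(0), mean_surround = double(0),
                  net_intensity = double(0))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter spots by area and positivity
#'
#' Applies the spot-size cutoff: only spots whose pixel area lies in
#' `[min_area_px, max_area_px]` and whose net intensity is positive
#' contribute to TFI. Row order is preserved.
#'
#' @param records Spot tibble from [measure_spots()].
#' @param min_area_px,max_area_px Inclusive area bounds in pixels.
#'
#' @return The retained rows of `records`.
#' @export
filter_spots <- function(records, min_area_px = 2L, max_area_px = 50L) {
  if (!(min_area_px >= 1 && min_area_px <= max_area_px)) {
    input_error("need 1 <= min_area_px <= max_area_px")
  }
  dplyr::filter(records,
                .data$pixel_count >= min_area_px,
                .data$pixel_count <= max_area_px,
                .data$net_intensity > 0)
}
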