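test_that("a constant field yields no spots", {
  f <- tirf_field(matrix(7, 64, 64))
  d <- denoise_field(f)
  expect_length(detect_spots(d$field, d$noise_sd), 0L)
})

test_that("two well-separated noiseless spots give two masks at the truth", {
  img <- matrix(0, 96, 96)
  f0 <- tirf_field(img + 1)
  centres <- list(c(40, 40), c(40, 60))  # 20 px apart
  for (ct in centres) {
    rows <- (ct[1] - 8):(ct[1] + 8); cols <- (ct[2] - 8):(ct[2] + 8)
    g <- (pnorm(rows + 0.5, ct[1], 1.3) - pnorm(rows - 0.5, ct[1], 1.3)) %o%
         (pnorm(cols + 0.5, ct[2], 1.3) - pnorm(cols - 0.5, ct[2], 1.3))
    img[rows, cols] <- img[rows, cols] + 100 * 2 * pi * 1.3^2 * g
  }
  f <- tirf_field(img + 1)
  d <- denoise_field(f)
  masks <- detect_spots(d$field, d$noise_sd, detect_k = 3)
  expect_length(masks, 2L)
  cents <- t(vapply(masks, function(m) attr(m, "centroid"), double(2)))
  # centroid (x, y) = (col, row)
  err <- min(
    max(abs(cents[, "x"] - c(40, 60)) + abs(cents[, "y"] - c(40, 40))),
    max(abs(cents[, "x"] - c(60, 40)) + abs(cents[, "y"] - c(40, 40))))
  expect_lt(err, 0.5)
})

test_that("detection at SNR 10 achieves >= 0.98 recall and precision", {
  cfg <- snr10_field_config()
  tp <- 0L; fp <- 0L; fn <- 0L
  for (sd0 in 1:4) {
    s <- simulate_field(cfg, seed = sd0)
    d <- denoise_field(s$field)
    rec <- filter_spots(
      measure_spots(s$field, detect_spots(d$field, d$noise_sd)), 2, 50)
    m <- match_spots(s$spots, rec, tol_px = 2)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.98)
  expect_gte(tp / (tp + fp), 0.98)
})

test_that("net intensity is independent of a uniform background", {
  cfg <- oracle_field_config(spot_count_mean = 8)
  s <- simulate_field(cfg, seed = 6)
  d <- denoise_field(s$field)
  masks <- detect_spots(d$field, d$noise_sd)
  r1 <- measure_spots(s$field, masks)
  shifted <- s$field; shifted$pixels <- shifted$pixels + 123.4
  r2 <- measure_spots(shifted, masks)
  expect_equal(r2$net_intensity, r1$net_intensity, tolerance = 1e-9)
  expect_equal(r2$mean_surround - r1$mean_surround,
               rep(123.4, nrow(r1)), tolerance = 1e-9)
})

test_that("a 3-sigma disc mask recovers ~0.989 of the integrated amplitude", {
  n <- 64; ct <- 32.5; sigma <- 1.3; A <- 5000
  rows <- 1:n
  g <- (pnorm(rows + 0.5, ct, sigma) - pnorm(rows - 0.5, ct, sigma)) %o%
       (pnorm(rows + 0.5, ct, sigma) - pnorm(rows - 0.5, ct, sigma))
  img <- 10 + A * g
  f <- tirf_field(img)
  rc <- expand.grid(row = 1:n, col = 1:n)
  inside <- (rc$row - ct)^2 + (rc$col - ct)^2 <= (3 * sigma)^2
  mask <- as.matrix(rc[inside, c("row", "col")])
  attr(mask, "centroid") <- c(x = ct, y = ct)
  rec <- measure_spots(f, list(mask))
  expect_equal(rec$net_intensity, 0.989 * A, tolerance = 0.05)
})

test_that("the annulus excludes neighbouring spot pixels", {
  # two adjacent spots; doubling spot 2 must not move spot 1's net intensity
  build <- function(a2) {
    img <- matrix(50, 64, 64)
    for (sp in list(list(c(32, 27), 4000), list(c(32, 37), a2))) {
      ct <- sp[[1]]
      rows <- (ct[1] - 7):(ct[1] + 7); cols <- (ct[2] - 7):(ct[2] + 7)
      g <- (pnorm(rows + 0.5, ct[1], 1.3) - pnorm(rows - 0.5, ct[1], 1.3)) %o%
           (pnorm(cols + 0.5, ct[2], 1.3) - pnorm(cols - 0.5, ct[2], 1.3))
      img[rows, cols] <- img[rows, cols] + sp[[2]] * g
    }
    tirf_field(img)
  }
  f1 <- build(4000); f2 <- build(8000)
  d1 <- denoise_field(f1)
  masks <- detect_spots(d1$field, d1$noise_sd)
  expect_length(masks, 2L)
  n1 <- measure_spots(f1, masks)$net_intensity[1L]
  n2 <- measure_spots(f2, masks)$net_intensity[1L]
  expect_lt(abs(n2 - n1) / n1, 0.01)
})

test_that("spot-size filtering applies the area bounds and positivity rule", {
  rec <- tibble::tibble(
    field_index = 0L, spot_id = 1:5,
    x_px = 1, y_px = 1,
    pixel_count = c(1L, 4L, 30L, 80L, 10L),
    mean_in = 5, mean_surround = c(1, 1, 1, 1, 9),
    net_intensity = (5 - mean_surround) * pixel_count
  )
  kept <- filter_spots(rec, 2, 50)
  expect_equal(kept$pixel_count, c(4L, 30L))
  # identity case: wide bounds and all-positive nets keep everything
  pos <- rec[rec$net_intensity > 0, ]
  expect_equal(filter_spots(pos, 1, Inf), pos)
  expect_error(filter_spots(rec, 5, 2), class = "evtirf_input_error")
})

test_that("connected-component labelling honours 8- vs 4-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch
  img <- matrix(0, 5, 5); img[m] <- 10
  f <- tirf_field(img)
  masks8 <- detect_spots(f, noise_sd = 1, detect_k = 3, connectivity = 8,
                         background = matrix(0, 5, 5))
  masks4 <- detect_spots(f, noise_sd = 1, detect_k = 3, connectivity = 4,
                         background = matrix(0, 5, 5))
  expect_length(masks8, 1L)
  expect_length(masks4, 2L)
})
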