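test_that("the centred spectrum matches a direct double-sum DFT", {
  set.seed(8)
  for (dims in list(c(16, 16), c(15, 16), c(9, 13))) {
    m <- matrix(runif(prod(dims)), dims[1], dims[2])
    sp <- compute_ft(m)
    oracle <- dft2_magnitude_centred(m)
    expect_lt(max(abs(sp - oracle)) / max(oracle), 1e-9)
    # Parseval: spectral energy equals N times the image energy
    expect_equal(sum(sp^2), prod(dims) * sum(m^2), tolerance = 1e-9)
  }
})

test_that("canonical spectra: constant image and a single sinusoid", {
  sp <- compute_ft(matrix(5, 16, 16))
  expect_equal(sp[9, 9], 5 * 256)
  expect_equal(max(sp[-(9 + 8 * 16)]), 0)

  # vertical sinusoid (varies along columns): two peaks on the horizontal
  # frequency axis plus DC
  x <- outer(rep(1, 32), cos(2 * pi * 4 * (0:31) / 32)) + 2
  sp2 <- compute_ft(x)
  big <- which(sp2 > 1e-6 * max(sp2), arr.ind = TRUE)
  expect_equal(nrow(big), 3L)
  expect_true(all(big[, "row"] == 17))           # on the k_y = 0 line
  expect_setequal(big[, "col"], c(13, 17, 21))   # DC and +/- 4 bins
})

test_that("thresholding keeps the DC-connected region and flags blank input", {
  sp <- compute_ft(matrix(3, 12, 12))
  mask <- threshold_ft(sp)
  expect_equal(sum(mask), 1L)
  expect_true(mask[7, 7])

  expect_error(threshold_ft(compute_ft(matrix(0, 8, 8))), "blank image")

  # disconnected bright bins are excluded from the centre component
  fake <- matrix(0, 11, 11)
  fake[6, 6] <- 100; fake[6, 7] <- 90; fake[5, 6] <- 85  # connected arm
  fake[2, 2] <- 95                                       # separate peak
  mask2 <- threshold_ft(fake)
  expect_true(mask2[6, 7] && mask2[5, 6])
  expect_false(mask2[2, 2])
  expect_equal(sum(mask2), 3L)
})

test_that("moment ellipse matches analytic shapes", {
  # filled disk: circular symmetry, R = 1 within discretisation
  g <- expand.grid(x = -25:25, y = -25:25)
  disk <- matrix(g$x^2 + g$y^2 <= 20^2, 51, 51)
  ed <- ellipse_from_mask(disk)
  expect_equal(ed$R, 1, tolerance = 0.02)

  # filled a x b rectangles approach R = b/a (exact with the 1/12
  # pixel-area correction)
  for (ab in list(c(30, 12), c(50, 20), c(120, 48))) {
    er <- ellipse_from_mask(matrix(TRUE, ab[2], ab[1]))
    expect_equal(er$R, ab[2] / ab[1], tolerance = 1e-9)
    expect_equal(er$major_axis, 4 * sqrt(ab[1]^2 / 12), tolerance = 1e-9)
  }

  # rotation by 90 degrees preserves R and turns the orientation
  rect <- matrix(TRUE, 10, 40)
  e0 <- ellipse_from_mask(rect)
  e90 <- ellipse_from_mask(t(rect))
  expect_equal(e0$R, e90$R, tolerance = 1e-12)
  expect_equal(e0$orientation, 0)
  expect_equal(abs(e90$orientation), 90)

  # single pixel: degenerate isotropic case
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(ellipse_from_mask(single)$R, 1)
  expect_error(ellipse_from_mask(matrix(FALSE, 3, 3)), "empty")
})

test_that("R is invariant to intensity scaling and 90-degree rotation", {
  img <- simulate_fibre_image(fibre_params(dispersion_sd = 3,
                                           waviness_amp = 1), seed = 6)
  w <- tile_rois(img)[[1]]$pixels
  r0 <- directionality_R(w)$R
  expect_gt(r0, 0); expect_lte(r0, 1)
  expect_equal(directionality_R(w * 7.3)$R, r0, tolerance = 1e-12)
  rot <- t(w[nrow(w):1, ])   # 90-degree rotation
  expect_equal(directionality_R(rot)$R, r0, tolerance = 1e-9)
})

test_that("R is stable under moderate detector noise", {
  pars <- fibre_params(dispersion_sd = 3, waviness_amp = 1,
                       background_sd = 0)
  set.seed(31)
  diffs <- vapply(1:6, function(s) {
    w <- tile_rois(simulate_fibre_image(pars, seed = s))[[1]]$pixels
    # zero-mean detector noise at SNR ~ 10 relative to the signal sd;
    # a positive background *offset* would instead inflate the DC bin
    # and shrink the threshold mask (see the methods vignette)
    noisy <- w + matrix(rnorm(length(w), 0, sd(w) / 10), nrow(w))
    abs(directionality_R(noisy)$R - directionality_R(w)$R)
  }, 0)
  expect_lt(median(diffs), 0.05)
})

test_that("brightest-10-pixel intensity equals the sort-and-average oracle", {
  m <- matrix(0, 5, 4); m[1:10] <- 100
  expect_equal(max10_intensity(m), 100)
  expect_equal(max10_intensity(matrix(7.5, 6, 6)), 7.5)

  set.seed(13)
  r <- matrix(rnorm(400, 50, 20), 20)
  expect_equal(max10_intensity(r),
               mean(sort(as.numeric(r), decreasing = TRUE)[1:10]))
  expect_error(max10_intensity(matrix(1, 3, 3)), "fewer than 10")
})

test_that("ROI tiling produces the expected grid of even-sided windows", {
  img <- fibre_image(matrix(1, 300, 300), pixel_size = 1 / 3)
  rois <- tile_rois(img, side_um = 60)
  expect_length(rois, 1L)                   # 300 %/% 180 = 1 per axis
  expect_equal(rois[[1]]$side, 180L)
  expect_equal(rois[[1]]$origin, c(row = 1L, col = 1L))

  img2 <- fibre_image(matrix(0, 930, 560), pixel_size = 1 / 3)
  rois2 <- tile_rois(img2, side_um = 60)
  expect_length(rois2, (930 %/% 180) * (560 %/% 180))  # 5 x 3 grid
  # row-major order
  expect_equal(vapply(rois2[1:3], function(w) w$roi_col, 0L), 1:3)
  expect_equal(dim(rois2[[4]]$pixels), c(180L, 180L))
})

test_that("tile stitching reconstructs a known source image", {
  set.seed(17)
  src <- fibre_image(matrix(runif(120 * 120, 0, 1000), 120),
                     pixel_size = 0.5)
  # identity on a 1x1 grid
  one <- cut_into_tiles(src, 1, 1, overlap_frac = 0.1)
  expect_equal(stitch_tiles(one, 0.1)$pixels, src$pixels)

  # cut-and-restitch with 10% overlap: exact within blending tolerance
  for (grid in list(c(1, 2), c(2, 2))) {
    tiles <- cut_into_tiles(src, grid[1], grid[2], overlap_frac = 0.1)
    mosaic <- stitch_tiles(tiles, overlap_frac = 0.1)
    expect_equal(dim(mosaic$pixels), dim(src$pixels))
    expect_lt(max(abs(mosaic$pixels - src$pixels)), 1)
  }

  # constant tiles blend to the same constant
  const <- lapply(1:4, function(i) fibre_image(matrix(42, 30, 30), 1))
  dim(const) <- c(2, 2)
  expect_equal(unique(as.numeric(stitch_tiles(const, 0.1)$pixels)), 42)

  # inconsistent tile sizes are rejected
  bad <- list(fibre_image(matrix(1, 30, 30), 1),
              fibre_image(matrix(1, 20, 30), 1))
  dim(bad) <- c(1, 2)
  expect_error(stitch_tiles(bad, 0.1), "size differs")
})

test_that("per-window analysis table carries R and intensity per ROI", {
  img <- simulate_fibre_image(fibre_params(image_size = 200,
                                           pixel_size = 0.5), seed = 21)
  tab <- analyze_shg_image(img, side_um = 50, image_id = "im1")
  expect_equal(nrow(tab), 4L)   # 200 %/% 100 = 2 per axis
  expect_named(tab, c("image", "roi_row", "roi_col", "R", "major", "minor",
                      "orientation_deg", "max10"))
  expect_true(all(tab$R > 0 & tab$R <= 1))
  expect_true(all(tab$minor <= tab$major))
  expect_true(all(tab$max10 <= max(img$pixels)))
})
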