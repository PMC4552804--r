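## Fibre directionality from the 2D Fourier spectrum.
##
## Parallel fibres concentrate spectral energy along the direction
## perpendicular to the fibre axis; the low-frequency region above 80% of
## the DC magnitude is therefore elongated, and the minor/major axis ratio
## R of its moment ellipse quantifies directionality: small R = parallel
## fibres, R near 1 = disorder.

#' Centred 2D Fourier magnitude spectrum of an image window
#'
#' Magnitude of the discrete 2D Fourier transform with the zero-frequency
#' (DC) bin shifted to the array centre, at row/column index
#' `floor(n/2) + 1`.
#'
#' @param window A numeric matrix, a `fibre_image`, or an ROI window from
#'   [tile_rois()].
#' @return Numeric matrix of spectral magnitudes, same size as the input.
#' @export
compute_ft <- function(window) {
  m <- as_pixels(window)
  stop_if(!is.numeric(m) || length(dim(m)) != 2L,
          "input must be a 2D numeric array")
  sp <- Mod(stats::fft(m))
  fftshift2(sp)
}

#' @noRd
as_pixels <- function(x) {
  if (inherits(x, "fibre_image")) return(x$pixels)
  if (inherits(x, "roi_window")) return(x$pixels)
  as.matrix(x)
}

## Swap quadrants so DC lands at (floor(nr/2)+1, floor(nc/2)+1).
#' @noRd
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((nr - floor(nr / 2) + 1):nr, 1:(nr - floor(nr / 2)))
  ci <- c((nc - floor(nc / 2) + 1):nc, 1:(nc - floor(nc / 2)))
  m[ri, ci, drop = FALSE]
}

#' @noRd
centre_bin <- function(m) c(floor(nrow(m) / 2) + 1L, floor(ncol(m) / 2) + 1L)

#' Threshold a centred spectrum at a fraction of its DC value
#'
#' Keeps bins whose magnitude reaches `threshold` (default 80%) of the
#' centre (DC) value, then restricts the mask to the 8-connected component
#' containing the centre: disconnected harmonic peaks would make a single
#' moment ellipse meaningless.
#'
#' @param spectrum Centred magnitude spectrum from [compute_ft()].
#' @param threshold Fraction of the DC magnitude (default 0.8).
#' @return Logical matrix; the centre bin is always `TRUE`.
#' @export
threshold_ft <- function(spectrum, threshold = 0.8) {
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  ctr <- centre_bin(spectrum)
  dc <- spectrum[ctr[1], ctr[2]]
  stop_if(dc <= 0, "blank image: spectrum centre value is zero")
  mask <- spectrum >= threshold * dc
  centre_component(mask, ctr)
}

## 8-connected component of `mask` containing `seed`, by iterated
## one-pixel dilation of the seed intersected with the mask.
#' @noRd
centre_component <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    vert <- comp
    vert[-1, ] <- vert[-1, ] | comp[-nr, ]
    vert[-nr, ] <- vert[-nr, ] | comp[-1, ]
    grown <- vert
    grown[, -1] <- grown[, -1] | vert[, -nc]
    grown[, -nc] <- grown[, -nc] | vert[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Moment ellipse of a binary region
#'
#' Fits the ellipse sharing the region's normalised second central moments
#' (each pixel treated as a unit square, adding 1/12 to the coordinate
#' variances). Axis lengths are `4 * sqrt(eigenvalue)` of the moment
#' matrix, the convention of standard region-properties tools; a single
#' pixel therefore yields equal axes and R = 1.
#'
#' @param mask Logical (or 0/1) matrix with at least one `TRUE` pixel.
#' @return An object of class `ft_ellipse`: `major_axis`, `minor_axis`
#'   (px), `orientation` (degrees counter-clockwise from the column axis,
#'   in (-90, 90]), `R = minor/major`, and `ft_peak` (`NA` here; filled by
#'   [directionality_R()]).
#' @export
ellipse_from_mask <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  stop_if(nrow(idx) == 0, "mask is empty")
  x <- idx[, 2]           # column -> x
  y <- -idx[, 1]          # row down -> y up, so angles are counter-clockwise
  n <- nrow(idx)
  mxx <- sum((x - mean(x))^2) / n + 1 / 12
  myy <- sum((y - mean(y))^2) / n + 1 / 12
  mxy <- sum((x - mean(x)) * (y - mean(y))) / n
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(ev$values[2])
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(list(major_axis = major, minor_axis = minor,
                 orientation = ang, R = minor / major, ft_peak = NA_real_),
            class = "ft_ellipse")
}

#' @export
print.ft_ellipse <- function(x, ...) {
  cat(sprintf("FT ellipse: R = %.3f (major %.2f px, minor %.2f px), orientation %.1f deg\n",
              x$R, x$major_axis, x$minor_axis, x$orientation))
  invisible(x)
}

#' Fibre directionality statistic R of an image window
#'
#' Composition of [compute_ft()], [threshold_ft()] and
#' [ellipse_from_mask()]: the ratio R of minor to major axes of the moment
#' ellipse of the 80%-thresholded Fourier magnitude. Small R means fibres
#' are very parallel; R near 1 reflects random fibre orientations.
#'
#' @param window Matrix, `fibre_image` or ROI window.
#' @inheritParams threshold_ft
#' @return An `ft_ellipse` with `ft_peak` set to the DC magnitude.
#' @export
directionality_R <- function(window, threshold = 0.8) {
  sp <- compute_ft(window)
  mask <- threshold_ft(sp, threshold = threshold)
  ell <- ellipse_from_mask(mask)
  ctr <- centre_bin(sp)
  ell$ft_peak <- sp[ctr[1], ctr[2]]
  ell
}

#' Mean of the ten brightest pixels
#'
#' The SHG "maximum intensity" of a window, robustified by averaging the
#' 10 highest pixel values; ties may be resolved arbitrarily without
#' changing the result.
#'
#' @param image Matrix, `fibre_image` or ROI window with >= 10 pixels.
#' @return Single number (counts).
#' @export
max10_intensity <- function(image) {
  px <- as.numeric(as_pixels(image))
  px <- px[!is.na(px)]
  stop_if(length(px) < 10, "image has fewer than 10 pixels")
  mean(sort(px, decreasing = TRUE)[1:10])
}

#' Partition an image into square analysis windows
#'
#' Non-overlapping grid of windows of physical side `side_um`, row-major,
#' anchored at the top-left corner; partial windows at the right/bottom
#' edges are discarded. The pixel side is `side_um / pixel_size` rounded to
#' the nearest even integer.
#'
#' @param image A `fibre_image`.
#' @param side_um Window side in um (default 60).
#' @return List of `roi_window` objects, each with `origin` (row, col,
#'   1-based), `side` (px), `roi_row`/`roi_col` grid indices and the pixel
#'   submatrix.
#' @export
tile_rois <- function(image, side_um = 60) {
  stopifnot(inherits(image, "fibre_image"))
  side <- 2L * as.integer(round(side_um / image$pixel_size / 2))
  stop_if(side < 16, "ROI side below 16 px; increase side_um or resolution")
  nr <- nrow(image$pixels) %/% side
  nc <- ncol(image$pixels) %/% side
  stop_if(nr < 1 || nc < 1, "image smaller than one ROI window")
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      r0 <- (i - 1L) * side + 1L
      c0 <- (j - 1L) * side + 1L
      out[[k]] <- structure(list(
        origin = c(row = r0, col = c0),
        side = side, roi_row = i, roi_col = j,
        pixel_size = image$pixel_size,
        pixels = image$pixels[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
      ), class = "roi_window")
    }
  }
  out
}

#' Analyse every window of an image
#'
#' Tiles the image with [tile_rois()] and computes the directionality R and
#' the brightest-10-pixel intensity per window.
#'
#' @inheritParams tile_rois
#' @inheritParams threshold_ft
#' @param image_id Identifier echoed into the output table.
#' @return data.frame `image, roi_row, roi_col, R, major, minor,`
#'   `orientation_deg, max10`.
#' @export
analyze_shg_image <- function(image, side_um = 60, threshold = 0.8,
                              image_id = "image") {
  rois <- tile_rois(image, side_um = side_um)
  rows <- lapply(rois, function(w) {
    ell <- directionality_R(w, threshold = threshold)
    data.frame(image = image_id, roi_row = w$roi_row, roi_col = w$roi_col,
               R = ell$R, major = ell$major_axis, minor = ell$minor_axis,
               orientation_deg = ell$orientation,
               max10 = max10_intensity(w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stitch a grid of image tiles into a mosaic
#'
#' Reassembles tiles acquired with a fixed fractional overlap (default
#' 10%). Overlapping strips are blended by linear feathering: each tile's
#' weight ramps linearly across the overlap zone, so tiles cut from one
#' source image restitch to the source exactly.
#'
#' @param tiles A list of `fibre_image`s (or matrices) with a `dim`
#'   attribute giving the grid layout, or a list of rows (list of lists).
#'   All tiles must share size and pixel size.
#' @param overlap_frac Fractional overlap between neighbouring tiles, in
#'   (0, 0.5).
#' @return A `fibre_image` mosaic.
#' @seealso [cut_into_tiles()] for the inverse used in testing.
#' @export
stitch_tiles <- function(tiles, overlap_frac = 0.1) {
  check_number(overlap_frac, "overlap_frac", lower = 0, upper = 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(dim(tiles))) {
    stop_if(!is.list(tiles) || !all(vapply(tiles, is.list, TRUE)),
            "tiles must be a matrix-like list (use dim<- or nested rows)")
    nr_g <- length(tiles); nc_g <- length(tiles[[1]])
    flat <- unlist(tiles, recursive = FALSE)
    get_tile <- function(i, j) flat[[(i - 1L) * nc_g + j]]
  } else {
    nr_g <- dim(tiles)[1]; nc_g <- dim(tiles)[2]
    get_tile <- function(i, j) tiles[[i, j]]
  }
  px1 <- as_pixels(get_tile(1, 1))
  th <- nrow(px1); tw <- ncol(px1)
  psz <- if (inherits(get_tile(1, 1), "fibre_image"))
    get_tile(1, 1)$pixel_size else 1

  ov_r <- round(th * overlap_frac); ov_c <- round(tw * overlap_frac)
  step_r <- th - ov_r; step_c <- tw - ov_c
  H <- th + (nr_g - 1L) * step_r
  W <- tw + (nc_g - 1L) * step_c
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)

  ramp <- function(len, ov, first, last) {
    w <- rep(1, len)
    if (ov > 0) {
      r <- seq_len(ov) / (ov + 1)
      if (!first) w[seq_len(ov)] <- r
      if (!last) w[len - ov + seq_len(ov)] <- rev(r)
    }
    w
  }
  for (i in seq_len(nr_g)) {
    for (j in seq_len(nc_g)) {
      t_ij <- get_tile(i, j)
      px <- as_pixels(t_ij)
      stop_if(nrow(px) != th || ncol(px) != tw,
              sprintf("tile (%d,%d) size differs from the first tile", i, j))
      w <- outer(ramp(th, ov_r, i == 1, i == nr_g),
                 ramp(tw, ov_c, j == 1, j == nc_g))
      r0 <- (i - 1L) * step_r; c0 <- (j - 1L) * step_c
      acc[r0 + 1:th, c0 + 1:tw] <- acc[r0 + 1:th, c0 + 1:tw] + w * px
      wacc[r0 + 1:th, c0 + 1:tw] <- wacc[r0 + 1:th, c0 + 1:tw] + w
    }
  }
  fibre_image(acc / wacc, psz, provenance = "synthetic")
}

#' Cut an image into an overlapping tile grid
#'
#' Inverse of [stitch_tiles()]: extracts an `n_rows x n_cols` grid of tiles
#' with the given fractional overlap. Used to exercise the stitcher against
#' a known source.
#'
#' @param image A `fibre_image`.
#' @param n_rows,n_cols Grid dimensions.
#' @param overlap_frac Fractional overlap in (0, 0.5).
#' @return A list of `fibre_image` tiles with `dim = c(n_rows, n_cols)`.
#' @export
cut_into_tiles <- function(image, n_rows, n_cols, overlap_frac = 0.1) {
  stopifnot(inherits(image, "fibre_image"))
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  ## tile size th solves H = th + (n_rows-1) * (th - round(th*ov))
  th <- solve_tile_side(H, n_rows, overlap_frac)
  tw <- solve_tile_side(W, n_cols, overlap_frac)
  step_r <- th - round(th * overlap_frac)
  step_c <- tw - round(tw * overlap_frac)
  tiles <- vector("list", n_rows * n_cols)
  dim(tiles) <- c(n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      r0 <- (i - 1L) * step_r; c0 <- (j - 1L) * step_c
      tiles[[i, j]] <- fibre_image(
        image$pixels[r0 + 1:th, c0 + 1:tw], image$pixel_size,
        provenance = image$provenance)
    }
  }
  tiles
}

#' @noRd
solve_tile_side <- function(total, n_tiles, overlap_frac) {
  if (n_tiles == 1L) return(total)
  for (th in seq.int(total, 16L)) {
    if (th + (n_tiles - 1L) * (th - round(th * overlap_frac)) == total) {
      return(th)
    }
  }
  stop(sprintf("no integer tile side tiles %d px into %d tiles at %.0f%% overlap",
               total, n_tiles, 100 * overlap_frac), call. = FALSE)
}

#' Compare a statistic between groups by one-way ANOVA
#'
#' Plain one-way ANOVA with pooled-variance pairwise t comparisons, as used
#' for the per-group R and SHG intensity tables.
#'
#' @param values Numeric response (e.g. per-ROI R).
#' @param groups Factor or character group labels.
#' @return List with `f_value`, `df`, `p_value`, `group_means`, and
#'   `pairwise` (matrix of pairwise pooled-t p-values).
#' @export
compare_shg_groups <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if(nlevels(droplevels(groups)) < 2, "need at least two groups")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(values, groups, pool.sd = TRUE,
                               p.adjust.method = "none")
  list(f_value = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p_value = s[["Pr(>F)"]][1],
       group_means = tapply(values, groups, mean),
       pairwise = pw$p.value)
}
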