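#' Parameters of a synthetic fibrous texture
#'
#' Describes an SHG-like collagen image as a set of fibre bundles
#' (fascicles). Each bundle is a chain of short Gaussian-ridge segments
#' grown from a centre point; every segment's direction is the mean
#' orientation plus independent Gaussian jitter of SD `dispersion_sd`.
#' With no jitter the chain is a straight, narrow band crossing the field
#' (well-aligned parallel fibres); with strong jitter it curls into a
#' compact disorganised clump — the two morphologies whose Fourier
#' signatures the directionality statistic R separates. Defaults match a
#' typical two-photon acquisition: 100 um x 100 um fields at 300 x 300 px.
#'
#' @param mean_orientation Mean fibre direction in degrees (counter-
#'   clockwise from the image x/column axis).
#' @param dispersion_sd SD of the per-segment orientation jitter (degrees);
#'   0 gives perfectly parallel straight fibres, ~60 an essentially
#'   isotropic texture.
#' @param waviness_amp,waviness_period Amplitude and period (um) of the
#'   sinusoidal transverse displacement along each fibre.
#' @param fibre_spacing Distance between neighbouring fibre axes within a
#'   bundle is `fibre_spacing / 2` (fascicles pack fibres densely); also
#'   the minimum image extent.
#' @param fibre_width Full width at half maximum of the fibre intensity
#'   profile (um).
#' @param intensity_peak Peak intensity in counts; the rendered (noise-free)
#'   image is normalised so its maximum equals this value.
#' @param background_sd SD of additive Gaussian background noise (counts).
#' @param pixel_size Physical pixel size in um/px (default 1/3).
#' @param image_size Image side in px.
#' @param bundle_spacing Distance between bundle axes (um); one bundle per
#'   ~55 um puts a fascicle in nearly every 60-um analysis window.
#' @param segment_length Chain segment length (um); `Inf` renders each
#'   bundle as unbroken fibres spanning the field.
#' @param fibres_per_segment Parallel fibres rendered per segment.
#' @param brightness_sdlog Lognormal SD of the per-bundle brightness
#'   (segment-level jitter is 0.3); bundle-to-bundle contrast is what makes
#'   one fascicle dominate a window, as in tissue.
#' @return An object of class `fibre_params`.
#' @export
fibre_params <- function(mean_orientation = 0, dispersion_sd = 10,
                         waviness_amp = 2, waviness_period = 25,
                         fibre_spacing = 5, fibre_width = 1.5,
                         intensity_peak = 1000, background_sd = 5,
                         pixel_size = 1 / 3, image_size = 300,
                         bundle_spacing = 55, segment_length = 14,
                         fibres_per_segment = 3, brightness_sdlog = 1.0) {
  check_number(mean_orientation, "mean_orientation")
  check_number(dispersion_sd, "dispersion_sd", lower = 0)
  check_number(waviness_amp, "waviness_amp", lower = 0)
  check_number(waviness_period, "waviness_period", lower = 0,
               strict_lower = TRUE)
  check_number(fibre_spacing, "fibre_spacing", lower = 0, strict_lower = TRUE)
  check_number(fibre_width, "fibre_width", lower = 0, strict_lower = TRUE)
  check_number(intensity_peak, "intensity_peak", lower = 0,
               strict_lower = TRUE)
  check_number(background_sd, "background_sd", lower = 0)
  stop_if(background_sd >= intensity_peak,
          "'background_sd' must be below 'intensity_peak'")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(bundle_spacing, "bundle_spacing", lower = 0,
               strict_lower = TRUE)
  stop_if(!(is.numeric(segment_length) && length(segment_length) == 1L &&
              segment_length > 0),
          "'segment_length' must be a positive number (Inf allowed)")
  check_number(brightness_sdlog, "brightness_sdlog", lower = 0)
  structure(list(mean_orientation = mean_orientation,
                 dispersion_sd = dispersion_sd,
                 waviness_amp = waviness_amp,
                 waviness_period = waviness_period,
                 fibre_spacing = fibre_spacing,
                 fibre_width = fibre_width,
                 intensity_peak = intensity_peak,
                 background_sd = background_sd,
                 pixel_size = pixel_size,
                 image_size = check_count(image_size, "image_size", 2L),
                 bundle_spacing = bundle_spacing,
                 segment_length = segment_length,
                 fibres_per_segment = check_count(fibres_per_segment,
                                                  "fibres_per_segment"),
                 brightness_sdlog = brightness_sdlog),
            class = "fibre_params")
}

#' Construct a fibre image object
#' @param pixels Numeric matrix of non-negative intensity counts.
#' @param pixel_size Physical pixel size in um/px.
#' @param provenance `"measured"` or `"synthetic"`.
#' @param ground_truth Optional [fibre_params()] for synthetic images.
#' @return Object of class `fibre_image`.
#' @export
fibre_image <- function(pixels, pixel_size, provenance = "measured",
                        ground_truth = NULL) {
  pixels <- as.matrix(pixels)
  stop_if(any(pixels < 0, na.rm = TRUE), "intensities must be non-negative")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  provenance <- match.arg(provenance, c("measured", "synthetic"))
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance, ground_truth = ground_truth),
            class = "fibre_image")
}

#' @export
print.fibre_image <- function(x, ...) {
  cat(sprintf("fibre_image: %d x %d px, %.3f um/px (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$provenance))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: orientation %g deg, dispersion %g deg, waviness %g um\n",
                x$ground_truth$mean_orientation, x$ground_truth$dispersion_sd,
                x$ground_truth$waviness_amp))
  }
  invisible(x)
}

#' Render a synthetic SHG-like fibre image
#'
#' Bundle axes are laid out with normal offsets covering the image diagonal
#' at `bundle_spacing` intervals; each bundle grows as a segment chain from
#' a centre point in both directions, every segment's direction being the
#' mean orientation plus independent jitter of SD `dispersion_sd`, so
#' aligned parameters give straight fascicle bands and dispersed parameters
#' give compact disorganised clumps. Segments render `fibres_per_segment`
#' parallel Gaussian ridges with sinusoidal waviness; segments paint only
#' their local neighbourhood, keeping rendering fast. The noise-free render
#' is normalised to `intensity_peak`, then Gaussian background noise is
#' added and clipped at zero.
#'
#' @param params A [fibre_params()].
#' @param seed Integer seed; a fixed seed gives a byte-identical image.
#' @return A `fibre_image` with `provenance = "synthetic"` and the ground
#'   truth attached.
#' @examples
#' img <- simulate_fibre_image(fibre_params(dispersion_sd = 0), seed = 1)
#' @export
simulate_fibre_image <- function(params, seed = 1L) {
  stopifnot(inherits(params, "fibre_params"))
  extent <- params$image_size * params$pixel_size
  stop_if(extent < params$fibre_spacing,
          sprintf("image extent (%.1f um) is smaller than one fibre period (%.1f um)",
                  extent, params$fibre_spacing))
  set.seed(substream_seed(seed, "fibre-image"))

  n <- params$image_size
  xy <- (seq_len(n) - 0.5) * params$pixel_size - extent / 2
  sigma <- params$fibre_width / (2 * sqrt(2 * log(2))) # FWHM -> sd
  diag_len <- extent * sqrt(2)
  th0 <- params$mean_orientation * pi / 180
  seg_len <- min(params$segment_length, 2 * diag_len)
  n_seg_half <- ceiling(diag_len / seg_len / 2)
  fib_step <- params$fibre_spacing / 2
  npf <- params$fibres_per_segment

  img <- matrix(0, n, n)
  paint_seg <- function(ctr, th, bright, phase) {
    r <- seg_len * 1.4 + params$waviness_amp + 4 * sigma +
      (npf / 2) * fib_step
    ri <- which(abs(xy - ctr[2]) <= r)
    ci <- which(abs(xy - ctr[1]) <= r)
    if (!length(ri) || !length(ci)) return(invisible())
    Xs <- matrix(xy[ci], length(ri), length(ci), byrow = TRUE)
    Ys <- matrix(xy[ri], length(ri), length(ci))
    s <- cos(th) * (Xs - ctr[1]) + sin(th) * (Ys - ctr[2])
    d <- -sin(th) * (Xs - ctr[1]) + cos(th) * (Ys - ctr[2])
    env_s <- if (is.finite(params$segment_length)) {
      exp(-s^2 / (2 * (seg_len / 1.6)^2))
    } else 1  # unbroken fibres: no along-fibre envelope
    doffs <- (seq_len(npf) - (npf + 1) / 2) * fib_step +
      stats::runif(npf, -0.8, 0.8)
    sub <- img[ri, ci]
    for (f in seq_len(npf)) {
      ridge <- doffs[f] +
        params$waviness_amp * sin(2 * pi * s / params$waviness_period +
                                    phase)
      sub <- pmax(sub, bright * exp(-(d - ridge)^2 / (2 * sigma^2)) * env_s)
    }
    img[ri, ci] <<- sub
    invisible()
  }

  offs <- seq(-diag_len / 2, diag_len / 2, by = params$bundle_spacing)
  offs <- offs + stats::runif(length(offs), -params$bundle_spacing / 3,
                              params$bundle_spacing / 3)
  for (b in seq_along(offs)) {
    bright_b <- stats::rlnorm(1, 0, params$brightness_sdlog)
    c0 <- stats::runif(1, -extent * 0.7, extent * 0.7)
    start <- c(cos(th0) * c0 - sin(th0) * offs[b],
               sin(th0) * c0 + cos(th0) * offs[b])
    if (!is.finite(params$segment_length)) {
      ## continuous fibres spanning the field: a single centred segment
      th <- th0 + stats::rnorm(1, 0, params$dispersion_sd) * pi / 180
      paint_seg(start, th, bright_b * stats::rlnorm(1, 0, 0.3),
                stats::runif(1, 0, 2 * pi))
      next
    }
    for (dir in c(1, -1)) {
      pos <- start
      for (k in seq_len(n_seg_half)) {
        th <- th0 + stats::rnorm(1, 0, params$dispersion_sd) * pi / 180
        u <- dir * c(cos(th), sin(th))
        ctr <- pos + u * seg_len / 2
        paint_seg(ctr, th, bright_b * stats::rlnorm(1, 0, 0.3),
                  stats::runif(1, 0, 2 * pi))
        pos <- pos + u * seg_len
        if (max(abs(pos)) > extent * 0.9) break
      }
    }
  }
  mx <- max(img)
  if (mx > 0) img <- img * (params$intensity_peak / mx)
  if (params$background_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, params$background_sd), n, n)
    img <- pmax(img, 0)
  }
  fibre_image(img, params$pixel_size, provenance = "synthetic",
              ground_truth = params)
}

#' Write / read a fibre image as 16-bit TIFF with a JSON sidecar
#'
#' The TIFF stores intensities scaled to the 16-bit range; the sidecar
#' (`<path>.json`) records the physical pixel size, the count scale and,
#' for synthetic images, the generating ground-truth parameters, so a
#' round trip restores the image exactly (to 16-bit quantisation).
#'
#' @param img A `fibre_image`.
#' @param path Output TIFF path.
#' @param max_count Count value mapped to the top of the 16-bit range.
#' @return `write_fibre_tiff` returns `path` invisibly; `read_fibre_tiff`
#'   returns a `fibre_image`.
#' @export
write_fibre_tiff <- function(img, path, max_count = NULL) {
  stopifnot(inherits(img, "fibre_image"))
  max_count <- max_count %||% max(img$pixels, 1)
  tiff::writeTIFF(pmin(img$pixels / max_count, 1), path,
                  bits.per.sample = 16L, compression = "none")
  side <- list(pixel_size_um = img$pixel_size,
               max_count = max_count,
               provenance = img$provenance)
  if (!is.null(img$ground_truth)) {
    side$ground_truth <- unclass(img$ground_truth)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fibre_tiff
#' @export
read_fibre_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  side_path <- paste0(path, ".json")
  stop_if(!file.exists(side_path),
          sprintf("sidecar '%s' not found; pixel size unknown", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  gt <- if (!is.null(side$ground_truth)) {
    do.call(fibre_params, side$ground_truth)
  }
  fibre_image(px * side$max_count, side$pixel_size_um,
              provenance = side$provenance %||% "measured",
              ground_truth = gt)
}
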