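#' Describe an elliptical canopy element
#'
#' Coordinates are 0-based (row, col) with the origin at the image top-left.
#'
#' @param center_r,center_c Ellipse center (pixels, may be fractional).
#' @param a,b Semi-axes (pixels) along the rotated row/col directions.
#' @param rot Rotation (radians).
#' @return Named numeric vector used by [scene_spec()].
#' @export
ellipse <- function(center_r, center_c, a, b = a, rot = 0) {
  c(center_r = center_r, center_c = center_c, a = a, b = b, rot = rot)
}

#' Specify a synthetic multispectral plant scene
#'
#' The scene is a union of ellipses ("canopy") over a uniform background.
#' Each channel takes its canopy/background intensity from `band_values` /
#' `background_values`; the sensor model applies pixel integration (8x8
#' subpixel supersampled rasterization), an optical Gaussian PSF
#' (`psf_sigma`), additive Gaussian read noise (`noise_sd`, clipped to
#' [0, 1]) and quantization to `bit_depth`.  The NIR channel can be
#' misaligned by a subpixel translation (`nir_shift`) or a 2x3 affine
#' (`nir_affine`), injected analytically: the NIR raster is rasterized at
#' transformed scene coordinates, so the injected transform is exact ground
#' truth rather than an interpolated approximation.
#'
#' Default band intensities emulate healthy foliage on a dark substrate:
#' high NIR reflectance (0.8), low red (0.2, strong chlorophyll
#' absorption), moderate green (0.45), bright chlorophyll fluorescence
#' (0.7) on a uniformly dark (0.05) background.
#'
#' @param height,width Scene size in pixels.
#' @param canopy List of [ellipse()]s (may overlap).
#' @param band_values,background_values Named intensities in [0, 1] for
#'   channels from [channel_labels()].
#' @param noise_sd Gaussian noise SD in normalized intensity units.
#' @param psf_sigma Optical blur sigma in pixels (0 disables).
#' @param nir_shift Length-2 `(dy, dx)`: NIR content displacement relative
#'   to the other channels (see [registration_transform()] conventions).
#' @param nir_affine Optional 2x3 matrix superseding `nir_shift`, in the
#'   moving-to-reference convention `nir(q) = scene(M q)`.
#' @param bit_depth 8 or 16.
#' @param supersample Subpixel sampling factor per axis for pixel
#'   integration (default 8, i.e. 64 coverage samples per pixel).  Finer
#'   sampling reduces residual rasterization aliasing; millipixel-precision
#'   registration studies should raise it (16-32), since at the default the
#'   1/64 coverage granularity itself becomes the dominant edge-position
#'   error.
#' @param seed Integer; fully determines the generated scene.
#' @param plant_id,timepoint,treatment Metadata forwarded to the stack.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 192, width = 192,
                       canopy = list(ellipse((height - 1) / 2,
                                             (width - 1) / 2, 50, 50)),
                       band_values = c(red = 0.2, green = 0.45, blue = 0.15,
                                       nir = 0.8, chlf = 0.7),
                       background_values = c(red = 0.05, green = 0.05,
                                             blue = 0.05, nir = 0.05,
                                             chlf = 0.05),
                       noise_sd = 0.01, psf_sigma = 0.7,
                       nir_shift = c(0, 0), nir_affine = NULL,
                       bit_depth = 8L, supersample = 8L, seed = 1L,
                       plant_id = "synthetic", timepoint = "t0",
                       treatment = NA_real_) {
  stopifnot(height > 0, width > 0, noise_sd >= 0, psf_sigma >= 0,
            bit_depth %in% c(8L, 16L), length(nir_shift) == 2)
  if (any(band_values < 0 | band_values > 1) ||
      any(background_values < 0 | background_values > 1))
    stop_canopyspec("band and background intensities must lie in [0, 1]",
                    "canopyspec_spec_error")
  if (!all(names(band_values) %in% CHANNEL_LABELS))
    stop_canopyspec("band_values names must be channel labels",
                    "canopyspec_spec_error")
  if (!is.null(nir_affine)) nir_affine <- matrix(nir_affine, 2, 3)
  structure(list(height = as.integer(height), width = as.integer(width),
                 canopy = canopy, band_values = band_values,
                 background_values = background_values,
                 noise_sd = noise_sd, psf_sigma = psf_sigma,
                 nir_shift = as.numeric(nir_shift), nir_affine = nir_affine,
                 bit_depth = as.integer(bit_depth),
                 supersample = as.integer(supersample), seed = seed,
                 plant_id = plant_id, timepoint = timepoint,
                 treatment = treatment),
            class = "scene_spec")
}

## ellipse-union coverage fraction per pixel, supersampled ss x ss.
## M (2x3) optionally transforms pixel coordinates before the inclusion
## test: value(q) = indicator(M q), the analytic warp-injection primitive.
rasterize_canopy <- function(canopy, height, width, M = NULL, ss = 8L) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  acc <- matrix(0, height, width)
  base_r <- matrix(0:(height - 1), height, width)
  base_c <- matrix(0:(width - 1), height, width, byrow = TRUE)
  for (or in off) for (oc in off) {
    r <- base_r + or; c <- base_c + oc
    if (!is.null(M)) {
      r2 <- M[1, 1] * r + M[1, 2] * c + M[1, 3]
      c2 <- M[2, 1] * r + M[2, 2] * c + M[2, 3]
      r <- r2; c <- c2
    }
    inside <- matrix(FALSE, height, width)
    for (e in canopy) {
      dr <- r - e["center_r"]; dc <- c - e["center_c"]
      u <- cos(e["rot"]) * dr + sin(e["rot"]) * dc
      v <- -sin(e["rot"]) * dr + cos(e["rot"]) * dc
      inside <- inside | ((u / e["a"])^2 + (v / e["b"])^2 <= 1)
    }
    acc <- acc + inside
  }
  acc / ss^2
}

quantize <- function(x, bit_depth) {
  levels <- 2^bit_depth - 1
  round(x * levels) / levels
}

#' Generate a synthetic multispectral scene with ground truth
#'
#' See [scene_spec()] for the scene model.  The ground-truth mask is the
#' rasterized ellipse union before NIR misalignment (pixels with coverage
#' fraction of at least 1/2), and `true_index_values` are the constant
#' canopy values implied by the band intensities, e.g.
#' `NDVI = (nir - red)/(nir + red)`.
#'
#' @param spec A [scene_spec()].
#' @return A list with `stack` (a [spectral_stack()]) and `truth` (class
#'   `scene_truth`: `mask`, `canopy_size_px`, `true_index_values`,
#'   `injected_transform`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  needed <- names(spec$band_values)
  miss <- setdiff(needed, names(spec$background_values))
  if (length(miss))
    stop_canopyspec(sprintf("background value missing for channel(s): %s",
                            paste(miss, collapse = ", ")),
                    "canopyspec_spec_error")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  ss <- spec$supersample %||% 8L
  cov <- rasterize_canopy(spec$canopy, h, w, ss = ss)
  M_nir <- if (!is.null(spec$nir_affine)) spec$nir_affine
           else if (any(spec$nir_shift != 0))
             cbind(diag(2), -spec$nir_shift)
           else NULL
  cov_nir <- if (is.null(M_nir)) cov
             else rasterize_canopy(spec$canopy, h, w, M = M_nir, ss = ss)
  channels <- list()
  for (ch in needed) {
    cv <- if (ch == "nir") cov_nir else cov
    img <- spec$background_values[[ch]] +
      (spec$band_values[[ch]] - spec$background_values[[ch]]) * cv
    if (spec$psf_sigma > 0) img <- ebi_blur(img, spec$psf_sigma)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    channels[[ch]] <- quantize(pmin(pmax(img, 0), 1), spec$bit_depth)
  }
  mask <- cov >= 0.5   # at least half the pixel is covered by canopy
  bv <- spec$band_values
  tiv <- list()
  if (all(c("nir", "red") %in% needed))
    tiv$NDVI <- unname((bv["nir"] - bv["red"]) / (bv["nir"] + bv["red"]))
  if (all(c("red", "green") %in% needed))
    tiv$ACI <- unname(bv["red"] / bv["green"])
  injected <- registration_transform(
    dy = spec$nir_shift[1], dx = spec$nir_shift[2],
    matrix = spec$nir_affine, moving_channel = "nir")
  list(stack = spectral_stack(channels, plant_id = spec$plant_id,
                              timepoint = spec$timepoint,
                              treatment = spec$treatment,
                              bit_depth_in = spec$bit_depth),
       truth = structure(list(mask = mask,
                              canopy_size_px = as.integer(sum(mask)),
                              true_index_values = tiv,
                              injected_transform = injected),
                         class = "scene_truth"))
}

ebi_blur <- function(img, sigma) {
  matrix(as.numeric(EBImage::gblur(img, sigma)), nrow(img), ncol(img))
}

#' Write a generated scene to image files plus manifest rows
#'
#' 8-bit scenes are written as grayscale PNG, 16-bit scenes as 16-bit TIFF.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return Data frame of manifest rows (`plant_id`, `timepoint`,
#'   `treatment`, `channel`, `file`), paths relative to `dir`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- scene$stack
  rows <- NULL
  for (ch in names(st$channels)) {
    fn <- sprintf("%s_%s_%s.%s", st$plant_id, st$timepoint, ch,
                  if (st$bit_depth_in == 8L) "png" else "tif")
    path <- file.path(dir, fn)
    if (st$bit_depth_in == 8L) {
      png::writePNG(st$channels[[ch]], path)
    } else {
      tiff::writeTIFF(st$channels[[ch]], path, bits.per.sample = 16L)
    }
    rows <- rbind(rows, data.frame(plant_id = st$plant_id,
                                   timepoint = st$timepoint,
                                   treatment = st$treatment,
                                   channel = ch, file = fn,
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Default fertilizer dose-response used by [generate_experiment()]
#'
#' Emulates a controlled-release fertilizer trial on potted plants: canopy
#' radius grows with the applied rate, and canopy NDVI follows the
#' saturating quadratic `NDVI(x) = 0.35 + 0.06 x - 0.00375 x^2`, rising
#' from 0.35 (unfertilized, chlorotic) to about 0.59 at 8 g/pot —
#' healthy-canopy NDVI in the low 0.6s, consistent with top-view imaging of
#' well-fertilized ornamentals.  The red band is held at 0.2 and the NIR
#' band solves `(nir - red)/(nir + red) = NDVI(x)`; chlorophyll
#' fluorescence rises mildly with rate.
#'
#' @param level Treatment level (g/pot).
#' @return List with `radius` (px) and `band_values`; the attribute
#'   `"true_coef"` on the function gives the NDVI-generating coefficients
#'   `(b0, b1, b2)`.
#' @export
default_dose_response <- function(level) {
  ndvi <- 0.35 + 0.06 * level - 0.00375 * level^2
  red <- 0.2
  list(radius = 14 + 2.2 * level,
       band_values = c(red = red, green = 0.45, blue = 0.15,
                       nir = red * (1 + ndvi) / (1 - ndvi),
                       chlf = 0.55 + 0.02 * level))
}
attr(default_dose_response, "true_coef") <- c(b0 = 0.35, b1 = 0.06,
                                              b2 = -0.00375)

#' Generate a full synthetic treatment experiment
#'
#' One scene per (treatment level, replicate), mirroring an
#' eight-replicate, six-rate fertilizer design by default.  Replicate
#' variation is modelled by jittering the canopy radius
#' (multiplicative, `radius_jitter_frac`) and the band intensities
#' (additive Gaussian, `band_jitter_sd`); each scene's NIR channel gets an
#' independent random integer misalignment within `nir_shift_max` pixels,
#' imitating the systematic NIR offset the pipeline must correct.
#'
#' @param levels Numeric treatment levels; defaults to the fertilizer rates
#'   0, 0.5, 1, 2, 4, 8 g/pot.
#' @param reps Replicates per level (default 8).
#' @param response `function(level) -> list(radius, band_values)`;
#'   defaults to [default_dose_response()].
#' @param noise_sd,psf_sigma Sensor model, see [scene_spec()].
#' @param height,width Scene size (smaller than single-scene default to
#'   keep full-design simulations light).
#' @param radius_jitter_frac,band_jitter_sd Replicate-level jitter.
#' @param nir_shift_max Integer; per-scene NIR shifts are drawn uniformly
#'   from `-nir_shift_max..nir_shift_max` on both axes (0 disables).
#' @param seed Integer; fully determines the experiment.
#' @return List with `scenes` (list of [generate_scene()] results, each
#'   also carrying `$level` and `$replicate`), `truth` (a
#'   [response_table()] of the true per-scene canopy NDVI implied by the
#'   jittered band values, metric `"ndvi_true"`), and `true_coef` (the
#'   generating NDVI coefficients, or NULL if `response` does not declare
#'   them).
#' @export
generate_experiment <- function(levels = c(0, 0.5, 1, 2, 4, 8), reps = 8,
                                response = default_dose_response,
                                noise_sd = 0.01, psf_sigma = 0.7,
                                height = 96, width = 96,
                                radius_jitter_frac = 0.03,
                                band_jitter_sd = 0.01,
                                nir_shift_max = 3L, seed = 1L) {
  stopifnot(reps >= 1, length(levels) >= 1)
  set.seed(seed)
  scenes <- list()
  tt <- NULL
  k <- 0
  for (lv in levels) for (r in seq_len(reps)) {
    k <- k + 1
    base <- response(lv)
    radius <- base$radius * (1 + rnorm(1, 0, radius_jitter_frac))
    bv <- pmin(pmax(base$band_values +
                      rnorm(length(base$band_values), 0, band_jitter_sd),
                    0.01), 0.99)
    shift <- if (nir_shift_max > 0)
      sample(seq(-nir_shift_max, nir_shift_max), 2, replace = TRUE)
    else c(0, 0)
    sp <- scene_spec(
      height = height, width = width,
      canopy = list(ellipse((height - 1) / 2, (width - 1) / 2,
                            radius, radius)),
      band_values = bv, noise_sd = noise_sd, psf_sigma = psf_sigma,
      nir_shift = shift, seed = sample.int(.Machine$integer.max - 1, 1),
      plant_id = sprintf("L%g_r%d", lv, r), timepoint = "t0",
      treatment = lv)
    sc <- generate_scene(sp)
    sc$level <- lv; sc$replicate <- r
    scenes[[k]] <- sc
    tt <- rbind(tt, data.frame(
      cultivar = "synthetic", treatment = lv, replicate = r,
      metric_name = "ndvi_true",
      value = unname((bv["nir"] - bv["red"]) / (bv["nir"] + bv["red"])),
      stringsAsFactors = FALSE))
  }
  class(tt) <- c("response_table", "data.frame")
  list(scenes = scenes, truth = tt,
       true_coef = attr(response, "true_coef", exact = TRUE))
}
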