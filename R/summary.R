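#' Summarise one plant at one timepoint
#'
#' Collects the scalar canopy metrics: projected canopy size (mask pixel
#' count), mean/population-SD of each index map over its valid pixels, and
#' the mean chlorophyll-fluorescence intensity over the mask.  The
#' fluorescence mean uses the mask itself (not any index's valid set),
#' since fluorescence is what defines the mask.
#'
#' @param stack A [spectral_stack()].
#' @param mask The [compute_mask()] result for that stack.
#' @param maps List of [compute_index()] maps computed from this
#'   stack/mask (any subset of NDVI/ACI).
#' @return An object of class `canopy_summary`; `as.data.frame()` yields
#'   the standard single-row summary.
#' @export
summarize_plant <- function(stack, mask, maps = list()) {
  stopifnot(inherits(stack, "spectral_stack"), inherits(mask, "plant_mask"))
  out <- list(plant_id = stack$plant_id, timepoint = stack$timepoint,
              treatment = stack$treatment,
              canopy_size_px = mask_pixel_count(mask),
              ndvi_mean = NA_real_, ndvi_sd = NA_real_,
              aci_mean = NA_real_, aci_sd = NA_real_,
              chlf_mean = NA_real_)
  for (map in maps) {
    s <- index_statistics(map)
    key <- tolower(map$name)
    if (key %in% c("ndvi", "aci")) {
      out[[paste0(key, "_mean")]] <- s$mean
      out[[paste0(key, "_sd")]] <- s$sd
    }
  }
  if ("chlf" %in% names(stack$channels) && any(mask$mask))
    out$chlf_mean <- mean(stack$channels$chlf[mask$mask])
  structure(out, class = "canopy_summary")
}

#' @export
as.data.frame.canopy_summary <- function(x, ...) {
  data.frame(plant_id = x$plant_id, timepoint = x$timepoint,
             treatment = x$treatment, canopy_size_px = x$canopy_size_px,
             ndvi_mean = x$ndvi_mean, ndvi_sd = x$ndvi_sd,
             aci_mean = x$aci_mean, aci_sd = x$aci_sd,
             chlf_mean = x$chlf_mean, stringsAsFactors = FALSE)
}

#' @export
print.canopy_summary <- function(x, ...) {
  cat(sprintf("<canopy_summary> %s @ %s: %d px", x$plant_id, x$timepoint,
              x$canopy_size_px))
  if (!is.na(x$ndvi_mean))
    cat(sprintf(", NDVI %.4f +/- %.4f", x$ndvi_mean, x$ndvi_sd))
  if (!is.na(x$chlf_mean)) cat(sprintf(", ChlF %.4f", x$chlf_mean))
  cat("\n")
  invisible(x)
}

#' Histogram of an index map's valid pixels
#'
#' Counts over `bins` equal-width bins spanning `range`; values outside the
#' range are clipped into the end bins, so counts always sum to the number
#' of valid pixels.
#'
#' @param map An [compute_index()] result.
#' @param bins Number of bins (>= 1); default 50.
#' @param range Length-2 numeric; defaults to the index's theoretical range
#'   ([-1, 1] for NDVI) or the data range otherwise.
#' @return An object of class `index_histogram` with `bin_edges` (length
#'   `bins + 1`), `counts` (length `bins`) and `index_name`.
#' @export
compute_histogram <- function(map, bins = 50L, range = NULL) {
  stopifnot(inherits(map, "index_map"), bins >= 1)
  v <- map$values[map$valid]
  if (is.null(range)) {
    range <- if (toupper(map$name) == "NDVI") c(-1, 1)
             else if (length(v)) base::range(v) else c(0, 1)
    if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  }
  stopifnot(length(range) == 2, range[1] < range[2])
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- integer(bins)
  if (length(v)) {
    v <- pmin(pmax(v, range[1]), range[2])
    bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                bins)
    counts <- tabulate(bin, nbins = bins)
  }
  structure(list(bin_edges = edges, counts = counts, index_name = map$name),
            class = "index_histogram")
}

#' @export
print.index_histogram <- function(x, ...) {
  cat(sprintf("<index_histogram> %s: %d bins over [%.3g, %.3g], %d px\n",
              x$index_name, length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

#' Write a histogram as CSV (bin edges and counts)
#'
#' @param hist An [compute_histogram()] result.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_histogram <- function(hist, path) {
  df <- data.frame(bin_left = hist$bin_edges[-length(hist$bin_edges)],
                   bin_right = hist$bin_edges[-1], count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Render an index map as a false-color RGB raster
#'
#' Valid pixels are mapped linearly (with clipping) from `[vmin, vmax]`
#' onto a 256-level colormap; invalid pixels render black.  The mapping is
#' `level = floor(255 * (x - vmin) / (vmax - vmin)) + 1` clipped to
#' 1..256, so the midpoint value maps to level 128.  Rendering is a pure
#' function of (map, vmin, vmax, colormap), hence byte-identical across
#' calls.
#'
#' @param map An [compute_index()] result.
#' @param vmin,vmax Display range; `vmin < vmax`.  The NDVI pipeline
#'   default is `[-0.2, 0.9]`, stable across timepoints for comparison.
#' @param colormap A palette name understood by [grDevices::hcl.colors()]
#'   (default `"Viridis"`); recorded in the output's `colormap` attribute.
#' @return A height x width x 3 numeric array in [0, 1] with attribute
#'   `colormap`.
#' @export
render_false_color <- function(map, vmin = -0.2, vmax = 0.9,
                               colormap = "Viridis") {
  stopifnot(inherits(map, "index_map"))
  if (vmin >= vmax)
    stop_canopyspec("vmin must be strictly less than vmax",
                    "canopyspec_validation_error")
  pal <- grDevices::hcl.colors(256, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  v <- map$values
  lvl <- floor(255 * (v - vmin) / (vmax - vmin)) + 1
  lvl <- pmin(pmax(lvl, 1), 256)
  out <- array(0, dim = c(nrow(v), ncol(v), 3))
  ok <- map$valid & !is.na(lvl)
  for (k in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- rgb[k, lvl[ok]]
    out[, , k] <- plane
  }
  attr(out, "colormap") <- colormap
  out
}

#' Write a false-color rendering to PNG
#'
#' A color scale bar (a 16 x 256 strip running from `vmin` at the left to
#' `vmax` at the right through the same colormap) is emitted alongside as
#' `<path minus extension>_scale.png`.
#'
#' @inheritParams render_false_color
#' @param path Output PNG path.
#' @param scale_bar Also write the scale-bar strip (default TRUE).
#' @return `path`, invisibly.
#' @export
write_false_color <- function(map, path, vmin = -0.2, vmax = 0.9,
                              colormap = "Viridis", scale_bar = TRUE) {
  img <- render_false_color(map, vmin, vmax, colormap)
  png::writePNG(img, path)
  if (scale_bar) {
    rgb <- grDevices::col2rgb(grDevices::hcl.colors(256, colormap)) / 255
    strip <- array(0, dim = c(16, 256, 3))
    for (k in 1:3) strip[, , k] <- matrix(rgb[k, ], 16, 256, byrow = TRUE)
    png::writePNG(strip, sub("\\.png$", "_scale.png", path))
  }
  invisible(path)
}
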