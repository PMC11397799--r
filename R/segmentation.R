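#' Segmentation parameters
#'
#' @param method Threshold rule for the chlorophyll-fluorescence channel:
#'   `"otsu"` (parameter-free, between-class-variance maximizing; the
#'   default) or `"fixed"` (explicit `fixed_threshold`).
#' @param fixed_threshold Intensity threshold in [0, 1]; required iff
#'   `method = "fixed"`.
#' @param open_radius,close_radius Radii (px, non-negative integers) of the
#'   disc structuring elements for morphological opening then closing;
#'   radius 0 skips the operation.
#' @param min_component_px Connected components (8-connectivity) smaller
#'   than this pixel count are removed.  The default of 50 px keeps
#'   trailing shoots that image as separate blobs while dropping specks.
#' @param keep `"all_components"` (default; a trailing plant may be several
#'   blobs) or `"largest_only"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                open_radius = 0L, close_radius = 0L,
                                min_component_px = 50L,
                                keep = c("all_components", "largest_only")) {
  method <- match.arg(method)
  keep <- match.arg(keep)
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop_canopyspec("method = 'fixed' requires fixed_threshold",
                      "canopyspec_validation_error")
    stopifnot(fixed_threshold >= 0, fixed_threshold <= 1)
  }
  stopifnot(open_radius >= 0, close_radius >= 0, min_component_px >= 0)
  structure(list(method = method, fixed_threshold = fixed_threshold,
                 open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius),
                 min_component_px = as.integer(min_component_px),
                 keep = keep),
            class = "segmentation_params")
}

## label connected components of a logical matrix under 8-connectivity.
## (EBImage::bwlabel is 4-connected, so the adjacency graph is built
## explicitly.)  Returns an integer matrix, 0 = background.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  n <- length(fg)
  if (!n) return(lab)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[fg] <- seq_len(n)
  coords <- arrayInd(fg, dim(mask))
  edges <- vector("list", 4)
  k <- 0
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- coords[, 1] + d[1]; c2 <- coords[, 2] + d[2]
    ok <- r2 >= 1 & r2 <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask)
    j <- idx[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    k <- k + 1
    edges[[k]] <- cbind(idx[fg][ok][keep], j[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || !nrow(edges)) {
    comp <- seq_len(n)
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
  }
  lab[fg] <- as.integer(comp)
  lab
}

#' Segment the plant from the chlorophyll-fluorescence channel
#'
#' Only tissue with functioning chlorophyll fluoresces under blue
#' excitation, so thresholding the fluorescence channel isolates the
#' photosynthetically active canopy.  Pixels strictly above the threshold
#' are foreground; the mask is then cleaned by morphological opening,
#' closing, small-component removal, and (optionally) retention of the
#' largest component only.
#'
#' @param stack A [spectral_stack()] containing a `chlf` channel.
#' @param params A [segmentation_params()] object.
#' @return An object of class `plant_mask` with fields `mask` (logical
#'   matrix), `threshold_used`, `n_components` (8-connectivity), and
#'   `source` (`"chlf"`).  An all-background image yields an empty mask
#'   (flagged by `n_components = 0`), not an error.
#' @export
compute_mask <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "spectral_stack"))
  chlf <- get_channel(stack, "chlf", "compute_mask")
  if (params$method == "otsu") {
    if (diff(range(chlf)) < 1e-9)
      stop_canopyspec(
        "Otsu thresholding is undefined on a constant fluorescence image",
        "canopyspec_degenerate_histogram_error")
    thr <- EBImage::otsu(chlf, range = c(0, 1), levels = 256)
  } else {
    thr <- params$fixed_threshold
  }
  mask <- chlf > thr                       # strict inequality
  if (params$open_radius > 0)
    mask <- ebi_morph(mask, params$open_radius, EBImage::opening)
  if (params$close_radius > 0)
    mask <- ebi_morph(mask, params$close_radius, EBImage::closing)
  lab <- label_components(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_component_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
    if (params$keep == "largest_only" && any(sizes >= params$min_component_px)) {
      keep_id <- which.max(sizes)
      mask <- lab == keep_id & mask
    }
    lab <- label_components(mask)
  }
  structure(list(mask = mask, threshold_used = as.numeric(thr),
                 n_components = max(lab), source = "chlf"),
            class = "plant_mask")
}

ebi_morph <- function(mask, radius, op) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- op(mask * 1, brush)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d px foreground, %d component(s), threshold %.4f (%s)\n",
              sum(x$mask), x$n_components, x$threshold_used, x$source))
  invisible(x)
}

#' Projected canopy size in pixels
#'
#' The number of foreground pixels of the plant mask: the 2-D projection of
#' the canopy as seen from above, a non-destructive proxy for biomass.
#'
#' @param mask A [compute_mask()] result (or a plain logical matrix).
#' @return Integer pixel count.
#' @export
mask_pixel_count <- function(mask) {
  m <- if (inherits(mask, "plant_mask")) mask$mask else mask
  as.integer(sum(m))
}
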