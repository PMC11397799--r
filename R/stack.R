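#' Construct a spectral stack
#'
#' A spectral stack is the co-registered set of single-wavelength rasters
#' for one plant at one timepoint.  All channels share dimensions, and all
#' intensities are normalized to [0, 1].
#'
#' @param channels Named list of numeric matrices, names from
#'   [channel_labels()], all with identical dimensions and values in [0, 1].
#' @param plant_id,timepoint Identifiers carried through to summaries.
#' @param treatment Optional numeric treatment level (e.g. fertilizer g/pot
#'   or solution pH); `NA` when unknown.
#' @param bit_depth_in Bit depth of the source images (8 or 16); purely
#'   informational once intensities are normalized.
#'
#' @return An object of class `spectral_stack` with fields `channels`,
#'   `height`, `width`, `bit_depth_in`, `plant_id`, `timepoint`,
#'   `treatment`, and `oob` (a named list of logical matrices flagging
#'   pixels moved out of frame by registration, empty until
#'   [apply_transform()] runs).
#' @export
spectral_stack <- function(channels, plant_id = "plant", timepoint = "t0",
                           treatment = NA_real_, bit_depth_in = 8L) {
  if (!length(channels))
    stop_canopyspec("a spectral stack needs at least one channel",
                    "canopyspec_stack_error")
  bad <- setdiff(names(channels), CHANNEL_LABELS)
  if (length(bad))
    stop_canopyspec(sprintf(
      "unknown channel label(s) %s; allowed labels are: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(CHANNEL_LABELS, collapse = ", ")), "canopyspec_channel_error")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_canopyspec("all channels must have identical height x width",
                    "canopyspec_stack_error")
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop_canopyspec("channel intensities must lie in [0, 1]",
                    "canopyspec_stack_error")
  structure(list(
    channels = channels,
    height = dims[1, 1], width = dims[2, 1],
    bit_depth_in = as.integer(bit_depth_in),
    plant_id = as.character(plant_id),
    timepoint = as.character(timepoint),
    treatment = as.numeric(treatment),
    oob = list()
  ), class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack> %s @ %s: %dx%d px, %d-bit source\n",
              x$plant_id, x$timepoint, x$height, x$width, x$bit_depth_in))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.na(x$treatment)) cat("  treatment:", x$treatment, "\n")
  invisible(x)
}

get_channel <- function(stack, label, caller = "this operation") {
  if (!label %in% names(stack$channels))
    stop_canopyspec(sprintf("channel %s required by %s is missing from the stack",
                            sQuote(label), caller),
                    "canopyspec_missing_channel_error")
  stack$channels[[label]]
}
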