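#' Parse an image manifest
#'
#' The manifest is a UTF-8 CSV with header columns `plant_id`, `timepoint`,
#' `treatment`, `channel`, `file`, one row per single-wavelength image.
#' File paths are resolved relative to `root` (by default the directory
#' containing the manifest).  The (plant_id, timepoint, channel) triple must
#' be unique and channel labels must come from [channel_labels()].
#'
#' @param path Path to the manifest CSV.
#' @param root Directory against which relative `file` paths resolve.
#' @return An object of class `manifest`: a list with `records` (data frame)
#'   and `root`.
#' @export
parse_manifest <- function(path, root = dirname(path)) {
  if (!file.exists(path))
    stop_canopyspec(sprintf("manifest file %s does not exist", sQuote(path)),
                    "canopyspec_io_error")
  rec <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("plant_id", "timepoint", "treatment", "channel", "file")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols))
    stop_canopyspec(sprintf("manifest is missing required column(s): %s",
                            paste(missing_cols, collapse = ", ")),
                    "canopyspec_format_error")
  bad <- setdiff(unique(rec$channel), CHANNEL_LABELS)
  if (length(bad))
    stop_canopyspec(sprintf(
      "manifest contains unknown channel label(s) %s; allowed labels are: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(CHANNEL_LABELS, collapse = ", ")),
      "canopyspec_validation_error")
  key <- paste(rec$plant_id, rec$timepoint, rec$channel, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- rec[which(dup)[1], ]
    stop_canopyspec(sprintf(
      "duplicate manifest entry for (plant_id=%s, timepoint=%s, channel=%s)",
      d$plant_id, d$timepoint, d$channel), "canopyspec_validation_error")
  }
  rec$treatment <- suppressWarnings(as.numeric(rec$treatment))
  structure(list(records = rec, root = root), class = "manifest")
}

#' @export
print.manifest <- function(x, ...) {
  cat(sprintf("<manifest> %d records, %d plants, root: %s\n",
              nrow(x$records), length(unique(x$records$plant_id)), x$root))
  invisible(x)
}

## read one single-channel PNG/TIFF; returns list(values in [0,1], bit_depth)
read_channel_image <- function(path) {
  if (!file.exists(path))
    stop_canopyspec(sprintf("image file %s does not exist", sQuote(path)),
                    "canopyspec_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE, all = TRUE)
    if (is.list(img)) {
      if (length(img) > 1)
        stop_canopyspec(sprintf(
          "%s is a multi-page TIFF; pass it through load_stack(), which maps pages to manifest rows",
          sQuote(path)), "canopyspec_channel_error")
      img <- img[[1]]
    }
    depth <- tiff_depth(img)
  } else {
    stop_canopyspec(sprintf("unsupported image container %s (use PNG or TIFF)",
                            sQuote(ext)), "canopyspec_format_error")
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1)
      stop_canopyspec(sprintf(
        "%s has %d channels; single-channel grayscale expected",
        sQuote(path), dim(img)[3]), "canopyspec_channel_error")
    img <- img[, , 1]
  }
  list(values = strip_attrs(img), bit_depth = as.integer(depth))
}

#' Load a spectral stack through a manifest
#'
#' Reads every channel image recorded for one (plant, timepoint), checks
#' dimensions agree, and assembles a [spectral_stack()].  `readPNG`/
#' `readTIFF` already scale raw digital numbers by `2^bit_depth - 1`, so all
#' returned intensities are normalized to [0, 1].  If several manifest rows
#' for the same plant/timepoint point at one multi-page TIFF, pages are
#' assigned to channels in manifest row order.
#'
#' @param manifest A [parse_manifest()] result.
#' @param plant_id,timepoint Which stack to load.
#' @return A `spectral_stack`.
#' @export
load_stack <- function(manifest, plant_id, timepoint) {
  stopifnot(inherits(manifest, "manifest"))
  rec <- manifest$records
  rec <- rec[rec$plant_id == plant_id & rec$timepoint == timepoint, ,
             drop = FALSE]
  if (!nrow(rec))
    stop_canopyspec(sprintf("no manifest records for (%s, %s)",
                            plant_id, timepoint), "canopyspec_validation_error")
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", rec$file), rec$file,
                  file.path(manifest$root, rec$file))
  channels <- list()
  depth <- 8L
  for (p in unique(paths)) {
    idx <- which(paths == p)
    ext <- tolower(tools::file_ext(p))
    if (length(idx) > 1 && ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(p, info = TRUE, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) < length(idx))
        stop_canopyspec(sprintf(
          "multi-page TIFF %s has %d pages but %d manifest rows reference it",
          sQuote(p), length(pages), length(idx)), "canopyspec_format_error")
      for (k in seq_along(idx)) {
        pg <- pages[[k]]
        if (length(dim(pg)) == 3L) pg <- pg[, , 1]
        depth <- tiff_depth(pages[[k]])
        channels[[rec$channel[idx[k]]]] <- strip_attrs(pg)
      }
    } else {
      ch <- read_channel_image(p)
      channels[[rec$channel[idx[1]]]] <- ch$values
      depth <- ch$bit_depth
    }
  }
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_canopyspec(sprintf(
      "channel images of (%s, %s) do not share dimensions", plant_id,
      timepoint), "canopyspec_stack_error")
  spectral_stack(channels, plant_id = plant_id, timepoint = timepoint,
                 treatment = rec$treatment[1], bit_depth_in = depth)
}

#' Write per-plant canopy summaries to CSV
#'
#' One row per (plant, timepoint) with the stable column order `plant_id`,
#' `timepoint`, `treatment`, `canopy_size_px`, `ndvi_mean`, `ndvi_sd`,
#' `aci_mean`, `aci_sd`, `chlf_mean`.  Undefined statistics (empty masks)
#' are written as `NA`.
#'
#' @param summaries A list of [summarize_plant()] results (or a single one).
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  if (inherits(summaries, "canopy_summary")) summaries <- list(summaries)
  if (!length(summaries))
    stop_canopyspec("no summaries to write", "canopyspec_validation_error")
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop_canopyspec(sprintf("cannot write summaries to %s: %s", sQuote(path),
                            conditionMessage(ok)), "canopyspec_io_error")
  invisible(df)
}

strip_attrs <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

## bits.per.sample lands in different attributes depending on readTIFF args
tiff_depth <- function(pg) {
  attr(pg, "bits.per.sample") %||%
    attr(pg, "info")$bits.per.sample %||% 8L
}

summary_columns <- function() {
  c("plant_id", "timepoint", "treatment", "canopy_size_px",
    "ndvi_mean", "ndvi_sd", "aci_mean", "aci_sd", "chlf_mean")
}
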