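#' Analyse one spectral stack end to end
#'
#' Runs the standard pipeline: (1) estimate and apply the NIR registration
#' correction against the reference channel; (2) segment the plant from
#' the chlorophyll-fluorescence channel; (3) compute the requested index
#' maps over the mask; (4) summarise.  Registration falls back to the
#' identity (with a warning) when the correlation peak confidence is below
#' `min_confidence`, so one degenerate image does not abort a batch.
#'
#' The mask is computed after registration so that the mask frame matches
#' all index channels.
#'
#' @param stack A [spectral_stack()].
#' @param register `"shift"` (default), `"affine"`, or `"none"`.
#' @param reference Reference channel for registration; default `"red"`
#'   because NDVI pairs NIR against red, which minimizes NDVI misalignment
#'   artifacts.
#' @param upsample Subpixel factor for shift estimation.
#' @param seg A [segmentation_params()] object.
#' @param indices Character subset of `c("ndvi", "aci")`.
#' @param aci_formula Formula string for the ACI map.
#' @param min_confidence Registration confidence below which the identity
#'   transform is used instead.
#' @return An object of class `canopy_analysis`: list with `stack` (after
#'   registration), `transform`, `mask`, `maps` (named by index), and
#'   `summary` (a `canopy_summary`).
#' @export
analyze_stack <- function(stack, register = c("shift", "affine", "none"),
                          reference = "red", upsample = 20,
                          seg = segmentation_params(),
                          indices = c("ndvi", "aci"),
                          aci_formula = "red/green",
                          min_confidence = 0.1) {
  register <- match.arg(register)
  transform <- registration_transform(0, 0)   # identity
  if (register != "none" &&
      all(c(reference, "nir") %in% names(stack$channels))) {
    ref <- get_channel(stack, reference, "registration")
    mov <- get_channel(stack, "nir", "registration")
    fell_back <- FALSE
    transform <- tryCatch(
      if (register == "shift") estimate_shift(ref, mov, upsample = upsample)
      else estimate_affine(ref, mov),
      canopyspec_error = function(e) {
        warning("registration failed (", conditionMessage(e),
                "); using identity", call. = FALSE)
        fell_back <<- TRUE
        registration_transform(0, 0, peak_confidence = 0)
      })
    if (!fell_back && transform$peak_confidence < min_confidence) {
      warning(sprintf(
        "registration confidence %.3f below %.2f; using identity transform",
        transform$peak_confidence, min_confidence), call. = FALSE)
      transform <- registration_transform(0, 0,
                                          peak_confidence = transform$peak_confidence)
    }
    stack <- apply_transform(stack, transform)
  }
  mask <- compute_mask(stack, seg)
  maps <- list()
  if ("ndvi" %in% indices &&
      all(c("nir", "red") %in% names(stack$channels)))
    maps$ndvi <- compute_ndvi(stack, mask)
  if ("aci" %in% indices &&
      all(c("red", "green") %in% names(stack$channels)))
    maps$aci <- compute_aci(stack, mask, formula = aci_formula)
  structure(list(stack = stack, transform = transform, mask = mask,
                 maps = maps,
                 summary = summarize_plant(stack, mask, maps)),
            class = "canopy_analysis")
}

#' @export
print.canopy_analysis <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Analyse every plant/timepoint in a manifest
#'
#' @param manifest A [parse_manifest()] result.
#' @param ... Passed to [analyze_stack()].
#' @param out Optional directory: when given, writes `summaries.csv` plus
#'   per-plant false-color PNGs and histogram CSVs there.
#' @return Data frame of per-plant summaries (one row per
#'   plant/timepoint).
#' @export
batch_analyze <- function(manifest, ..., out = NULL) {
  stopifnot(inherits(manifest, "manifest"))
  rec <- unique(manifest$records[c("plant_id", "timepoint")])
  summaries <- list()
  for (i in seq_len(nrow(rec))) {
    stack <- load_stack(manifest, rec$plant_id[i], rec$timepoint[i])
    an <- analyze_stack(stack, ...)
    summaries[[i]] <- an$summary
    if (!is.null(out)) {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      tag <- sprintf("%s_%s", rec$plant_id[i], rec$timepoint[i])
      for (nm in names(an$maps)) {
        rng <- if (nm == "ndvi") c(-0.2, 0.9) else c(0, 2)
        write_false_color(an$maps[[nm]],
                          file.path(out, sprintf("%s_%s.png", tag, nm)),
                          vmin = rng[1], vmax = rng[2])
        write_histogram(compute_histogram(an$maps[[nm]]),
                        file.path(out, sprintf("%s_%s_hist.csv", tag, nm)))
      }
    }
  }
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  if (!is.null(out))
    write.csv(df, file.path(out, "summaries.csv"), row.names = FALSE)
  df
}

#' Analyse a generated experiment and fit the dose-response
#'
#' Convenience wrapper used by simulation studies and the validation
#' script: runs [analyze_stack()] on every scene of a
#' [generate_experiment()] result, assembles the chosen metric into a
#' [response_table()], and fits the quadratic treatment response.
#'
#' @param experiment A [generate_experiment()] result.
#' @param metric `"ndvi_mean"`, `"canopy_size_px"`, `"chlf_mean"`, ...
#' @param ... Passed to [analyze_stack()].
#' @return List with `summaries` (data frame), `table`
#'   (a `response_table`), and `fit` (a [fit_quadratic()] result).
#' @export
analyze_experiment <- function(experiment, metric = "ndvi_mean", ...) {
  summaries <- lapply(experiment$scenes,
                      function(sc) analyze_stack(sc$stack, ...)$summary)
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  tab <- response_from_summaries(df, metric, cultivar = "synthetic")
  list(summaries = df, table = tab,
       fit = fit_quadratic(tab, metric_name = metric))
}
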