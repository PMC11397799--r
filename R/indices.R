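#' Spectral index formula registry
#'
#' Two-band index formulas are written as strings: a ratio `"red/green"` or
#' a normalized difference `"nd(nir,red)"`, with band names from
#' [channel_labels()].  The registry keeps the pipeline self-describing:
#' every index map records the `formula_id` it was computed with.
#'
#' @param formula Formula string.
#' @return A list with `fun(stack)` returning `list(values, defined)` and
#'   the normalized `formula_id`.
#' @keywords internal
parse_index_formula <- function(formula) {
  formula <- gsub(" ", "", formula)
  nd <- regmatches(formula, regexec("^nd\\((\\w+),(\\w+)\\)$", formula))[[1]]
  if (length(nd) == 3) {
    a <- nd[2]; b <- nd[3]
    check_band <- c(a, b)
    fun <- function(stack) {
      x <- get_channel(stack, a, formula); y <- get_channel(stack, b, formula)
      s <- x + y
      list(values = ifelse(s > 0, (x - y) / ifelse(s > 0, s, 1), NA_real_),
           defined = s > 0)
    }
  } else {
    rt <- regmatches(formula, regexec("^(\\w+)/(\\w+)$", formula))[[1]]
    if (length(rt) != 3)
      stop_canopyspec(sprintf(
        "cannot parse index formula %s (use 'a/b' or 'nd(a,b)')",
        sQuote(formula)), "canopyspec_validation_error")
    a <- rt[2]; b <- rt[3]
    check_band <- c(a, b)
    fun <- function(stack) {
      x <- get_channel(stack, a, formula); y <- get_channel(stack, b, formula)
      list(values = ifelse(y > 0, x / ifelse(y > 0, y, 1), NA_real_),
           defined = y > 0)
    }
  }
  bad <- setdiff(check_band, CHANNEL_LABELS)
  if (length(bad))
    stop_canopyspec(sprintf("unknown band(s) %s in index formula",
                            paste(sQuote(bad), collapse = ", ")),
                    "canopyspec_validation_error")
  list(fun = fun, formula_id = formula, bands = check_band)
}

#' Compute a per-pixel index map over the plant mask
#'
#' Values are computed per pixel on normalized intensities, only where the
#' pixel is (i) inside the plant mask, (ii) has a well-defined denominator,
#' and (iii) was not moved out of frame by registration.  All other pixels
#' hold `NA` and are excluded from every downstream statistic.
#'
#' @param stack A registered [spectral_stack()].
#' @param mask A [compute_mask()] result.
#' @param name Index name recorded in the map (e.g. `"NDVI"`).
#' @param formula Formula string, see [parse_index_formula()].
#' @return An object of class `index_map` with fields `name`, `values`
#'   (numeric matrix, `NA` at invalid pixels), `valid` (logical matrix) and
#'   `formula_id`.
#' @export
compute_index <- function(stack, mask, name, formula) {
  stopifnot(inherits(stack, "spectral_stack"), inherits(mask, "plant_mask"))
  pf <- parse_index_formula(formula)
  res <- pf$fun(stack)
  valid <- mask$mask & res$defined
  for (b in pf$bands)
    if (!is.null(stack$oob[[b]])) valid <- valid & !stack$oob[[b]]
  values <- res$values
  values[!valid] <- NA_real_
  structure(list(name = name, values = values, valid = valid,
                 formula_id = pf$formula_id),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  s <- index_statistics(x)
  cat(sprintf("<index_map> %s [%s]: %d valid px, mean %.4f, sd %.4f\n",
              x$name, x$formula_id, s$n_valid,
              s$mean %||% NA, s$sd %||% NA))
  invisible(x)
}

#' Normalized difference vegetation index, per pixel
#'
#' `NDVI = (NIR - red) / (NIR + red)` for every masked pixel; near 1 for
#' healthy dense vegetation.  Registration of the NIR channel should be
#' applied before calling this.
#'
#' @inheritParams compute_index
#' @return An `index_map` named `"NDVI"` with values in [-1, 1].
#' @export
compute_ndvi <- function(stack, mask) {
  compute_index(stack, mask, "NDVI", "nd(nir,red)")
}

#' Anthocyanin content index, per pixel
#'
#' Anthocyanin accumulation reddens foliage; the default formula is the
#' red/green ratio, chosen because this class of five-band system lacks the
#' red-edge bands of standard anthocyanin indices.  Any two-band formula
#' can be substituted; the map records the formula actually used.
#'
#' @inheritParams compute_index
#' @param formula Two-band formula string (default `"red/green"`).
#' @return An `index_map` named `"ACI"`.
#' @export
compute_aci <- function(stack, mask, formula = "red/green") {
  compute_index(stack, mask, "ACI", formula)
}

#' Mean and population SD of an index map over its valid pixels
#'
#' @param map An [compute_index()] result.
#' @return A list with `mean`, `sd` (population, i.e. divisor `n`),
#'   `n_valid`, and `defined` (FALSE when no valid pixel exists; `mean` and
#'   `sd` are then `NA`, never silently propagated NaN).
#' @export
index_statistics <- function(map) {
  stopifnot(inherits(map, "index_map"))
  v <- map$values[map$valid]
  n <- length(v)
  if (!n)
    return(list(mean = NA_real_, sd = NA_real_, n_valid = 0L,
                defined = FALSE))
  m <- mean(v)
  list(mean = m, sd = sqrt(mean((v - m)^2)), n_valid = n, defined = TRUE)
}
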