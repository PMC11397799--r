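#' Build a treatment-response table
#'
#' Long-format table of one metric value per plant: cultivar, numeric
#' treatment level, replicate index, metric name, value.  This is the input
#' to [fit_quadratic()] and [group_means()].
#'
#' @param cultivar,metric_name Character vectors (recycled).
#' @param treatment Numeric treatment levels (finite).
#' @param replicate Integer replicate indices.
#' @param value Numeric metric values (finite).
#' @return A data frame of class `response_table`.
#' @export
response_table <- function(cultivar, treatment, replicate, metric_name,
                           value) {
  df <- data.frame(cultivar = as.character(cultivar),
                   treatment = as.numeric(treatment),
                   replicate = as.integer(replicate),
                   metric_name = as.character(metric_name),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  if (any(!is.finite(df$treatment)) || any(!is.finite(df$value)))
    stop_canopyspec("treatment levels and values must be finite",
                    "canopyspec_validation_error")
  class(df) <- c("response_table", "data.frame")
  df
}

#' Assemble a response table from canopy summaries
#'
#' @param summaries Data frame from [write_summaries()]/[batch_analyze()]
#'   (or list of `canopy_summary`).
#' @param metric_name Which summary column to extract (e.g. `"ndvi_mean"`,
#'   `"canopy_size_px"`).
#' @param cultivar Cultivar label to attach.
#' @return A [response_table()].
#' @export
response_from_summaries <- function(summaries, metric_name,
                                    cultivar = "unknown") {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  if (!metric_name %in% names(summaries))
    stop_canopyspec(sprintf("metric %s not found in summaries",
                            sQuote(metric_name)),
                    "canopyspec_validation_error")
  ok <- is.finite(summaries[[metric_name]]) & is.finite(summaries$treatment)
  s <- summaries[ok, , drop = FALSE]
  rep_idx <- stats::ave(seq_len(nrow(s)), s$treatment,
                        FUN = seq_along)
  response_table(cultivar, s$treatment, rep_idx, metric_name,
                 s[[metric_name]])
}

subset_response <- function(table, cultivar, metric_name) {
  d <- table
  if (!is.null(cultivar)) d <- d[d$cultivar == cultivar, , drop = FALSE]
  if (!is.null(metric_name))
    d <- d[d$metric_name == metric_name, , drop = FALSE]
  d
}

#' Quadratic treatment-response regression
#'
#' Ordinary least squares of a canopy metric on the treatment level and its
#' square, `y = b0 + b1 x + b2 x^2`, summarised the way dose-response
#' panels report it: the coefficient estimates, `R^2 = 1 - SSE/SST`, and
#' the p-value of the overall regression F-test,
#' `F = ((SST - SSE)/2) / (SSE/(n - 3))` on (2, n - 3) degrees of freedom —
#' the probability of no effect of the treatment on the metric.
#' Per-coefficient t-tests are kept in `coef_table` as supplementary
#' output.  No multiple-testing correction is applied across metrics.
#'
#' @param table A [response_table()].
#' @param cultivar,metric_name Optional filters; fits are always per
#'   cultivar per metric (no pooling).
#' @return An object of class `quadratic_fit` with fields `b0`, `b1`, `b2`,
#'   `r_squared`, `p_value`, `n`, `metric_name`, `cultivar`, `coef_table`.
#' @export
fit_quadratic <- function(table, cultivar = NULL, metric_name = NULL) {
  d <- subset_response(table, cultivar, metric_name)
  if (nrow(d) < 4)
    stop_canopyspec("quadratic fit needs at least 4 observations",
                    "canopyspec_insufficient_data_error")
  if (length(unique(d$treatment)) < 3)
    stop_canopyspec(
      "quadratic fit needs at least 3 distinct treatment levels",
      "canopyspec_rank_deficiency_error")
  fit <- lm(value ~ treatment + I(treatment^2), data = d)
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  p <- unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  cf <- coef(fit)
  structure(list(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]),
                 r_squared = sm$r.squared, p_value = p,
                 n = nrow(d),
                 metric_name = metric_name %||% unique(d$metric_name)[1],
                 cultivar = cultivar %||% unique(d$cultivar)[1],
                 coef_table = sm$coefficients),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf(
    "<quadratic_fit> %s ~ treatment + treatment^2 (%s, n = %d)\n",
    x$metric_name, x$cultivar, x$n))
  cat(sprintf("  y = %.4g + %.4g x + %.4g x^2\n", x$b0, x$b1, x$b2))
  cat(sprintf("  R^2 = %.4f, F-test p = %.4g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' Per-treatment group means with standard errors
#'
#' The replicate mean and standard error (sample SD / sqrt(n)) per
#' treatment level — the error bars of a dose-response panel.  A single
#' replicate yields `sem = NA` (undefined, flagged), constant replicates
#' yield `sem = 0`.
#'
#' @inheritParams fit_quadratic
#' @return Data frame with columns `treatment`, `mean`, `sem`, `n`, sorted
#'   by treatment.
#' @export
group_means <- function(table, cultivar = NULL, metric_name = NULL) {
  d <- subset_response(table, cultivar, metric_name)
  lv <- sort(unique(d$treatment))
  out <- data.frame(treatment = lv, mean = NA_real_, sem = NA_real_,
                    n = NA_integer_)
  for (i in seq_along(lv)) {
    v <- d$value[d$treatment == lv[i]]
    out$mean[i] <- mean(v)
    out$n[i] <- length(v)
    out$sem[i] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  }
  out
}
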