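# Model validation against observed series: alignment and error metrics.

#' Align observed and predicted series on the logger cadence
#'
#' Inner-joins the two series on shared timestamps after thinning both to
#' the eight-hourly logger cadence (00:00 / 08:00 / 16:00). Stamps present
#' in only one series are dropped with a warning count.
#'
#' @param observed,predicted `temperature_series` objects.
#' @param cadence `8` for the logger cadence or `NULL` to join raw stamps.
#' @return A `paired_series` data frame (`time`, `observed`, `predicted`).
#' @export
align_series <- function(observed, predicted, cadence = 8) {
  if (!is.null(cadence) && cadence == 8) {
    observed <- resample_8hourly(observed)
    predicted <- resample_8hourly(predicted)
  }
  key_o <- as.numeric(observed$time)
  key_p <- as.numeric(predicted$time)
  common <- intersect(key_o, key_p)
  if (!length(common))
    stop("observed and predicted series share no timestamps", call. = FALSE)
  dropped <- (length(key_o) - length(common)) +
    (length(key_p) - length(common))
  if (dropped > 0)
    warning(sprintf("%d unmatched timestamps dropped", dropped))
  common <- sort(common)
  out <- data.frame(
    time = as.POSIXct(common, origin = "1970-01-01", tz = "UTC"),
    observed = observed$temp_c[match(common, key_o)],
    predicted = predicted$temp_c[match(common, key_p)])
  structure(out, class = c("paired_series", "data.frame"))
}

#' Error metrics for a paired observed/predicted series
#'
#' Root mean squared error, coefficient of determination, mean error and
#' mean absolute error. A positive mean error indicates the model runs warm
#' relative to observations. `r2_method = "correlation"` (default) squares
#' the Pearson correlation of observed vs predicted; `"ss"` uses
#' `1 - SSE/SST`, which differs off the identity line.
#'
#' @param pairs A `paired_series` from [align_series()].
#' @param r2_method `"correlation"` or `"ss"`.
#' @return Named numeric vector `c(rmse, r2, me, mae)`; `r2` is `NA` when
#'   either series has zero variance.
#' @export
validation_metrics <- function(pairs, r2_method = c("correlation", "ss")) {
  r2_method <- match.arg(r2_method)
  if (nrow(pairs) < 2) stop("need at least two pairs", call. = FALSE)
  err <- pairs$predicted - pairs$observed
  r2 <- if (stats::var(pairs$observed) == 0 || stats::var(pairs$predicted) == 0)
    NA_real_
  else if (r2_method == "correlation")
    stats::cor(pairs$observed, pairs$predicted)^2
  else
    1 - sum(err^2) / sum((pairs$observed - mean(pairs$observed))^2)
  c(rmse = sqrt(mean(err^2)), r2 = r2, me = mean(err), mae = mean(abs(err)))
}

#' Validation table for the three in-clutch logger locations
#'
#' @param observed Named list of `temperature_series` (`base`, `centre`,
#'   `top`).
#' @param predicted Named list of `temperature_series` at the same locations.
#' @param cadence Passed to [align_series()].
#' @return Data frame with one metrics row per location.
#' @export
validation_table <- function(observed, predicted, cadence = 8) {
  locs <- intersect(names(observed), names(predicted))
  if (!length(locs)) stop("no shared locations", call. = FALSE)
  do.call(rbind, lapply(locs, function(l) {
    m <- validation_metrics(align_series(observed[[l]], predicted[[l]],
                                         cadence))
    data.frame(location = l, rmse = m["rmse"], r2 = m["r2"], me = m["me"],
               mae = m["mae"], row.names = NULL)
  }))
}
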