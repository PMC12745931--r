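# Hourly temperature series: a data frame with POSIXct `time` and `temp_c`.

#' Create a temperature series
#'
#' @param time POSIXct timestamps (hourly cadence expected).
#' @param temp_c Temperatures, degC.
#' @param location Optional location label, kept as an attribute and column.
#' @return A `temperature_series` data frame.
#' @export
temperature_series <- function(time, temp_c, location = NULL) {
  stopifnot(inherits(time, "POSIXct"), length(time) == length(temp_c))
  if (any(!is.finite(temp_c))) stop("non-finite temperatures", call. = FALSE)
  df <- data.frame(time = time, temp_c = as.numeric(temp_c))
  if (!is.null(location)) df$location <- location
  structure(df, class = c("temperature_series", "data.frame"))
}

#' Hourly timestamp sequence
#' @param t0 Start time (POSIXct or string parsed as UTC).
#' @param n Number of stamps.
#' @export
series_hours <- function(t0, n) {
  if (is.character(t0)) t0 <- as.POSIXct(t0, tz = "UTC")
  t0 + 3600 * (seq_len(n) - 1)
}

#' Read / write temperature series CSV (`timestamp`, `temp_c`[, `location`])
#' @param path CSV path.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path))
    stop("boundary series file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(d)))
    stop("temperature CSV needs columns 'timestamp' and 'temp_c': ", path,
         call. = FALSE)
  tt <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  temperature_series(tt, d$temp_c, location = d$location)
}

#' @rdname read_temperature_csv
#' @param series A `temperature_series`.
#' @export
write_temperature_csv <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    temp_c = series$temp_c)
  if (!is.null(series$location)) out$location <- series$location
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# check hourly cadence
.assert_hourly <- function(series) {
  dt <- diff(as.numeric(series$time))
  if (length(dt) && any(abs(dt - 3600) > 1))
    stop("series is not on an hourly cadence", call. = FALSE)
  invisible(series)
}

# 24 h centred rolling mean with edge fill (slow seasonal component)
.slow_component <- function(x) {
  n <- length(x)
  if (n < 25) return(rep(mean(x), n))
  s <- as.numeric(stats::filter(x, rep(1 / 24, 24), sides = 2))
  first <- which(!is.na(s))[1]
  last <- max(which(!is.na(s)))
  s[seq_len(first - 1)] <- s[first]
  s[seq(last + 1, length.out = n - last)] <- s[last]
  s
}

#' Translate a measured series to another depth with a damped-diel profile
#'
#' Splits the series into a slow (24 h rolling mean) component and a diel
#' residual, then scales the residual by `exp(-dz / D)` and delays it by
#' `dz / D` radians of the 24 h cycle, where `D = sqrt(2 alpha / omega)` is
#' the diurnal damping depth of the sand. Moving toward the surface
#' (`dz < 0`) amplifies and advances the residual symmetrically.
#'
#' @param series Hourly `temperature_series` measured at depth `z_from`.
#' @param z_from,z_to Depths, m (positive down).
#' @param diffusivity Thermal diffusivity alpha, m^2 s^-1.
#' @param period Forcing period, s (diel).
#' @return A `temperature_series` at `z_to`.
#' @export
adjust_series_depth <- function(series, z_from, z_to, diffusivity,
                                period = 86400) {
  .assert_hourly(series)
  if (abs(z_to - z_from) < 1e-12) return(series)
  omega <- 2 * pi / period
  D <- sqrt(2 * diffusivity / omega)
  dz <- z_to - z_from
  slow <- .slow_component(series$temp_c)
  resid <- series$temp_c - slow
  lag_hours <- dz / D / omega / 3600
  idx <- seq_along(resid)
  shifted <- stats::approx(idx, resid, xout = idx - lag_hours, rule = 2)$y
  temperature_series(series$time, slow + exp(-dz / D) * shifted)
}

#' Resample a series to the eight-hourly logger cadence
#'
#' Keeps stamps at 00:00, 08:00 and 16:00 (UTC), the cadence used when
#' comparing modelled and observed clutch temperatures.
#'
#' @param series A `temperature_series`.
#' @param hours Hours of day to keep.
#' @return The thinned `temperature_series`.
#' @export
resample_8hourly <- function(series, hours = c(0L, 8L, 16L)) {
  hod <- as.integer(format(series$time, "%H", tz = "UTC"))
  min_s <- as.integer(format(series$time, "%M", tz = "UTC"))
  keep <- hod %in% hours & min_s == 0L
  out <- series[keep, , drop = FALSE]
  structure(out, class = c("temperature_series", "data.frame"))
}
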