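# Embryonic development, metabolic heat and per-egg flux schedules.

#' Thermal performance curve for embryonic development rate
#'
#' Asymmetric Gaussian development-rate curve in percent development per
#' hour: rises gently from cool temperatures to a peak in the 33-34 degC
#' band and falls off steeply above it, capturing the decline of development
#' rate at supra-optimal nest temperatures. Parameters are configuration
#' values, not physiological constants; see the methods vignette for how the
#' defaults were chosen.
#'
#' @param r_max_pct_day Peak development rate, percent per day.
#' @param t_opt Temperature of the peak, degC.
#' @param sigma_low,sigma_high Gaussian widths below/above the peak, degC.
#' @return A `dev_rate` function `f(T)` returning percent development per
#'   hour.
#' @export
dev_rate_curve <- function(r_max_pct_day = 2.2, t_opt = 33.5,
                           sigma_low = 9, sigma_high = 3.5) {
  stopifnot(r_max_pct_day > 0, sigma_low > 0, sigma_high > 0)
  f <- function(T) {
    sigma <- ifelse(T < t_opt, sigma_low, sigma_high)
    (r_max_pct_day / 24) * exp(-((T - t_opt)^2) / (2 * sigma^2))
  }
  structure(f, class = c("dev_rate", "function"),
            params = list(r_max_pct_day = r_max_pct_day, t_opt = t_opt,
                          sigma_low = sigma_low, sigma_high = sigma_high))
}

#' Integrate development over an hourly temperature history
#'
#' Maturity accumulates as `min(100, sum(r(T_i) * 1 h))`; the hatch hour is
#' the first hour at which maturity reaches 100%.
#'
#' @param temp_c Hourly temperatures, degC.
#' @param rate A `dev_rate` function.
#' @return List with `maturity` (percent, same length as `temp_c`) and
#'   `hatch_hour` (1-based index into `temp_c`, or `NA`).
#' @export
integrate_development <- function(temp_c, rate = dev_rate_curve()) {
  if (any(!is.finite(temp_c))) stop("non-finite temperatures", call. = FALSE)
  maturity <- pmin(100, cumsum(rate(temp_c)))
  hatch <- which(maturity >= 100)[1]
  list(maturity = maturity, hatch_hour = if (is.na(hatch)) NA_integer_ else hatch)
}

#' Metabolic heat at the 29.5 degC reference, as a function of maturity
#'
#' Exponential-in-maturity heat production: near zero for a fresh egg and
#' rising steeply towards hatching,
#' `h(m) = h_max * (exp(b m / 100) - 1) / (exp(b) - 1)` mW per embryo.
#'
#' @param maturity Percent development, 0-100.
#' @param h_max_mw Heat production at full term, mW per embryo.
#' @param shape Exponential shape `b` (larger = later rise).
#' @return Heat production, mW per embryo, at 29.5 degC.
#' @export
reference_heat <- function(maturity, h_max_mw = 70, shape = 3.5) {
  if (any(maturity < 0 | maturity > 100))
    stop("maturity must lie in [0, 100]", call. = FALSE)
  h_max_mw * (exp(shape * maturity / 100) - 1) / (exp(shape) - 1)
}

#' Q10 temperature adjustment of a metabolic rate
#'
#' `h(T) = h_ref * Q10^((T - T_ref) / 10)`.
#'
#' @param h_ref Rate at the reference temperature (any units).
#' @param temp_c Temperature, degC.
#' @param q10 Q10 coefficient (> 1 for biological rates).
#' @param t_ref Reference temperature, degC.
#' @return Adjusted rate, same units as `h_ref`.
#' @export
q10_adjust <- function(h_ref, temp_c, q10 = 2.0, t_ref = 29.5) {
  if (any(h_ref < 0)) stop("reference rate must be non-negative", call. = FALSE)
  h_ref * q10^((temp_c - t_ref) / 10)
}

#' Temperature-dependent Q10 derived from a development-rate curve
#'
#' Ratio form: `Q10(T) = r(T + 5) / r(T - 5)`, mirroring Q10 coefficients
#' based on expected development rates at each temperature.
#'
#' @param rate A `dev_rate` function.
#' @return Function `Q10(T)`.
#' @export
q10_from_rate <- function(rate = dev_rate_curve()) {
  function(T) rate(T + 5) / rate(T - 5)
}

#' Mortality categories and their clutch proportions
#'
#' Categories follow excavation scoring: `hatched_or_pipped` eggs (full
#' flux through incubation), `full_term_dead` (full flux), `pre_term_dead`
#' (flux terminated at two-thirds of development) and `undeveloped` (no
#' flux). Default proportions are the observed means for modelled nests.
#'
#' @param hatched_or_pipped,full_term_dead,pre_term_dead,undeveloped
#'   Proportions; renormalised to sum to 1.
#' @return Named numeric vector of proportions.
#' @export
mortality_proportions <- function(hatched_or_pipped = 0.374,
                                  full_term_dead = 0.257,
                                  pre_term_dead = 0.311,
                                  undeveloped = 0.047) {
  p <- c(hatched_or_pipped = hatched_or_pipped,
         full_term_dead = full_term_dead,
         pre_term_dead = pre_term_dead,
         undeveloped = undeveloped)
  if (any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
  p / sum(p)
}

#' Randomly assign mortality categories to clutch positions
#'
#' @param n Clutch size.
#' @param proportions From [mortality_proportions()]; `NULL` means all eggs
#'   viable (the unadjusted model).
#' @param seed Integer seed.
#' @return Character vector of categories, length `n`.
#' @export
assign_categories <- function(n, proportions = NULL, seed = 1L) {
  if (is.null(proportions)) return(rep("hatched_or_pipped", n))
  counts <- floor(proportions * n)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- proportions * n - counts
    top_up <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[top_up] <- counts[top_up] + 1
  }
  pool <- rep(names(proportions), counts)
  withr::with_seed(as.integer(seed), sample(pool))
}

#' Build a per-egg hourly heat-flux schedule from a proxy temperature series
#'
#' The three-step flux calculation: (1) integrate development over the proxy
#' series; (2) evaluate maturity-dependent metabolic heat at the 29.5 degC
#' reference; (3) adjust to each hour's temperature with a Q10 coefficient.
#' Fluxes are then gated per egg by mortality category: undeveloped eggs
#' never heat, pre-term-dead eggs stop at two-thirds of development, and all
#' eggs stop at hatching.
#'
#' @param proxy_temp_c Hourly proxy incubation temperatures, degC.
#' @param categories Character vector of per-egg categories (see
#'   [assign_categories()]).
#' @param rate A `dev_rate` function.
#' @param h_max_mw,shape Passed to [reference_heat()].
#' @param q10,t_ref Passed to [q10_adjust()]; `q10` may be a function of
#'   temperature.
#' @return A `flux_schedule`.
#' @export
build_schedule <- function(proxy_temp_c, categories,
                           rate = dev_rate_curve(), h_max_mw = 70,
                           shape = 3.5, q10 = 2.0, t_ref = 29.5) {
  dev <- integrate_development(proxy_temp_c, rate)
  m <- dev$maturity
  h_ref <- reference_heat(m, h_max_mw, shape)
  q10v <- if (is.function(q10)) q10(proxy_temp_c) else q10
  h_mw <- q10_adjust(h_ref, proxy_temp_c, q10v, t_ref)
  hours <- length(proxy_temp_c)
  # per-hour gate: active until hatch (inclusive of the hatching hour)
  active <- if (is.na(dev$hatch_hour)) rep(TRUE, hours) else
    seq_len(hours) <= dev$hatch_hour
  watts <- matrix(0, hours, length(categories))
  for (e in seq_along(categories)) {
    gate <- switch(categories[e],
      undeveloped = rep(FALSE, hours),
      pre_term_dead = active & (m <= 200 / 3),
      full_term_dead = active,
      hatched_or_pipped = active,
      stop("unknown mortality category: ", categories[e], call. = FALSE))
    watts[gate, e] <- h_mw[gate] / 1000
  }
  flux_schedule(watts, categories, hatch_hour = dev$hatch_hour,
                maturity = m)
}

#' Flux schedule container
#'
#' @param watts Matrix (hours x eggs) of heat sources, W per egg.
#' @param categories Per-egg mortality categories.
#' @param hatch_hour Hatch hour of the proxy embryo, or `NA`.
#' @param maturity Optional proxy maturity trajectory.
#' @return A `flux_schedule`.
#' @export
flux_schedule <- function(watts, categories, hatch_hour = NA_integer_,
                          maturity = NULL) {
  stopifnot(is.matrix(watts), ncol(watts) == length(categories))
  if (any(watts < 0)) stop("heat fluxes must be non-negative", call. = FALSE)
  structure(list(watts = watts, categories = categories,
                 hatch_hour = hatch_hour, maturity = maturity),
            class = "flux_schedule")
}

#' @export
print.flux_schedule <- function(x, ...) {
  cat(sprintf(
    "<flux_schedule> %d hours x %d eggs; total energy %.1f kJ; hatch hour %s\n",
    nrow(x$watts), ncol(x$watts), sum(x$watts) * 3600 / 1000,
    ifelse(is.na(x$hatch_hour), "none", x$hatch_hour)))
  invisible(x)
}

#' Metabolic coupling for an online simulation
#'
#' In coupled mode the flux proxy is the simulated centre-egg temperature of
#' the previous hour (one-step lag), so the metabolic source responds to the
#' temperatures the model itself predicts without implicit coupling.
#'
#' @param categories Per-egg mortality categories.
#' @param proxy_egg Index of the proxy egg (the clutch-centre logger egg).
#' @param rate,h_max_mw,shape,q10,t_ref As in [build_schedule()].
#' @return A coupling specification for [run_simulation()].
#' @export
metabolic_coupling <- function(categories, proxy_egg,
                               rate = dev_rate_curve(), h_max_mw = 70,
                               shape = 3.5, q10 = 2.0, t_ref = 29.5) {
  list(categories = categories, proxy_egg = proxy_egg, rate = rate,
       h_max_mw = h_max_mw, shape = shape, q10 = q10, t_ref = t_ref)
}

coupling_init <- function(coupling, n_eggs) {
  stopifnot(length(coupling$categories) == n_eggs,
            coupling$proxy_egg >= 1, coupling$proxy_egg <= n_eggs)
  list(maturity = 0, hatch_hour = NA_integer_, hour = 0L,
       maturity_trace = 0)
}

coupling_fluxes <- function(coupling, state, egg_temp_prev) {
  T_proxy <- egg_temp_prev[coupling$proxy_egg]
  hatched_before <- state$maturity >= 100
  m <- min(100, state$maturity + coupling$rate(T_proxy))
  hour <- state$hour + 1L
  hatch_hour <- state$hatch_hour
  if (is.na(hatch_hour) && m >= 100) hatch_hour <- hour
  h_ref <- reference_heat(m, coupling$h_max_mw, coupling$shape)
  q10v <- if (is.function(coupling$q10)) coupling$q10(T_proxy) else coupling$q10
  h_mw <- q10_adjust(h_ref, T_proxy, q10v, coupling$t_ref)
  watts <- rep(h_mw / 1000, length(coupling$categories))
  watts[coupling$categories == "undeveloped"] <- 0
  if (m > 200 / 3) watts[coupling$categories == "pre_term_dead"] <- 0
  if (hatched_before) watts[] <- 0
  list(state = list(maturity = m, hatch_hour = hatch_hour, hour = hour,
                    maturity_trace = c(state$maturity_trace, m)),
       watts = watts)
}
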