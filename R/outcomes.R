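# Developmental outcomes: duration, sex and hatching success per embryo.

#' Hill reaction norm for temperature-dependent sex determination
#'
#' The logit of the male proportion is linear in log temperature: at constant
#' incubation temperature `T`,
#' `p_male = 1 / (1 + exp((1/S) * (ln P - ln T)))`, so the pivotal
#' temperature `P` produces a 1:1 sex ratio and the sign of `S` sets the
#' direction of the transition (female-at-warm for `S < 0`).
#'
#' @param P Pivotal temperature, degC.
#' @param S Shape parameter (signed, dimensionless); must be non-zero.
#' @return A `tsd_norm` object.
#' @export
tsd_norm <- function(P = 30.3, S = -0.01) {
  stopifnot(P > 0)
  if (S == 0) stop("S must be non-zero", call. = FALSE)
  structure(list(P = P, S = S), class = "tsd_norm")
}

#' @export
print.tsd_norm <- function(x, ...) {
  trt <- trt_limits(x)
  cat(sprintf(
    "<tsd_norm> Hill model, P = %.2f degC, S = %g; TRT (5%%-95%% female) %.1f-%.1f degC\n",
    x$P, x$S, trt[1], trt[2]))
  invisible(x)
}

#' Female probability at a constant incubation temperature
#'
#' @param temp_c Incubation temperature, degC (must be positive).
#' @param norm A `tsd_norm`.
#' @return Probability of developing as female, in `[0, 1]`.
#' @export
female_probability <- function(temp_c, norm = tsd_norm()) {
  if (any(temp_c <= 0))
    stop("temperature must be positive (absolute-scale guard)", call. = FALSE)
  p_male <- 1 / (1 + exp((1 / norm$S) * (log(norm$P) - log(temp_c))))
  1 - p_male
}

#' Transitional range of temperatures
#'
#' Solves `female_probability = level` and `1 - level` in closed form:
#' `T = P * exp(+/- S * ln((1 - level) / level))`.
#'
#' @param norm A `tsd_norm`.
#' @param level Sex-ratio level defining the range (conventionally 0.05).
#' @return Numeric `c(lower, upper)` temperatures, degC.
#' @export
trt_limits <- function(norm = tsd_norm(), level = 0.05) {
  stopifnot(level > 0, level < 0.5)
  spread <- abs(norm$S) * log((1 - level) / level)
  norm$P * exp(c(-1, 1) * spread)
}

#' Mean temperature over the thermosensitive period
#'
#' The TSP is the middle third of development (maturity between 33.3% and
#' 66.7%); its mean temperature drives the sex-ratio prediction. If the
#' embryo dies inside the TSP the mean over the partial window is returned
#' with attribute `partial = TRUE`.
#'
#' @param temp_c Hourly temperatures, degC.
#' @param maturity Hourly maturity trajectory, percent (same length).
#' @return Mean TSP temperature, degC.
#' @export
tsp_mean_temperature <- function(temp_c, maturity) {
  stopifnot(length(temp_c) == length(maturity))
  sel <- maturity >= 100 / 3 & maturity < 200 / 3
  if (!any(sel)) stop("embryo never enters the thermosensitive period",
                      call. = FALSE)
  out <- mean(temp_c[sel])
  if (max(maturity) < 200 / 3) attr(out, "partial") <- TRUE
  out
}

#' Hatching success from mean incubation temperature
#'
#' Logistic survival curve with its inflection at 32.7 degC, the temperature
#' above which hatchling mortality rises sharply in sea turtles:
#' `p = 1 / (1 + exp(beta * (T - t_crit)))`.
#'
#' @param mean_temp_c Mean incubation temperature, degC.
#' @param beta Slope (> 0); configuration value.
#' @param t_crit Inflection temperature, degC.
#' @return Hatching probability in `(0, 1)`.
#' @export
hatch_probability <- function(mean_temp_c, beta = 0.8, t_crit = 32.7) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  1 / (1 + exp(beta * (mean_temp_c - t_crit)))
}

#' Per-embryo developmental predictions from a simulation
#'
#' For each egg, integrates development over its own centre-temperature
#' series, then reports incubation duration (first hour at 100% maturity,
#' in days), female probability from the mean TSP temperature (or the mean
#' of hourly female probabilities over the TSP with
#' `sex_aggregation = "hourly"`), and hatching success from the mean
#' incubation temperature. A single sand-proxy prediction from a boundary
#' series, plus the conventional +0.5 / +1.0 / +1.5 degC corrected variants,
#' is computed for comparison when `sand_temp_c` is supplied.
#'
#' @param result A `simulation_result`.
#' @param rate A `dev_rate` function.
#' @param norm A `tsd_norm`.
#' @param beta,t_crit Passed to [hatch_probability()].
#' @param sand_temp_c Optional hourly sand-proxy series (adjacent sand).
#' @param sex_aggregation `"tsp_mean"` or `"hourly"`.
#' @return An `outcome_prediction` list: per-egg data frame `eggs`, clutch
#'   `summary`, and `sand_proxy` comparison table when applicable.
#' @export
predict_outcomes <- function(result, rate = dev_rate_curve(),
                             norm = tsd_norm(), beta = 0.8, t_crit = 32.7,
                             sand_temp_c = NULL,
                             sex_aggregation = c("tsp_mean", "hourly")) {
  sex_aggregation <- match.arg(sex_aggregation)
  n_eggs <- ncol(result$egg_temp)
  one <- function(temp_c) {
    dev <- integrate_development(temp_c, rate)
    hatched <- !is.na(dev$hatch_hour)
    end <- if (hatched) dev$hatch_hour else length(temp_c)
    mean_t <- mean(temp_c[seq_len(end)])
    in_tsp <- dev$maturity >= 100 / 3 & dev$maturity < 200 / 3
    tsp_t <- if (any(in_tsp)) mean(temp_c[in_tsp]) else NA_real_
    p_f <- if (!any(in_tsp)) NA_real_
      else if (sex_aggregation == "tsp_mean") female_probability(tsp_t, norm)
      else mean(female_probability(temp_c[in_tsp], norm))
    data.frame(
      duration_days = if (hatched) dev$hatch_hour / 24 else NA_real_,
      hatched = hatched,
      tsp_mean_c = tsp_t,
      mean_c = mean_t,
      p_female = p_f,
      p_hatch = hatch_probability(mean_t, beta, t_crit))
  }
  eggs <- do.call(rbind, lapply(seq_len(n_eggs), function(e) {
    cbind(egg_id = e, one(result$egg_temp[, e]))
  }))
  summary <- data.frame(
    n_eggs = n_eggs,
    mean_duration_days = mean(eggs$duration_days, na.rm = TRUE),
    min_duration_days = suppressWarnings(min(eggs$duration_days, na.rm = TRUE)),
    max_duration_days = suppressWarnings(max(eggs$duration_days, na.rm = TRUE)),
    mean_p_female = mean(eggs$p_female, na.rm = TRUE),
    mean_p_hatch = mean(eggs$p_hatch),
    mean_tsp_c = mean(eggs$tsp_mean_c, na.rm = TRUE),
    mean_incubation_c = mean(eggs$mean_c))
  out <- list(eggs = eggs, summary = summary)
  if (!is.null(sand_temp_c)) {
    variants <- c(sand = 0, `sand+0.5` = 0.5, `sand+1.0` = 1.0,
                  `sand+1.5` = 1.5)
    out$sand_proxy <- do.call(rbind, lapply(names(variants), function(v) {
      p <- one(sand_temp_c + variants[[v]])
      cbind(method = v, p)
    }))
  }
  class(out) <- "outcome_prediction"
  out
}

#' @export
print.outcome_prediction <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<outcome_prediction> %d eggs: duration %.1f days (%.1f-%.1f), %%female %.1f, hatch success %.1f%%\n",
    s$n_eggs, s$mean_duration_days, s$min_duration_days, s$max_duration_days,
    100 * s$mean_p_female, 100 * s$mean_p_hatch))
  invisible(x)
}
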