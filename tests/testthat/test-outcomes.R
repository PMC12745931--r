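test_that("the Hill reaction norm is pivotal at P and matches the TRT ends", {
  norm <- tsd_norm(30.3, -0.01)
  expect_equal(female_probability(30.3, norm), 0.5, tolerance = 1e-12)
  expect_lt(abs(female_probability(31.2, norm) - 0.95), 0.005)
  expect_lt(abs(female_probability(29.4, norm) - 0.05), 0.005)
  expect_error(tsd_norm(30.3, 0), "non-zero")
  expect_error(female_probability(-3, norm), "positive")
})

test_that("female probability is continuous, strictly increasing, with 0/1 limits", {
  norm <- tsd_norm(30.3, -0.01)
  T <- seq(27, 34, by = 0.01)
  p <- female_probability(T, norm)
  expect_true(all(diff(p) > 0))
  expect_lt(female_probability(25, norm), 1e-6)
  expect_gt(female_probability(36, norm), 1 - 1e-6)
})

test_that("TRT closed form agrees with numerical inversion of the norm", {
  norm <- tsd_norm(30.3, -0.01)
  trt <- trt_limits(norm, 0.05)
  for (i in 1:2) {
    level <- c(0.05, 0.95)[i]
    root <- uniroot(function(T) female_probability(T, norm) - level,
                    c(25, 36), tol = 1e-12)$root
    expect_equal(trt[i], root, tolerance = 1e-9)
  }
  # a step-function norm collapses the TRT onto the pivotal temperature
  sharp <- trt_limits(tsd_norm(30.3, -1e-6), 0.05)
  expect_equal(sharp, c(30.3, 30.3), tolerance = 1e-4)
})

test_that("TSP means slice the middle third of development", {
  flat2 <- function(T) rep(2 / 24, length(T))
  temps <- rep(31, 60 * 24)
  m <- integrate_development(temps, flat2)$maturity
  expect_equal(tsp_mean_temperature(temps, m), 31)

  # linear ramp at constant rate: the TSP mean is the ramp mean over the
  # middle-third hours, computed independently by slicing
  n <- 60 * 24
  ramp <- seq(29, 33, length.out = n)
  m <- integrate_development(ramp, flat2)$maturity
  sel <- m >= 100 / 3 & m < 200 / 3
  expect_equal(tsp_mean_temperature(ramp, m), mean(ramp[sel]))
  expect_gt(sum(sel), 0)

  # death inside the TSP: partial window is flagged
  m_dead <- pmin(m, 50)
  out <- tsp_mean_temperature(ramp, m_dead)
  expect_true(isTRUE(attr(out, "partial")))
  expect_error(tsp_mean_temperature(ramp, pmin(m, 20)), "never enters")
})

test_that("the hatching-success logistic pivots at its inflection", {
  expect_equal(hatch_probability(32.7), 0.5)
  expect_gt(hatch_probability(30), hatch_probability(35))
  # doubling the slope steepens the curve but fixes the inflection
  expect_equal(hatch_probability(32.7, beta = 1.6), 0.5)
  expect_lt(hatch_probability(34, beta = 1.6), hatch_probability(34, beta = 0.8))
  expect_gt(hatch_probability(31, beta = 1.6), hatch_probability(31, beta = 0.8))
  expect_error(hatch_probability(32, beta = -1), "positive")
})

test_that("duration responds to temperature on both sides of the rate peak", {
  rate <- dev_rate_curve()
  dur <- function(T) integrate_development(rep(T, 80 * 24), rate)$hatch_hour
  # below the peak warmer is faster; above the peak warmer is slower
  expect_true(dur(30) >= dur(31) && dur(31) >= dur(32) && dur(32) >= dur(33))
  expect_true(dur(34.5) <= dur(35.5) && dur(35.5) <= dur(36.5))
})

test_that("per-egg predictions collapse when all series are identical", {
  lay <- manual_layout(rbind(c(0, 0, 0.45), c(0.05, 0, 0.45), c(0, 0.05, 0.45)))
  temps <- matrix(rep(31 + 1.5 * sin(2 * pi * (0:(55 * 24)) / 24), 3), ncol = 3)
  res <- manual_result(lay, temps)
  pred <- predict_outcomes(res)
  expect_equal(sd(pred$eggs$duration_days), 0)
  expect_equal(sd(pred$eggs$p_female), 0)
  expect_equal(sd(pred$eggs$p_hatch), 0)
})

test_that("post-TSP warming changes duration but not predicted sex", {
  rate <- dev_rate_curve()
  n <- 60 * 24
  base <- rep(31, n)
  m <- integrate_development(base, rate)$maturity
  cut <- which(m >= 200 / 3)[1]
  warmed <- base
  warmed[(cut + 1):n] <- 32.5 # heat applied after the TSP closes
  lay <- manual_layout(rbind(c(0, 0, 0.45), c(0.05, 0, 0.45)))
  res <- manual_result(lay, cbind(base, warmed))
  pred <- predict_outcomes(res, rate = rate)
  expect_equal(pred$eggs$p_female[1], pred$eggs$p_female[2], tolerance = 1e-12)
  expect_false(pred$eggs$duration_days[1] == pred$eggs$duration_days[2])
})

test_that("sand-proxy corrections raise predicted femaleness for S < 0", {
  lay <- manual_layout(matrix(c(0, 0, 0.45), 1))
  n <- 55 * 24 + 1
  temps <- matrix(30.5 + 0.04 * (0:(n - 1)) / 24, ncol = 1)
  res <- manual_result(lay, temps)
  pred <- predict_outcomes(res, sand_temp_c = temps[, 1] - 0.8)
  pf <- pred$sand_proxy$p_female
  expect_equal(pred$sand_proxy$method,
               c("sand", "sand+0.5", "sand+1.0", "sand+1.5"))
  expect_true(all(diff(pf) > 0))
})
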