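make_pair <- function(obs, pred, t0 = "2020-12-10 00:00:00") {
  tt <- series_hours(t0, length(obs))
  list(o = temperature_series(tt, obs), p = temperature_series(tt, pred))
}

test_that("alignment joins logger stamps and counts a 55-day window", {
  n <- 55 * 24 + 1
  s <- make_pair(rep(30, n), rep(30, n))
  pairs <- align_series(s$o, s$p)
  expect_equal(nrow(pairs), 166)

  # stamps that never coincide with the logger grid leave an empty join
  tt <- series_hours("2020-12-10 00:00:00", 48)
  o <- temperature_series(tt, rep(30, 48))
  p <- temperature_series(tt + 1800, rep(30, 48))
  expect_error(suppressWarnings(align_series(o, p)), "no timestamps")

  # partial overlap drops unmatched stamps with a warning
  o2 <- temperature_series(series_hours("2020-12-10 00:00:00", 72), rep(30, 72))
  p2 <- temperature_series(series_hours("2020-12-11 00:00:00", 72), rep(30, 72))
  expect_warning(pairs2 <- align_series(o2, p2), "unmatched")
  expect_equal(nrow(pairs2), 6)
})

test_that("metrics match closed forms on engineered series", {
  n <- 200
  tt <- series_hours("2020-12-10 00:00:00", n)
  base <- 30 + 2 * sin(2 * pi * (0:(n - 1)) / 24)
  o <- temperature_series(tt, base)
  # identical series: perfect score
  m <- validation_metrics(align_series(o, o, cadence = NULL))
  expect_equal(unname(m), c(0, 1, 0, 0))
  # constant +0.5 offset: all three errors are 0.5 and correlation is intact
  p <- temperature_series(tt, base + 0.5)
  m <- validation_metrics(align_series(o, p, cadence = NULL))
  expect_equal(unname(m["rmse"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(m["me"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(m["mae"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(m["r2"]), 1, tolerance = 1e-12)
  # anti-correlated pair: R2 equals the brute-force squared correlation
  q <- temperature_series(tt, 60 - base + rnorm(n, sd = 1e-8))
  m <- validation_metrics(align_series(o, q, cadence = NULL))
  expect_equal(unname(m["r2"]),
               cor(base, 60 - base + (q$temp_c - (60 - base)))^2,
               tolerance = 1e-6)
})

test_that("metrics agree with the caret implementation on noisy data", {
  withr::with_seed(77, {
    n <- 300
    tt <- series_hours("2020-12-10 00:00:00", n)
    obs <- 31 + cumsum(rnorm(n, sd = 0.1))
    pred <- obs + rnorm(n, sd = 0.4) + 0.2
    o <- temperature_series(tt, obs); p <- temperature_series(tt, pred)
    m <- validation_metrics(align_series(o, p, cadence = NULL))
    ref <- caret::postResample(pred, obs)
    expect_equal(unname(m["rmse"]), unname(ref["RMSE"]), tolerance = 1e-10)
    expect_equal(unname(m["r2"]), unname(ref["Rsquared"]), tolerance = 1e-10)
    expect_equal(unname(m["mae"]), unname(ref["MAE"]), tolerance = 1e-10)
  })
})

test_that("metric inequalities and shift invariance hold on random pairs", {
  withr::with_seed(78, {
    for (i in 1:15) {
      n <- 100
      obs <- 30 + rnorm(n); pred <- obs + rnorm(n, sd = runif(1, 0.1, 2))
      tt <- series_hours("2020-12-10 00:00:00", n)
      m <- validation_metrics(align_series(temperature_series(tt, obs),
                                           temperature_series(tt, pred),
                                           cadence = NULL))
      expect_lte(unname(m["mae"]), unname(m["rmse"]) + 1e-12)
      expect_lte(abs(unname(m["me"])), unname(m["mae"]) + 1e-12)
      # shifting both series by a common lag leaves the metrics unchanged
      m2 <- validation_metrics(align_series(
        temperature_series(tt + 86400, obs),
        temperature_series(tt + 86400, pred), cadence = NULL))
      expect_equal(m, m2, tolerance = 1e-12)
    }
  })
  # zero-variance series: R2 undefined, reported missing
  tt <- series_hours("2020-12-10 00:00:00", 10)
  m <- validation_metrics(align_series(temperature_series(tt, rep(30, 10)),
                                       temperature_series(tt, rep(31, 10)),
                                       cadence = NULL))
  expect_true(is.na(m["r2"]))
  expect_equal(unname(m["rmse"]), 1)
})

test_that("the per-location validation table covers shared locations", {
  n <- 100
  tt <- series_hours("2020-12-10 00:00:00", n)
  mk <- function(x) temperature_series(tt, x)
  base <- 30 + sin(2 * pi * (0:(n - 1)) / 24)
  obs <- list(base = mk(base), centre = mk(base + 0.3), top = mk(base - 0.1))
  pred <- list(base = mk(base + 0.2), centre = mk(base + 0.3), top = mk(base))
  tab <- validation_table(obs, pred, cadence = NULL)
  expect_equal(tab$location, c("base", "centre", "top"))
  expect_equal(tab$me, c(0.2, 0, 0.1), tolerance = 1e-12)
})
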