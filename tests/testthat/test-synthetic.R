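test_that("boundary generation reduces to a ramp without diel or noise", {
  scen <- boundary_scenario(duration_days = 4, base_c = 30,
                            trend_c_per_day = 0.5, diel_amplitude_c = 0,
                            noise_sd = 0, seed = 1)
  out <- generate_boundaries(scen, c(0.1, 0.45))
  expect_equal(nrow(out[[1]]), 4 * 24)
  hrs <- 0:(4 * 24 - 1)
  expect_equal(out[[1]]$temp_c, 30 + 0.5 * hrs / 24, tolerance = 1e-12)
  # with no diel component, depth does not matter
  expect_equal(out[[1]]$temp_c, out[[2]]$temp_c, tolerance = 1e-12)
})

test_that("deeper series carry a smaller diel range and a 55-day count", {
  scen <- boundary_scenario(duration_days = 55, noise_sd = 0, seed = 2)
  out <- generate_boundaries(scen, c(0.1, 0.5))
  expect_equal(nrow(out[[1]]), 1320)
  rng <- function(s) diff(range(s$temp_c))
  expect_gt(rng(out$z0.10), rng(out$z0.50))
  # damping follows exp(-(z2-z1)/D) once the trend is removed
  detrend <- function(s) s$temp_c - (scen$base_c +
    scen$trend_c_per_day * (0:(nrow(s) - 1)) / 24)
  a1 <- (max(detrend(out$z0.10)) - min(detrend(out$z0.10))) / 2
  a2 <- (max(detrend(out$z0.50)) - min(detrend(out$z0.50))) / 2
  # hourly sampling of the shifted sinusoid perturbs the extremes slightly
  expect_equal(a2 / a1, exp(-0.4 / scen$damping_depth), tolerance = 0.01)
})

test_that("generators are bit-reproducible under a fixed seed", {
  scen <- boundary_scenario(duration_days = 10, seed = 9)
  a <- generate_boundaries(scen, 0.3)[[1]]
  b <- generate_boundaries(scen, 0.3)[[1]]
  expect_identical(a$temp_c, b$temp_c)
  c_ <- generate_boundaries(boundary_scenario(duration_days = 10, seed = 10),
                            0.3)[[1]]
  expect_false(identical(a$temp_c, c_$temp_c))
  # AR(1) noise realisations differ between depths
  two <- generate_boundaries(scen, c(0.3, 0.31))
  expect_false(identical(two[[1]]$temp_c - mean(two[[1]]$temp_c),
                         two[[2]]$temp_c - mean(two[[2]]$temp_c)))
})

test_that("the reference nest fixture is canonical and reproducible", {
  cfg <- make_reference_nest(42)
  expect_equal(cfg$geometry$depth_cm, 60)
  expect_equal(cfg$geometry$clutch_size, 51L)
  expect_equal(cfg$geometry$egg_diameter_mm, 46.7)
  expect_identical(make_reference_nest(42), make_reference_nest(42))
  expect_false(identical(make_reference_nest(42)$geometry$seed,
                         make_reference_nest(43)$geometry$seed))
  # the fixture passes the geometry invariants
  g <- build_nest_geometry(cfg$geometry$depth_cm / 100,
                           cfg$geometry$clutch_size,
                           cfg$geometry$egg_diameter_mm / 1000)
  lay <- pack_eggs(g, seed = cfg$geometry$seed)
  expect_equal(nrow(lay), 51)
  expect_true(all(lay$z_m >= g$chamber_top + g$egg_radius - 1e-9))
})

# memoised pseudo-observation sets on the small fixture (the forward solve
# is identical across noise settings; only the noise draw differs)
small_observed <- function(key, ...) {
  slot <- paste0("obs_", key)
  if (is.null(.nestherm_cache[[slot]]))
    .nestherm_cache[[slot]] <- simulate_observed(small_config(), ...)
  .nestherm_cache[[slot]]
}

test_that("noiseless pseudo-observations equal the forward model exactly", {
  obs <- small_observed("clean", logger_noise_sd = 0, seed = 3)
  sim <- obs$simulation
  centre <- extract_probe(sim$result,
                          unlist(sim$loggers$centre[c("x_m", "y_m", "z_m")]))
  expect_identical(obs$observed$centre$temp_c, centre$temp_c)
  # round-trip through the validation module: a model compared with its own
  # noiseless pseudo-observations scores a perfect fit
  m <- validation_metrics(align_series(obs$observed$centre, centre))
  expect_equal(unname(m["rmse"]), 0)
  expect_equal(unname(m["me"]), 0)
  # the observed list follows the field dialect (location column present)
  expect_equal(obs$observed$adjacent$location[1], "adjacent")
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperature_csv(obs$observed$base, path)
  back <- read_temperature_csv(path)
  expect_equal(back$temp_c, obs$observed$base$temp_c, tolerance = 1e-12)
  expect_equal(back$time, obs$observed$base$time)
})

test_that("logger noise is seeded and respects per-logger accuracies", {
  a <- small_observed("seed4", seed = 4)
  b <- small_observed("seed4b", seed = 4)
  expect_identical(a$observed$centre$temp_c, b$observed$centre$temp_c)
  c_ <- small_observed("seed5", seed = 5)
  expect_false(identical(a$observed$centre$temp_c, c_$observed$centre$temp_c))
  # the base logger (0.2 degC) is quieter than the centre logger (1.0 degC)
  clean <- small_observed("clean", logger_noise_sd = 0, seed = 3)
  res_base <- a$observed$base$temp_c - clean$observed$base$temp_c
  res_centre <- a$observed$centre$temp_c - clean$observed$centre$temp_c
  expect_lt(sd(res_base), sd(res_centre))
})
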