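# Shared fixtures and independent oracles for the test suite.

.nestherm_cache <- new.env(parent = emptyenv())

# Reference synthetic nest, noiseless boundaries, run once with and once
# without metabolic sources; shared by the heavier tests.
reference_runs <- function() {
  if (!is.null(.nestherm_cache$ref)) return(.nestherm_cache$ref)
  cfg <- make_reference_nest(42)
  cfg$scenario$noise_sd_c <- 0
  sim <- simulate_nest(cfg)
  cfg0 <- cfg
  cfg0$metabolism$enabled <- FALSE
  sim0 <- simulate_nest(cfg0)
  ctr <- which(sim$layout$egg_id == sim$loggers$centre$egg_id)
  .nestherm_cache$ref <- list(cfg = cfg, sim = sim, sim0 = sim0,
                              centre_idx = ctr)
  .nestherm_cache$ref
}

# Two independent pipeline runs of the same small configuration, memoised.
determinism_sims <- function() {
  if (is.null(.nestherm_cache$det)) {
    cfg <- small_config(seed = 11L)
    .nestherm_cache$det <- list(s1 = simulate_nest(cfg),
                                s2 = simulate_nest(cfg))
  }
  .nestherm_cache$det
}

# Small, fast configuration for end-to-end and determinism tests.
small_config <- function(seed = 5L) {
  cfg <- make_reference_nest(seed)
  cfg$geometry$clutch_size <- 8L
  cfg$geometry$depth_cm <- 50
  cfg$scenario$duration_days <- 2L
  cfg
}

# Independent Hashin-Shtrikman bounds for a two-phase mixture (conductivity
# form with spherical microstructure), written directly from the bound
# formulas rather than through the package's Mori-Tanaka code.
hs_bounds_two_phase <- function(k1, f1, k2, f2) {
  stopifnot(abs(f1 + f2 - 1) < 1e-12)
  lo_k <- min(k1, k2); hi_k <- max(k1, k2)
  lo_f <- if (k1 <= k2) f1 else f2
  hi_f <- 1 - lo_f
  lower <- lo_k + hi_f / (1 / (hi_k - lo_k) + lo_f / (3 * lo_k))
  upper <- hi_k + lo_f / (1 / (lo_k - hi_k) + hi_f / (3 * hi_k))
  c(lower = lower, upper = upper)
}

# Build a small uniform 3D grid of one material with all outer faces of the
# box Dirichlet ("wall" type), optionally with source cells.
uniform_box_grid <- function(n = 15, h = 0.02, material = NULL) {
  mats <- reference_materials()
  if (is.null(material)) material <- mats$beach
  bt <- rep(0L, n^3)
  idx <- seq_len(n^3)
  i <- ((idx - 1) %% n) + 1
  j <- (((idx - 1) %/% n) %% n) + 1
  k <- ((idx - 1) %/% n^2) + 1
  bt[i %in% c(1, n) | j %in% c(1, n) | k %in% c(1, n)] <- 2L
  grid_from_axes(rep(h, n), rep(h, n), rep(h, n), x0 = 0, y0 = 0, z0 = 0,
                 materials = list(beach = material, nest = material,
                                  egg = mats$egg),
                 bctype = bt)
}

# 1-D sand column with a Dirichlet top cell.
column_grid <- function(n = 150, dz = 0.01, material = NULL) {
  mats <- reference_materials()
  if (is.null(material)) material <- mats$beach
  bt <- rep(0L, n); bt[1] <- 1L
  grid_from_axes(0.02, 0.02, rep(dz, n), z0 = 0,
                 materials = list(beach = material, nest = material,
                                  egg = mats$egg),
                 bctype = bt)
}

# Hand-built clutch layout for selection-rule tests.
manual_layout <- function(xyz, egg_radius = 0.02335) {
  structure(data.frame(egg_id = seq_len(nrow(xyz)), x_m = xyz[, 1],
                       y_m = xyz[, 2], z_m = xyz[, 3]),
            egg_radius = egg_radius,
            class = c("clutch_layout", "data.frame"))
}

# Minimal simulation_result for probe-selection tests.
manual_result <- function(layout, egg_temp,
                          t0 = as.POSIXct("2020-12-10", tz = "UTC")) {
  structure(list(hours = 0:(nrow(egg_temp) - 1),
                 time = t0 + 3600 * (0:(nrow(egg_temp) - 1)),
                 egg_temp = egg_temp, layout = layout,
                 ledger = NULL, grid_dims = c(0, 0, 0)),
            class = "simulation_result")
}
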