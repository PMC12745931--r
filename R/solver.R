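# Implicit finite-volume solver for rho*C*dT/dt = div(k grad T) + r.

#' Boundary forcing for a nest simulation
#'
#' Binds the two measured (or synthetic) series to the model surfaces: the
#' series recorded 10 cm below the surface drives the upper Dirichlet plane,
#' and the series recorded in undisturbed sand at clutch-centre depth drives
#' the lateral cylinder wall, translated to each wall depth with the
#' damped-diel profile of [adjust_series_depth()].
#'
#' @param above Hourly `temperature_series` at the 10 cm plane.
#' @param adjacent Hourly `temperature_series` at `z_adjacent`.
#' @param z_adjacent Depth of the adjacent series, m.
#' @param diffusivity Beach-sand thermal diffusivity, m^2 s^-1; default from
#'   [reference_materials()].
#' @return A `boundary_forcing` object.
#' @export
boundary_forcing <- function(above, adjacent, z_adjacent,
                             diffusivity = NULL) {
  .assert_hourly(above); .assert_hourly(adjacent)
  if (is.null(diffusivity)) {
    b <- reference_materials()$beach
    diffusivity <- b$conductivity / (b$density * b$heat_capacity)
  }
  if (nrow(above) != nrow(adjacent) ||
      any(abs(as.numeric(above$time) - as.numeric(adjacent$time)) > 1))
    stop("above and adjacent series must share timestamps", call. = FALSE)
  structure(list(above = above, adjacent = adjacent,
                 z_adjacent = z_adjacent, diffusivity = diffusivity),
            class = "boundary_forcing")
}

# Assemble conduction operator over interior cells.
# Returns interior index map, sparse L (n_int x n_int), boundary coupling
# B (n_int x n_bdry), lumped capacities M (J/degC) and metadata.
build_system <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz; N <- grid$n_cells
  K <- grid$kc
  wx <- grid$wx; wy <- grid$wy; wz <- grid$wz

  faces_i <- integer(0); faces_j <- integer(0); faces_g <- numeric(0)
  add_faces <- function(a, b, g) {
    faces_i <<- c(faces_i, a); faces_j <<- c(faces_j, b)
    faces_g <<- c(faces_g, g)
  }
  idx_all <- seq_len(N)
  ii <- ((idx_all - 1L) %% nx) + 1L
  jj <- (((idx_all - 1L) %/% nx) %% ny) + 1L
  kk <- ((idx_all - 1L) %/% (nx * ny)) + 1L
  # x-direction faces
  if (nx > 1L) {
    a <- idx_all[ii < nx]; b <- a + 1L
    g <- (wy[jj[a]] * wz[kk[a]]) /
      (0.5 * wx[ii[a]] / K[a] + 0.5 * wx[ii[b]] / K[b])
    add_faces(a, b, g)
  }
  if (ny > 1L) {
    a <- idx_all[jj < ny]; b <- a + nx
    g <- (wx[ii[a]] * wz[kk[a]]) /
      (0.5 * wy[jj[a]] / K[a] + 0.5 * wy[jj[b]] / K[b])
    add_faces(a, b, g)
  }
  if (nz > 1L) {
    a <- idx_all[kk < nz]; b <- a + nx * ny
    g <- (wx[ii[a]] * wy[jj[a]]) /
      (0.5 * wz[kk[a]] / K[a] + 0.5 * wz[kk[b]] / K[b])
    add_faces(a, b, g)
  }

  interior <- which(grid$bctype == 0L)
  bdry <- which(grid$bctype > 0L)
  if (!length(bdry))
    stop("no Dirichlet cells: the all-Neumann problem is singular",
         call. = FALSE)
  g2i <- integer(N); g2i[interior] <- seq_along(interior)
  g2b <- integer(N); g2b[bdry] <- seq_along(bdry)

  int_i <- grid$bctype[faces_i] == 0L
  int_j <- grid$bctype[faces_j] == 0L
  both <- int_i & int_j
  ib <- int_i & !int_j   # interior - boundary
  bi <- !int_i & int_j   # boundary - interior

  diag_acc <- numeric(length(interior))
  tab <- function(idx, w) {
    v <- numeric(length(interior))
    s <- tapply(w, idx, sum)
    v[as.integer(names(s))] <- as.numeric(s)
    v
  }
  diag_acc <- diag_acc +
    tab(g2i[faces_i[int_i]], faces_g[int_i]) +
    tab(g2i[faces_j[int_j]], faces_g[int_j])

  L <- Matrix::sparseMatrix(
    i = c(g2i[faces_i[both]], g2i[faces_j[both]], seq_along(interior)),
    j = c(g2i[faces_j[both]], g2i[faces_i[both]], seq_along(interior)),
    x = c(-faces_g[both], -faces_g[both], diag_acc),
    dims = c(length(interior), length(interior)))
  B <- Matrix::sparseMatrix(
    i = c(g2i[faces_i[ib]], g2i[faces_j[bi]]),
    j = c(g2b[faces_j[ib]], g2b[faces_i[bi]]),
    x = c(faces_g[ib], faces_g[bi]),
    dims = c(length(interior), length(bdry)))
  M <- grid$volume[interior] * grid$rho[interior] * grid$cp[interior]
  list(interior = interior, bdry = bdry, L = L, B = B, M = M,
       rsB = Matrix::rowSums(B))
}

# Normalise boundary forcing to a (n_bdry x hours+1) value matrix.
.boundary_matrix <- function(grid, forcing, hours) {
  bdry <- which(grid$bctype > 0L)
  n_b <- length(bdry)
  if (is.matrix(forcing)) {
    stopifnot(nrow(forcing) == n_b, ncol(forcing) >= hours + 1)
    return(forcing[, seq_len(hours + 1), drop = FALSE])
  }
  if (is.numeric(forcing) && length(forcing) == 1L)
    return(matrix(forcing, n_b, hours + 1))
  if (is.function(forcing)) {
    vals <- vapply(0:hours, function(h) {
      v <- forcing(h)
      if (length(v) == 1L) rep(v, n_b) else v
    }, numeric(n_b))
    return(matrix(vals, nrow = n_b, ncol = hours + 1))
  }
  if (inherits(forcing, "boundary_forcing")) {
    if (nrow(forcing$above) < hours + 1)
      stop("boundary series shorter than the simulation window",
           call. = FALSE)
    vals <- matrix(NA_real_, n_b, hours + 1)
    is_top <- grid$bctype[bdry] == 1L
    vals[is_top, ] <- matrix(forcing$above$temp_c[seq_len(hours + 1)],
                             sum(is_top), hours + 1, byrow = TRUE)
    wall <- which(!is_top)
    if (length(wall)) {
      zw <- grid$zc[bdry[wall]]
      for (z in unique(zw)) {
        s <- adjust_series_depth(forcing$adjacent, forcing$z_adjacent, z,
                                 forcing$diffusivity)
        vals[wall[zw == z], ] <- matrix(s$temp_c[seq_len(hours + 1)],
                                        sum(zw == z), hours + 1, byrow = TRUE)
      }
    }
    return(vals)
  }
  stop("unsupported forcing specification", call. = FALSE)
}

#' Run a transient nest heat-conduction simulation
#'
#' Backward-Euler finite-volume integration with hourly outer steps (and
#' optional equal substeps), Dirichlet values imposed exactly on the forcing
#' surfaces, and each egg's metabolic wattage deposited in the cell holding
#' its centre. The per-step energy ledger records the residual of
#' storage = boundary influx + source input, which a direct solve keeps at
#' rounding level.
#'
#' @param grid A `simulation_grid`.
#' @param forcing A `boundary_forcing`, value matrix, function of hour, or
#'   scalar.
#' @param hours Number of hourly steps.
#' @param schedule Optional `flux_schedule` (watts per egg per hour).
#' @param coupling Optional metabolic coupling list from
#'   [metabolic_coupling()]; mutually exclusive with `schedule`.
#' @param substeps Substeps per hour (backward Euler each).
#' @param init `"steady"` (stationary solve at the initial boundary values,
#'   zero sources) or a numeric initial field (scalar or per-cell).
#' @param snapshot_hours Hours at which to store the full field.
#' @param t0 Timestamp of hour 0; taken from the forcing series when
#'   available.
#' @return A `simulation_result` with hourly per-egg centre temperatures,
#'   the energy ledger, any coupled development state and schedule, and
#'   optional field snapshots.
#' @export
run_simulation <- function(grid, forcing, hours, schedule = NULL,
                           coupling = NULL, substeps = 1L, init = "steady",
                           snapshot_hours = integer(0), t0 = NULL) {
  stopifnot(hours >= 1, substeps >= 1)
  if (!is.null(schedule) && !is.null(coupling))
    stop("supply either a flux schedule or a metabolic coupling, not both",
         call. = FALSE)
  sys <- build_system(grid)
  bvals <- .boundary_matrix(grid, forcing, hours)
  if (any(!is.finite(bvals))) stop("non-finite boundary values", call. = FALSE)
  if (!is.null(schedule)) {
    if (nrow(schedule$watts) < hours)
      stop("flux schedule shorter than the simulation window", call. = FALSE)
    if (ncol(schedule$watts) != length(grid$egg_cells))
      stop("flux schedule does not match the clutch", call. = FALSE)
  }
  if (is.null(t0)) {
    t0 <- if (inherits(forcing, "boundary_forcing")) forcing$above$time[1]
          else as.POSIXct("2020-12-10 00:00:00", tz = "UTC")
  }

  dt <- 3600 / substeps
  A <- L_plus_mass(sys, dt)
  ch <- Matrix::Cholesky(A, LDL = FALSE)

  # initial field
  if (identical(init, "steady")) {
    chs <- Matrix::Cholesky(sys$L, LDL = FALSE)
    Tint <- as.numeric(Matrix::solve(chs, sys$B %*% bvals[, 1]))
  } else {
    Tint <- rep_len(as.numeric(init), length(sys$interior))
  }
  Tfull <- numeric(grid$n_cells)
  Tfull[sys$interior] <- Tint
  Tfull[sys$bdry] <- bvals[, 1]

  n_eggs <- length(grid$egg_cells)
  egg_temp <- matrix(NA_real_, hours + 1, n_eggs)
  if (n_eggs) egg_temp[1, ] <- Tfull[grid$egg_cells]
  egg_int <- if (n_eggs) match(grid$egg_cells, sys$interior) else integer(0)
  if (n_eggs && any(is.na(egg_int)))
    stop("an egg centre fell in a Dirichlet cell", call. = FALSE)

  state <- if (!is.null(coupling)) coupling_init(coupling, n_eggs) else NULL
  watts_log <- if (!is.null(coupling)) matrix(0, hours, n_eggs) else NULL
  ledger <- data.frame(hour = seq_len(hours), storage_j = NA_real_,
                       boundary_j = NA_real_, source_j = NA_real_,
                       residual_j = NA_real_, turnover_j = NA_real_)
  snapshots <- list()

  for (h in seq_len(hours)) {
    if (!is.null(coupling)) {
      st <- coupling_fluxes(coupling, state, egg_temp[h, ])
      state <- st$state
      watts <- st$watts
      watts_log[h, ] <- watts
    } else if (!is.null(schedule)) {
      watts <- schedule$watts[h, ]
    } else {
      watts <- numeric(n_eggs)
    }
    q <- numeric(length(sys$interior))
    if (n_eggs && any(watts != 0)) {
      for (e in which(watts != 0))
        q[egg_int[e]] <- q[egg_int[e]] + watts[e]
    }
    e_bdry <- 0; e_src <- 0
    T_prev_hour <- Tint
    for (m in seq_len(substeps)) {
      th <- m / substeps
      Tb <- (1 - th) * bvals[, h] + th * bvals[, h + 1]
      rhs <- sys$M / dt * Tint + as.numeric(sys$B %*% Tb) + q
      Tint <- as.numeric(Matrix::solve(ch, rhs))
      e_bdry <- e_bdry + dt * (sum(sys$B %*% Tb) - sum(sys$rsB * Tint))
      e_src <- e_src + dt * sum(q)
    }
    e_sto <- sum(sys$M * (Tint - T_prev_hour))
    ledger$storage_j[h] <- e_sto
    ledger$boundary_j[h] <- e_bdry
    ledger$source_j[h] <- e_src
    ledger$residual_j[h] <- abs(e_sto - e_bdry - e_src)
    ledger$turnover_j[h] <- abs(e_sto) + abs(e_bdry) + abs(e_src)
    if (n_eggs) egg_temp[h + 1, ] <- Tint[egg_int]
    if (h %in% snapshot_hours) {
      Tfull[sys$interior] <- Tint
      Tfull[sys$bdry] <- bvals[, h + 1]
      snapshots[[as.character(h)]] <- Tfull
    }
  }
  Tfull[sys$interior] <- Tint
  Tfull[sys$bdry] <- bvals[, hours + 1]

  out <- list(
    hours = 0:hours, time = t0 + 3600 * (0:hours),
    egg_temp = egg_temp, final_field = Tfull, ledger = ledger,
    snapshots = snapshots, layout = grid$layout,
    egg_cells = grid$egg_cells,
    maturity = if (!is.null(state)) state$maturity_trace else NULL,
    hatch_hour = if (!is.null(state)) state$hatch_hour else NULL,
    schedule = if (!is.null(coupling)) {
      flux_schedule(watts_log, coupling$categories,
                    hatch_hour = state$hatch_hour)
    } else schedule,
    grid_dims = c(grid$nx, grid$ny, grid$nz)
  )
  class(out) <- "simulation_result"
  out
}

L_plus_mass <- function(sys, dt) {
  sys$L + Matrix::Diagonal(x = sys$M / dt)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d hours, %d eggs, grid %s; max |energy residual| = %.2e of turnover\n",
    max(x$hours), ncol(x$egg_temp), paste(x$grid_dims, collapse = "x"),
    max(x$ledger$residual_j / pmax(x$ledger$turnover_j, 1e-300))))
  invisible(x)
}

#' Solve the stationary problem for a grid and fixed boundary values
#'
#' @param grid A `simulation_grid`.
#' @param forcing Scalar, per-boundary-cell vector, or value matrix.
#' @param watts Optional per-egg steady wattages.
#' @return Full-field temperature vector over all cells.
#' @export
steady_state <- function(grid, forcing, watts = NULL) {
  sys <- build_system(grid)
  Tb <- .boundary_matrix(grid, forcing, 0)[, 1]
  q <- numeric(length(sys$interior))
  if (!is.null(watts) && length(grid$egg_cells)) {
    egg_int <- match(grid$egg_cells, sys$interior)
    for (e in seq_along(watts))
      q[egg_int[e]] <- q[egg_int[e]] + watts[e]
  }
  chs <- Matrix::Cholesky(sys$L, LDL = FALSE)
  Tint <- as.numeric(Matrix::solve(chs, as.numeric(sys$B %*% Tb) + q))
  Tfull <- numeric(grid$n_cells)
  Tfull[sys$interior] <- Tint
  Tfull[sys$bdry] <- Tb
  Tfull
}

#' Extract the centre-temperature series of the egg nearest a point
#'
#' Mirrors how modelled temperatures are compared with in-clutch loggers:
#' the centre node of the egg closest to the query point is selected
#' (Euclidean distance, ties to the lowest egg id), optionally thinned to
#' the eight-hourly logger cadence.
#'
#' @param result A `simulation_result`.
#' @param location Numeric `c(x, y, z)` in metres.
#' @param cadence `NULL` for hourly or `8` for the 00:00/08:00/16:00 stamps.
#' @return A `temperature_series`.
#' @export
extract_probe <- function(result, location, cadence = NULL) {
  lay <- result$layout
  if (is.null(lay) || nrow(lay) == 0L) stop("empty clutch", call. = FALSE)
  d2 <- (lay$x_m - location[1])^2 + (lay$y_m - location[2])^2 +
    (lay$z_m - location[3])^2
  cand <- which(d2 <= min(d2) + 1e-12)
  egg <- cand[which.min(lay$egg_id[cand])]
  s <- temperature_series(result$time, result$egg_temp[, egg])
  if (!is.null(cadence) && cadence == 8) s <- resample_8hourly(s)
  s
}

#' Per-trimester means of an hourly signal
#'
#' Splits the incubation window `[0, hatch_hour]` into three equal trimesters
#' and returns the mean of the signal in each.
#'
#' @param x Numeric vector indexed by hour (first element = hour 0).
#' @param hatch_hour End of incubation, hours; defaults to the full window.
#' @return Numeric vector of three trimester means.
#' @export
trimester_means <- function(x, hatch_hour = length(x) - 1L) {
  h <- seq_along(x) - 1L
  edges <- hatch_hour * c(0, 1, 2, 3) / 3
  vapply(1:3, function(t) {
    mean(x[h >= edges[t] & h < edges[t + 1]])
  }, numeric(1))
}
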