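#' Default egg-chamber profile
#'
#' Axisymmetric flask describing the egg chamber: a cylindrical throat above
#' an ellipsoidal bulb. Dimensions follow published averages for flatback
#' turtle egg chambers; the total chamber height (0.31 m) equals the constant
#' offset between nest depth and neck length observed across nests.
#'
#' @param height Total chamber height, m.
#' @param bulb_height Height of the ellipsoidal bulb, m.
#' @param bulb_radius Equatorial radius of the bulb, m.
#' @param throat_radius Radius of the cylindrical throat (and of the refilled
#'   neck shaft above the chamber), m.
#' @return A `chamber_spec` list with a vectorised `radius(z_rel)` function,
#'   `z_rel` measured downward from the chamber top.
#' @export
chamber_spec <- function(height = 0.31, bulb_height = 0.22,
                         bulb_radius = 0.12, throat_radius = 0.09) {
  stopifnot(height > 0, bulb_height > 0, bulb_height <= height,
            bulb_radius > 0, throat_radius > 0, throat_radius <= bulb_radius)
  zc <- height - bulb_height / 2 # bulb centre below chamber top
  c_half <- bulb_height / 2
  radius <- function(z_rel) {
    ell <- bulb_radius * sqrt(pmax(0, 1 - ((z_rel - zc) / c_half)^2))
    throat <- ifelse(z_rel >= 0 & z_rel <= zc, throat_radius, 0)
    out <- pmax(ell, throat)
    out[z_rel < 0 | z_rel > height] <- 0
    out
  }
  structure(list(height = height, bulb_height = bulb_height,
                 bulb_radius = bulb_radius, throat_radius = throat_radius,
                 radius = radius),
            class = "chamber_spec")
}

#' Chamber volume by numerical integration of the profile
#' @param chamber A `chamber_spec`.
#' @param dz Integration step, m.
#' @return Volume, m^3.
#' @export
chamber_volume <- function(chamber, dz = 5e-4) {
  z <- seq(dz / 2, chamber$height - dz / 2, by = dz)
  sum(pi * chamber$radius(z)^2) * dz
}

#' Build the three-subdomain nest geometry
#'
#' The beach is a fixed cylinder of 2 m diameter and 1.5 m depth. The egg
#' chamber (flask profile from [chamber_spec()]) sits with its base at the
#' nest depth; the neck length is whatever vertical distance remains between
#' the sand surface and the chamber top, so neck length is an affine function
#' of depth with unit slope.
#'
#' @param nest_depth Depth of the chamber base below the sand surface, m.
#' @param clutch_size Number of eggs.
#' @param egg_diameter Egg diameter, m.
#' @param chamber A `chamber_spec`.
#' @return A `nest_geometry` object. Coordinates: origin at the sand surface
#'   on the chamber axis, z positive downward, SI metres.
#' @export
build_nest_geometry <- function(nest_depth, clutch_size,
                                egg_diameter = 0.0467,
                                chamber = chamber_spec()) {
  stopifnot(clutch_size >= 1, egg_diameter > 0)
  if (nest_depth < chamber$height)
    stop(sprintf("nest depth %.2f m is too shallow for the %.2f m chamber",
                 nest_depth, chamber$height), call. = FALSE)
  if (nest_depth < 0.3 || nest_depth > 1.0)
    warning("nest depth outside the plausible 0.3-1.0 m band")
  egg_radius <- egg_diameter / 2
  clutch_volume <- clutch_size * (4 / 3) * pi * egg_radius^3
  structure(list(
    beach_diameter = 2, beach_depth = 1.5,
    nest_depth = nest_depth,
    neck_length = nest_depth - chamber$height,
    chamber = chamber,
    chamber_top = nest_depth - chamber$height,
    egg_radius = egg_radius,
    clutch_size = clutch_size,
    clutch_volume = clutch_volume
  ), class = "nest_geometry")
}

#' @export
print.nest_geometry <- function(x, ...) {
  cat(sprintf(
    "<nest_geometry> depth %.2f m (neck %.2f m), clutch %d eggs of %.1f mm,\n  chamber %.2f m flask (bulb r=%.2f m), beach cylinder 2 m x 1.5 m\n",
    x$nest_depth, x$neck_length, x$clutch_size, 2000 * x$egg_radius,
    x$chamber$height, x$chamber$bulb_radius))
  invisible(x)
}

# TRUE if a sphere of radius r centred at (rho, z) fits inside the chamber
# profile; checked on a discretised set of latitudes of the sphere.
.sphere_inside_chamber <- function(rho, z, r, geometry, n_check = 17) {
  ch <- geometry$chamber
  top <- geometry$chamber_top
  base <- geometry$nest_depth
  if (z - r < top - 1e-12 || z + r > base + 1e-12) return(FALSE)
  dz <- seq(-r, r, length.out = n_check)
  horiz <- sqrt(pmax(0, r^2 - dz^2))
  all(rho + horiz <= ch$radius(z + dz - top) + 1e-12)
}

# Deepest feasible z for a sphere at horizontal offset rho (floor rest),
# found by bisection on the inside test.
.floor_rest_z <- function(rho, r, geometry) {
  lo <- geometry$chamber_top + r
  hi <- geometry$nest_depth - r
  if (!.sphere_inside_chamber(rho, lo, r, geometry)) return(NA_real_)
  if (.sphere_inside_chamber(rho, hi, r, geometry)) return(hi)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (.sphere_inside_chamber(rho, mid, r, geometry)) lo <- mid else hi <- mid
  }
  lo
}

# Tabulate, once per packing run, the feasible band of centre depths
# [z_lo(rho), z_hi(rho)] for a sphere of radius r at horizontal offset rho.
# The flask profile is unimodal in depth, so the band is an interval.
.feasible_band <- function(geometry, r, n_rho = 160) {
  rho_max <- geometry$chamber$bulb_radius - r
  rho <- seq(0, rho_max, length.out = n_rho)
  z_top <- geometry$chamber_top + r
  z_bot <- geometry$nest_depth - r
  z_hi <- vapply(rho, .floor_rest_z, numeric(1), r = r, geometry = geometry)
  z_lo <- vapply(rho, function(p) {
    if (.sphere_inside_chamber(p, z_top, r, geometry)) return(z_top)
    lo <- z_top; hi <- z_bot
    if (!.sphere_inside_chamber(p, hi, r, geometry)) return(NA_real_)
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (.sphere_inside_chamber(p, mid, r, geometry)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  list(rho = rho, rho_max = rho_max, z_lo = z_lo, z_hi = z_hi,
       lookup = function(p) {
         if (p > rho_max) return(c(NA_real_, NA_real_))
         c(stats::approx(rho, z_lo, p, rule = 2)$y,
           stats::approx(rho, z_hi, p, rule = 2)$y)
       })
}

# Resting depth of a sphere dropped at (x, y): deepest of the wall/floor rest
# and the first contact with any placed egg while descending. NA if the
# resting position is not fully inside the chamber.
.rest_z <- function(x, y, placed, r, band) {
  rho <- sqrt(x^2 + y^2)
  bz <- band$lookup(rho)
  if (any(is.na(bz))) return(NA_real_)
  zc <- bz[2]
  if (!is.null(placed) && nrow(placed)) {
    dh2 <- (placed[, 1] - x)^2 + (placed[, 2] - y)^2
    near <- which(dh2 < (2 * r)^2 - 1e-12)
    if (length(near))
      zc <- min(zc, placed[near, 3] - sqrt((2 * r)^2 - dh2[near]))
  }
  if (zc < bz[1] - 1e-9) return(NA_real_)
  zc
}

# Let a resting sphere roll downhill: greedy horizontal moves (8 compass
# directions, shrinking step) accepted whenever the resting depth increases.
.settle <- function(x, y, z, placed, r, band, step0) {
  ang <- (0:7) * pi / 4
  step <- step0
  for (round in 1:40) {
    improved <- FALSE
    for (a in ang) {
      xn <- x + step * cos(a); yn <- y + step * sin(a)
      zn <- .rest_z(xn, yn, placed, r, band)
      if (!is.na(zn) && zn > z + 1e-7) {
        x <- xn; y <- yn; z <- zn; improved <- TRUE
      }
    }
    if (!improved) {
      step <- step / 2
      if (step < 2e-4) break
    }
  }
  c(x, y, z)
}

#' Pack the clutch into the chamber under gravity
#'
#' Random sequential deposition: each egg is dropped at a number of random
#' horizontal positions, comes to rest at the deepest feasible point (on the
#' chamber floor or on previously placed eggs), and the deepest of the
#' candidate rests is kept. This reproduces the outcome of a gravity-settled
#' random arrangement, which is all the heat-transfer model depends on. The
#' layout is deterministic for a given seed.
#'
#' @param geometry A `nest_geometry`.
#' @param clutch_size Number of eggs; defaults to the geometry's clutch size.
#' @param seed Integer seed for the deposition RNG.
#' @param n_trials Candidate drop positions per egg.
#' @param overlap_tol Maximum allowed pairwise penetration, m.
#' @return A `clutch_layout`: data frame (`egg_id`, `x_m`, `y_m`, `z_m`) plus
#'   egg radius, as attributes of class `clutch_layout`.
#' @export
pack_eggs <- function(geometry, clutch_size = geometry$clutch_size,
                      seed = 1L, n_trials = 80L, overlap_tol = 1e-4) {
  r <- geometry$egg_radius
  if (geometry$clutch_volume >= chamber_volume(geometry$chamber))
    stop("clutch volume exceeds chamber volume: packing infeasible",
         call. = FALSE)
  ch <- geometry$chamber
  band <- .feasible_band(geometry, r)
  centres <- matrix(NA_real_, nrow = clutch_size, ncol = 3)
  withr::with_seed(as.integer(seed), {
    for (e in seq_len(clutch_size)) {
      placed <- if (e > 1L) centres[seq_len(e - 1L), , drop = FALSE] else NULL
      # first egg: drop on the axis so a singleton rests at the lowest point
      if (e == 1L) {
        centres[1L, ] <- c(0, 0, .rest_z(0, 0, NULL, r, band))
        next
      }
      cand <- matrix(NA_real_, n_trials, 3)
      for (t in seq_len(n_trials)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * band$rho_max
        x <- rad * cos(ang); y <- rad * sin(ang)
        zc <- .rest_z(x, y, placed, r, band)
        if (!is.na(zc)) cand[t, ] <- c(x, y, zc)
      }
      cand <- cand[!is.na(cand[, 3]), , drop = FALSE]
      if (!nrow(cand))
        stop(sprintf("packing infeasible: no resting place for egg %d", e),
             call. = FALSE)
      # settle the deepest few drops and keep the overall deepest rest
      cand <- cand[order(-cand[, 3]), , drop = FALSE]
      best <- NULL
      for (s in seq_len(min(3L, nrow(cand)))) {
        st <- .settle(cand[s, 1], cand[s, 2], cand[s, 3], placed, r, band,
                      step0 = r / 2)
        if (is.null(best) || st[3] > best[3]) best <- st
      }
      centres[e, ] <- best
    }
  })
  layout <- data.frame(egg_id = seq_len(clutch_size),
                       x_m = centres[, 1], y_m = centres[, 2],
                       z_m = centres[, 3])
  # hard guarantee: contacts are exact, penetration can only be numerical
  if (clutch_size > 1L) {
    dmin <- min(stats::dist(centres))
    if (dmin < 2 * r - overlap_tol)
      stop("packing produced overlapping eggs beyond tolerance", call. = FALSE)
  }
  structure(layout, egg_radius = r, class = c("clutch_layout", "data.frame"))
}

#' Logger positions within a packed clutch
#'
#' Mirrors the placement of the three in-clutch temperature loggers: `base`
#' is the deepest egg centre, `top` the shallowest, and `centre` the egg
#' nearest the clutch centroid. Ties are broken by lowest egg id.
#'
#' @param layout A `clutch_layout`.
#' @return List of three rows of the layout: `base`, `centre`, `top`.
#' @export
logger_positions <- function(layout) {
  if (nrow(layout) == 0L) stop("empty clutch layout", call. = FALSE)
  z <- layout$z_m
  pick <- function(score) {
    best <- min(score)
    cand <- which(score <= best + 1e-12)
    layout[cand[which.min(layout$egg_id[cand])], , drop = FALSE]
  }
  centroid <- c(mean(layout$x_m), mean(layout$y_m), mean(layout$z_m))
  d2 <- (layout$x_m - centroid[1])^2 + (layout$y_m - centroid[2])^2 +
    (layout$z_m - centroid[3])^2
  list(base = pick(-z), centre = pick(d2), top = pick(z))
}

#' Write / read a clutch layout as CSV
#' @param layout A `clutch_layout`.
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  df <- as.data.frame(layout)
  df$egg_radius_m <- attr(layout, "egg_radius")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path)
  r <- df$egg_radius_m[1]
  df$egg_radius_m <- NULL
  structure(df, egg_radius = r, class = c("clutch_layout", "data.frame"))
}
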