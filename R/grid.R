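# Rectilinear simulation grids: graded axes, material tagging, cell lookup.

# Build one graded axis: fine spacing h inside [fine_lo, fine_hi], cell widths
# growing geometrically (capped at max_w) out to the domain limits. An
# optional thin leading width at dom_lo resolves a Dirichlet boundary layer.
graded_axis <- function(dom_lo, dom_hi, fine_lo, fine_hi, h,
                        growth = 1.6, max_w = 0.12, lead_w = NULL) {
  stopifnot(dom_lo < dom_hi, fine_lo >= dom_lo, fine_hi <= dom_hi,
            fine_lo < fine_hi, h > 0)
  n_fine <- max(1L, round((fine_hi - fine_lo) / h))
  w_fine <- rep((fine_hi - fine_lo) / n_fine, n_fine)
  fill_gap <- function(gap, w0) {
    ws <- numeric(0); w <- w0; pos <- 0
    while (gap - pos > 1e-9) {
      w <- min(w * growth, max_w, gap - pos)
      # absorb a sliver remainder into the last cell
      if (gap - pos - w > 1e-9 && gap - pos - w < 0.3 * w) w <- gap - pos
      ws <- c(ws, w); pos <- pos + w
    }
    ws
  }
  gap_lo <- fine_lo - dom_lo
  w_lead <- numeric(0)
  if (!is.null(lead_w) && gap_lo > lead_w + 1e-9) {
    w_lead <- lead_w
    gap_lo <- gap_lo - lead_w
  }
  w_left <- rev(fill_gap(gap_lo, h))
  w_right <- fill_gap(dom_hi - fine_hi, h)
  widths <- c(w_lead, w_left, w_fine, w_right)
  edges <- dom_lo + cumsum(c(0, widths))
  list(widths = widths, centres = (edges[-1] + edges[-length(edges)]) / 2,
       edges = edges)
}

# linear index of cell (i, j, k)
.cell_index <- function(i, j, k, nx, ny) i + nx * (j - 1L) + nx * ny * (k - 1L)

#' Rasterize a nest model onto a rectilinear finite-volume grid
#'
#' Cells are tagged by first-match precedence egg > nest sand > beach: a cell
#' is egg-tagged when its centre lies inside an egg sphere, nest-sand-tagged
#' when its centre lies inside the chamber flask or the refilled neck shaft,
#' and beach-tagged otherwise. Per-cell density, heat capacity and
#' conductivity follow the tag; interface conductivities use harmonic means
#' at assembly time.
#'
#' The grid spans the beach cylinder laterally and the depth range from the
#' upper forcing plane (10 cm) to the 1.5 m base. Cells whose centre (plus
#' half-diagonal) reaches the 1 m cylinder radius form the lateral Dirichlet
#' wall; the top layer within `footprint_radius` of the axis is the upper
#' Dirichlet plane, and every other external face is zero-flux.
#'
#' @param geometry A `nest_geometry`.
#' @param layout A `clutch_layout`.
#' @param materials Named list with `beach`, `nest`, `egg`
#'   `effective_properties`, e.g. [reference_materials()].
#' @param cell_size Fine cell size near the clutch, m.
#' @param z_top Depth of the upper forcing plane, m.
#' @param footprint_radius Radius of the upper Dirichlet plane, m.
#' @param fine_margin Padding of the fine region around the clutch, m.
#' @param growth,max_spacing Grading of coarse cells away from the clutch.
#' @return A `simulation_grid` object.
#' @export
make_nest_grid <- function(geometry, layout, materials = reference_materials(),
                           cell_size = 0.02, z_top = 0.10,
                           footprint_radius = 0.30, fine_margin = 0.05,
                           growth = 1.6, max_spacing = 0.12) {
  r_egg <- geometry$egg_radius
  half <- geometry$beach_diameter / 2
  rx <- geometry$chamber$bulb_radius + fine_margin
  ax <- graded_axis(-half, half, -rx, rx, cell_size,
                    growth = growth, max_w = max_spacing)
  az <- graded_axis(z_top, geometry$beach_depth,
                    max(z_top + 0.02, geometry$chamber_top - fine_margin),
                    min(geometry$beach_depth, geometry$nest_depth + fine_margin),
                    cell_size, growth = growth, max_w = max_spacing,
                    lead_w = 0.01)
  grid_from_axes(ax, ax, az, geometry = geometry, layout = layout,
                 materials = materials, footprint_radius = footprint_radius)
}

#' Low-level grid constructor from explicit axes
#'
#' Exposed for analytic test problems (columns, uniform blocks). When
#' `geometry`/`layout` are NULL the whole grid is beach sand and boundary
#' types must be supplied via `bctype`.
#'
#' @param ax,ay,az Axis lists from `graded_axis()`, or numeric width vectors
#'   (then `x0`/`y0`/`z0` give the lower edges).
#' @param geometry,layout,materials As in [make_nest_grid()].
#' @param footprint_radius Upper Dirichlet plane radius, m.
#' @param bctype Optional explicit boundary-type vector (0 interior, 1 top
#'   Dirichlet, 2 wall Dirichlet).
#' @param x0,y0,z0 Lower domain edges when axes are width vectors.
#' @return A `simulation_grid`.
#' @export
grid_from_axes <- function(ax, ay, az, geometry = NULL, layout = NULL,
                           materials = reference_materials(),
                           footprint_radius = Inf, bctype = NULL,
                           x0 = 0, y0 = 0, z0 = 0) {
  as_axis <- function(a, lo) {
    if (is.list(a)) return(a)
    edges <- lo + cumsum(c(0, a))
    list(widths = a, centres = (edges[-1] + edges[-length(edges)]) / 2,
         edges = edges)
  }
  ax <- as_axis(ax, x0); ay <- as_axis(ay, y0); az <- as_axis(az, z0)
  nx <- length(ax$widths); ny <- length(ay$widths); nz <- length(az$widths)
  N <- nx * ny * nz
  xc <- rep(ax$centres, times = ny * nz)
  yc <- rep(rep(ay$centres, each = nx), times = nz)
  zc <- rep(az$centres, each = nx * ny)
  wxc <- rep(ax$widths, times = ny * nz)
  wyc <- rep(rep(ay$widths, each = nx), times = nz)
  wzc <- rep(az$widths, each = nx * ny)

  mat <- rep(1L, N) # 1 beach, 2 nest sand, 3 egg
  egg_id <- rep(0L, N)
  egg_cells <- integer(0)
  if (!is.null(geometry)) {
    rho_c <- sqrt(xc^2 + yc^2)
    in_chamber <- zc >= geometry$chamber_top & zc <= geometry$nest_depth &
      rho_c <= geometry$chamber$radius(zc - geometry$chamber_top)
    in_neck <- zc < geometry$chamber_top &
      rho_c <= geometry$chamber$throat_radius
    mat[in_chamber | in_neck] <- 2L
    if (!is.null(layout) && nrow(layout)) {
      r_egg <- attr(layout, "egg_radius")
      for (e in seq_len(nrow(layout))) {
        d2 <- (xc - layout$x_m[e])^2 + (yc - layout$y_m[e])^2 +
          (zc - layout$z_m[e])^2
        inside <- d2 <= r_egg^2
        mat[inside] <- 3L
        egg_id[inside] <- layout$egg_id[e]
      }
      if (!all(layout$egg_id %in% egg_id))
        stop("grid too coarse: at least one egg captures zero cells",
             call. = FALSE)
      find_cell <- function(x, y, z) {
        i <- findInterval(x, ax$edges, rightmost.closed = TRUE)
        j <- findInterval(y, ay$edges, rightmost.closed = TRUE)
        k <- findInterval(z, az$edges, rightmost.closed = TRUE)
        .cell_index(i, j, k, nx, ny)
      }
      egg_cells <- find_cell(layout$x_m, layout$y_m, layout$z_m)
    }
  }
  props <- list(materials$beach, materials$nest, materials$egg)
  rho <- vapply(props, `[[`, numeric(1), "density")[mat]
  cp <- vapply(props, `[[`, numeric(1), "heat_capacity")[mat]
  kc <- vapply(props, `[[`, numeric(1), "conductivity")[mat]

  if (is.null(bctype)) {
    bctype <- rep(0L, N)
    half_diag <- sqrt(wxc^2 + wyc^2) / 2
    wall <- sqrt(xc^2 + yc^2) + half_diag >= min(max(ax$edges), -min(ax$edges))
    bctype[wall] <- 2L
    top <- zc <= az$edges[1] + az$widths[1] + 1e-12 &
      sqrt(xc^2 + yc^2) <= footprint_radius
    bctype[top & bctype == 0L] <- 1L
  }
  structure(list(
    nx = nx, ny = ny, nz = nz, n_cells = N,
    x = ax$centres, y = ay$centres, z = az$centres,
    wx = ax$widths, wy = ay$widths, wz = az$widths,
    edges = list(x = ax$edges, y = ay$edges, z = az$edges),
    xc = xc, yc = yc, zc = zc,
    volume = wxc * wyc * wzc,
    mat = mat, egg_id = egg_id, egg_cells = egg_cells,
    rho = rho, cp = cp, kc = kc, bctype = bctype,
    geometry = geometry, layout = layout
  ), class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf(
    "<simulation_grid> %d x %d x %d = %s cells (%d egg-tagged, %d Dirichlet)\n",
    x$nx, x$ny, x$nz, format(x$n_cells, big.mark = ","),
    sum(x$mat == 3L), sum(x$bctype > 0L)))
  invisible(x)
}
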