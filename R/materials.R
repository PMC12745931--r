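#' Constituent phase
#'
#' A single constituent of a granular mixture (mineral grains, pore water or
#' pore air), carrying the three constants that enter the heat equation.
#'
#' @param name Label for the phase.
#' @param density Particle density in kg m^-3.
#' @param conductivity Thermal conductivity in W m^-1 degC^-1.
#' @param heat_capacity Specific heat capacity in J kg^-1 degC^-1.
#' @return An object of class `constituent_phase`.
#' @export
constituent_phase <- function(name, density, conductivity, heat_capacity) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  if (!is.finite(conductivity) || conductivity <= 0)
    stop("conductivity must be positive", call. = FALSE)
  if (!is.finite(heat_capacity) || heat_capacity <= 0)
    stop("heat_capacity must be positive", call. = FALSE)
  structure(list(name = name, density = density,
                 conductivity = conductivity, heat_capacity = heat_capacity),
            class = "constituent_phase")
}

#' @export
print.constituent_phase <- function(x, ...) {
  cat(sprintf("<constituent_phase> %s: rho=%g kg/m3, k=%g W/m/degC, c=%g J/kg/degC\n",
              x$name, x$density, x$conductivity, x$heat_capacity))
  invisible(x)
}

#' Default constituent constants for beach sand
#'
#' Handbook-style constants for the three phases of a nesting-beach sand:
#' quartzite grains, pore water and pore air. The quartzite conductivity
#' (5.6 W m^-1 degC^-1) sits in the usual 5-7 W m^-1 degC^-1 handbook range
#' and, together with the water and air values, reproduces the reference
#' effective conductivities of the beach and nest-chamber sands used
#' throughout the package. The water heat capacity is the tabulated value
#' near 0 degC. All values are overridable per call.
#'
#' @return Named list of `constituent_phase` objects: `quartzite`, `water`,
#'   `air`.
#' @export
default_constituents <- function() {
  list(
    quartzite = constituent_phase("quartzite", 2650, 5.6, 661.3),
    water = constituent_phase("water", 1000, 0.60, 4217),
    air = constituent_phase("air", 1.2, 0.026, 1005)
  )
}

#' Phase volume fractions of an unsaturated sand
#'
#' Splits unit bulk volume into solid, water and air fractions from the dry
#' bulk density and the gravimetric moisture content (water mass per unit dry
#' mass).
#'
#' @param dry_bulk_density Dry bulk density, kg m^-3.
#' @param particle_density Particle (grain) density, kg m^-3.
#' @param gravimetric_moisture Water mass fraction of dry mass, in `[0, 1)`.
#' @param water_density Water density, kg m^-3.
#' @return Named numeric vector `c(solid, water, air)` summing to 1.
#' @export
volume_fractions <- function(dry_bulk_density, particle_density = 2650,
                             gravimetric_moisture, water_density = 1000) {
  stopifnot(is.finite(dry_bulk_density), is.finite(particle_density),
            is.finite(gravimetric_moisture), is.finite(water_density))
  if (dry_bulk_density <= 0) stop("dry bulk density must be positive", call. = FALSE)
  if (gravimetric_moisture < 0 || gravimetric_moisture >= 1)
    stop("gravimetric moisture must lie in [0, 1)", call. = FALSE)
  if (dry_bulk_density > particle_density)
    stop("dry bulk density exceeds particle density: physically impossible",
         call. = FALSE)
  f_solid <- dry_bulk_density / particle_density
  f_water <- gravimetric_moisture * dry_bulk_density / water_density
  f_air <- 1 - f_solid - f_water
  if (f_air < 0)
    stop("negative air fraction: mixture is over-saturated (inconsistent inputs)",
         call. = FALSE)
  c(solid = f_solid, water = f_water, air = f_air)
}

#' Mori-Tanaka effective conductivity (spherical inclusions)
#'
#' Effective thermal conductivity of a matrix with embedded spherical
#' inclusions, using the Mori-Tanaka mean-field estimate
#' \deqn{k_{eff} = k_m + \frac{\sum_i f_i (k_i - k_m) A_i}
#'   {f_m + \sum_i f_i A_i}, \quad A_i = \frac{3 k_m}{2 k_m + k_i}.}
#'
#' @param matrix_phase A `constituent_phase` acting as the continuous matrix.
#' @param inclusions List of `list(phase = constituent_phase, fraction = f)`
#'   entries; the matrix fraction is `1 - sum(f)`.
#' @return Effective conductivity, W m^-1 degC^-1.
#' @export
mori_tanaka_conductivity <- function(matrix_phase, inclusions) {
  stopifnot(inherits(matrix_phase, "constituent_phase"))
  km <- matrix_phase$conductivity
  fi <- vapply(inclusions, function(p) p$fraction, numeric(1))
  ki <- vapply(inclusions, function(p) p$phase$conductivity, numeric(1))
  if (any(fi < 0) || sum(fi) > 1 + 1e-10)
    stop("inclusion fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  if (any(ki <= 0) || km <= 0)
    stop("conductivities must be positive", call. = FALSE)
  fm <- 1 - sum(fi)
  A <- 3 * km / (2 * km + ki)
  keff <- km + sum(fi * (ki - km) * A) / (fm + sum(fi * A))
  kmin <- min(km, ki); kmax <- max(km, ki)
  # mean-field estimate must respect the elementary bounds
  stopifnot(keff >= kmin - 1e-12, keff <= kmax + 1e-12)
  keff
}

#' Rule-of-mixtures heat capacity
#'
#' Mass-weighted specific heat capacity of a mixture,
#' \eqn{c_{eff} = \sum_i w_i c_i} with mass fractions `w` summing to 1.
#'
#' @param phases List of `list(phase = constituent_phase, fraction = w)`
#'   entries with mass fractions `w`.
#' @param tol Tolerance on the sum of fractions.
#' @return Effective specific heat capacity, J kg^-1 degC^-1.
#' @export
mixture_heat_capacity <- function(phases, tol = 1e-8) {
  w <- vapply(phases, function(p) p$fraction, numeric(1))
  ci <- vapply(phases, function(p) p$phase$heat_capacity, numeric(1))
  if (abs(sum(w) - 1) > tol)
    stop("mass fractions must sum to 1", call. = FALSE)
  sum(w * ci)
}

#' Sand heat capacity on a dry-mass basis
#'
#' Specific heat capacity of an unsaturated sand expressed per unit dry mass:
#' `c_solid + moisture * c_water`. This convention pairs with the dry bulk
#' density, so that `rho_dry * C` equals the volumetric heat capacity of the
#' solid + water mixture (pore air carries negligible mass). The reference
#' property set for repacked egg-chamber sand excludes the pore-water term
#' (`include_pore_water = FALSE`), matching the published effective value for
#' that material; the physically complete form is the default for
#' user-supplied sands.
#'
#' @param gravimetric_moisture Water mass per unit dry mass, in `[0, 1)`.
#' @param constituents Named list of phases as in [default_constituents()].
#' @param include_pore_water Include the `moisture * c_water` term?
#' @return Specific heat capacity, J kg^-1 degC^-1 (per unit dry mass).
#' @export
sand_heat_capacity <- function(gravimetric_moisture,
                               constituents = default_constituents(),
                               include_pore_water = TRUE) {
  if (gravimetric_moisture < 0 || gravimetric_moisture >= 1)
    stop("gravimetric moisture must lie in [0, 1)", call. = FALSE)
  cs <- constituents$quartzite$heat_capacity
  cw <- constituents$water$heat_capacity
  if (include_pore_water) cs + gravimetric_moisture * cw else cs
}

#' Effective thermal properties of a sand subdomain
#'
#' Derives the density / conductivity / heat-capacity triple used by the heat
#' equation from field measurements: conductivity by Mori-Tanaka
#' homogenisation of quartzite grains with water and air inclusions (volume
#' fractions from [volume_fractions()]), heat capacity by the dry-mass-basis
#' rule of mixtures of [sand_heat_capacity()].
#'
#' @param dry_bulk_density Dry bulk density, kg m^-3.
#' @param gravimetric_moisture Water mass per unit dry mass.
#' @param constituents Constituent constants, see [default_constituents()].
#' @param include_pore_water Passed to [sand_heat_capacity()].
#' @return An `effective_properties` object (fields `density`, `conductivity`,
#'   `heat_capacity`).
#' @export
sand_properties <- function(dry_bulk_density, gravimetric_moisture,
                            constituents = default_constituents(),
                            include_pore_water = TRUE) {
  f <- volume_fractions(dry_bulk_density,
                        particle_density = constituents$quartzite$density,
                        gravimetric_moisture = gravimetric_moisture,
                        water_density = constituents$water$density)
  k <- mori_tanaka_conductivity(
    constituents$quartzite,
    list(list(phase = constituents$water, fraction = unname(f["water"])),
         list(phase = constituents$air, fraction = unname(f["air"]))))
  cp <- sand_heat_capacity(gravimetric_moisture, constituents,
                           include_pore_water = include_pore_water)
  effective_properties(dry_bulk_density, k, cp)
}

#' Effective properties container
#'
#' @param density Density, kg m^-3 (for sands: dry bulk density, paired with
#'   the dry-mass-basis heat capacity).
#' @param conductivity Thermal conductivity, W m^-1 degC^-1.
#' @param heat_capacity Specific heat capacity, J kg^-1 degC^-1.
#' @return An object of class `effective_properties`.
#' @export
effective_properties <- function(density, conductivity, heat_capacity) {
  vals <- c(density, conductivity, heat_capacity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all effective properties must be positive and finite", call. = FALSE)
  structure(list(density = density, conductivity = conductivity,
                 heat_capacity = heat_capacity),
            class = "effective_properties")
}

#' @export
print.effective_properties <- function(x, ...) {
  cat(sprintf("<effective_properties> rho=%.4g kg/m3  k=%.4g W/m/degC  C=%.5g J/kg/degC\n",
              x$density, x$conductivity, x$heat_capacity))
  invisible(x)
}

#' Nest-chamber sand density from field volumes
#'
#' Density of the sand a female repacks around her clutch: the mass of sand
#' returned to the nest (beach density times returned volume) divided by the
#' unoccupied chamber volume (chamber minus clutch).
#'
#' @param beach_density Beach-sand dry bulk density, kg m^-3.
#' @param returned_sand_volume Volume of sand returned to the nest, m^3.
#' @param chamber_volume Egg-chamber volume, m^3.
#' @param clutch_volume Total egg volume, m^3.
#' @return Nest-sand density, kg m^-3.
#' @export
nest_sand_density <- function(beach_density, returned_sand_volume,
                              chamber_volume, clutch_volume) {
  if (returned_sand_volume <= 0)
    stop("returned sand volume must be positive", call. = FALSE)
  void <- chamber_volume - clutch_volume
  if (void <= 0)
    stop("clutch volume must be smaller than chamber volume", call. = FALSE)
  beach_density * returned_sand_volume / void
}

#' Egg thermal properties
#'
#' Eggs are modelled with the thermal properties of water throughout
#' incubation (they are ~80% water by mass and within a few percent of water
#' density). Defaults are overridable.
#'
#' @param density Egg density, kg m^-3.
#' @param conductivity Egg conductivity, W m^-1 degC^-1.
#' @param heat_capacity Egg specific heat capacity, J kg^-1 degC^-1.
#' @return An `effective_properties` object.
#' @export
egg_properties <- function(density = 1000, conductivity = 0.6,
                           heat_capacity = 4177.6) {
  effective_properties(density, conductivity, heat_capacity)
}

#' Reference material set
#'
#' The canonical per-subdomain properties used by the simulator: beach sand
#' (dry bulk density 1282.2 kg m^-3, 4.0% moisture), repacked nest-chamber
#' sand (1026.6 kg m^-3, same moisture assumed, pore water excluded from the
#' heat-capacity budget) and eggs-as-water. All derived through the
#' homogenisation chain, not hard-coded.
#'
#' @param beach_density Beach dry bulk density, kg m^-3.
#' @param nest_density Nest-chamber dry bulk density, kg m^-3.
#' @param moisture Gravimetric moisture for both sands.
#' @param constituents Constituent constants.
#' @return Named list of `effective_properties`: `beach`, `nest`, `egg`.
#' @export
reference_materials <- function(beach_density = 1282.2, nest_density = 1026.6,
                                moisture = 0.04,
                                constituents = default_constituents()) {
  list(
    beach = sand_properties(beach_density, moisture, constituents),
    nest = sand_properties(nest_density, moisture, constituents,
                           include_pore_water = FALSE),
    egg = egg_properties()
  )
}

#' Read a field sand-core table and derive bulk density and moisture
#'
#' Reads a CSV of core measurements (columns `depth_cm`, `wet_mass_g`,
#' `dry_mass_g`, `core_volume_cm3`) and returns per-core and pooled dry bulk
#' density (kg m^-3) and gravimetric moisture.
#'
#' @param path Path to the CSV file.
#' @return List with `cores` (data frame) and pooled `dry_bulk_density`,
#'   `moisture`.
#' @export
read_sand_cores <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_cm", "wet_mass_g", "dry_mass_g", "core_volume_cm3")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sand-core CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L) stop("sand-core CSV is empty", call. = FALSE)
  d$dry_bulk_density <- 1000 * d$dry_mass_g / d$core_volume_cm3
  d$moisture <- (d$wet_mass_g - d$dry_mass_g) / d$dry_mass_g
  list(cores = d,
       dry_bulk_density = mean(d$dry_bulk_density),
       moisture = mean(d$moisture))
}
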