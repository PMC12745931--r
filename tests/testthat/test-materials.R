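test_that("volume fractions split bulk volume consistently and round-trip", {
  # fully solid limit
  f <- volume_fractions(2650, 2650, 0)
  expect_equal(unname(f), c(1, 0, 0))

  f <- volume_fractions(1282.2, 2650, 0.04, 1000)
  expect_equal(unname(f["solid"]), 1282.2 / 2650, tolerance = 1e-12)
  expect_equal(unname(f["water"]), 0.04 * 1282.2 / 1000, tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-15)

  # round-trip: reconstruct the field measurements from the fractions
  withr::with_seed(11, {
    for (i in 1:25) {
      db <- runif(1, 900, 1800); m <- runif(1, 0, 0.15)
      f <- volume_fractions(db, 2650, m, 1000)
      db_back <- unname(f["solid"]) * 2650
      m_back <- unname(f["water"]) * 1000 / db_back
      expect_equal(db_back, db, tolerance = 1e-9)
      expect_equal(m_back, m, tolerance = 1e-9)
    }
  })

  expect_error(volume_fractions(3000, 2650, 0.04), "impossible")
  expect_error(volume_fractions(2600, 2650, 0.5), "over-saturated")
})

test_that("Mori-Tanaka conductivity has the homogeneous limit and is monotone", {
  ph <- function(k) constituent_phase("p", 1000, k, 1000)
  # identical phases collapse to the common conductivity
  expect_equal(mori_tanaka_conductivity(ph(1.3), list(
    list(phase = ph(1.3), fraction = 0.3),
    list(phase = ph(1.3), fraction = 0.2))), 1.3)
  # zero inclusion fraction returns the matrix value
  expect_equal(mori_tanaka_conductivity(ph(2.7), list(
    list(phase = ph(9), fraction = 0))), 2.7)
  # monotone non-decreasing in each phase conductivity
  withr::with_seed(21, {
    for (i in 1:20) {
      km <- runif(1, 0.5, 8); ki <- runif(1, 0.01, 8); f <- runif(1, 0.05, 0.6)
      base <- mori_tanaka_conductivity(ph(km), list(list(phase = ph(ki), fraction = f)))
      up_i <- mori_tanaka_conductivity(ph(km), list(list(phase = ph(ki * 1.2), fraction = f)))
      up_m <- mori_tanaka_conductivity(ph(km * 1.2), list(list(phase = ph(ki), fraction = f)))
      expect_gte(up_i, base - 1e-12)
      expect_gte(up_m, base - 1e-12)
      expect_gte(base, min(km, ki) - 1e-12)
      expect_lte(base, max(km, ki) + 1e-12)
    }
  })
})

test_that("Mori-Tanaka estimates lie within independent Hashin-Shtrikman bounds", {
  withr::with_seed(31, {
    for (i in 1:25) {
      km <- runif(1, 0.3, 9); ki <- runif(1, 0.01, 9); fi <- runif(1, 0.02, 0.7)
      mt <- mori_tanaka_conductivity(
        constituent_phase("m", 1, km, 1),
        list(list(phase = constituent_phase("i", 1, ki, 1), fraction = fi)))
      hs <- hs_bounds_two_phase(km, 1 - fi, ki, fi)
      expect_gte(mt, hs["lower"] - 1e-9)
      expect_lte(mt, hs["upper"] + 1e-9)
    }
  })
})

test_that("rule-of-mixtures heat capacity is mass-weighted and bounded", {
  ph <- function(c) list(phase = constituent_phase("p", 1000, 1, c))
  expect_equal(mixture_heat_capacity(list(c(ph(750), fraction = 1))), 750)
  expect_equal(mixture_heat_capacity(list(c(ph(1000), fraction = 0.5),
                                          c(ph(3000), fraction = 0.5))), 2000)
  expect_error(mixture_heat_capacity(list(c(ph(1000), fraction = 0.6),
                                          c(ph(3000), fraction = 0.6))),
               "sum to 1")
  withr::with_seed(41, {
    for (i in 1:10) {
      cs <- runif(3, 500, 4500); w <- runif(3); w <- w / sum(w)
      c_eff <- mixture_heat_capacity(list(c(ph(cs[1]), fraction = w[1]),
                                          c(ph(cs[2]), fraction = w[2]),
                                          c(ph(cs[3]), fraction = w[3])))
      expect_gte(c_eff, min(cs)); expect_lte(c_eff, max(cs))
    }
  })
})

test_that("nest-chamber sand density follows the returned-sand mass balance", {
  # identity packing: returned volume equals the void -> beach density
  expect_equal(nest_sand_density(1282.2, 0.015, 0.018, 0.003), 1282.2)
  expect_equal(nest_sand_density(1282.2, 0.012, 0.018, 0.003),
               1282.2 * 0.012 / 0.015) # = 1025.76, the arithmetic oracle
  expect_error(nest_sand_density(1282.2, 0.012, 0.003, 0.018), "smaller")
  expect_error(nest_sand_density(1282.2, -1, 0.018, 0.003), "positive")
})

test_that("egg properties default to water and validate overrides", {
  e <- egg_properties()
  expect_equal(c(e$density, e$conductivity, e$heat_capacity),
               c(1000, 0.6, 4177.6))
  e2 <- egg_properties(conductivity = 0.65)
  expect_equal(e2$conductivity, 0.65)
  expect_equal(e2$density, 1000)
  expect_equal(e2$heat_capacity, 4177.6)
  expect_error(egg_properties(density = -5), "positive")
})

test_that("derived sand properties preserve the beach/nest ordering", {
  m <- reference_materials()
  # lower dry bulk density at equal moisture -> lower conductivity
  expect_lt(m$nest$conductivity, m$beach$conductivity)
  # effective conductivities sit between the air and grain conductivities
  cons <- default_constituents()
  for (p in list(m$beach, m$nest)) {
    expect_gt(p$conductivity, cons$air$conductivity)
    expect_lt(p$conductivity, cons$quartzite$conductivity)
  }
})

test_that("field sand-core tables reduce to bulk density and moisture", {
  path <- withr::local_tempfile(fileext = ".csv")
  # 310 cm3 cores: dry mass 397.5 g -> 1282.26 kg/m3; 4% moisture
  write.csv(data.frame(depth_cm = c(33, 53), wet_mass_g = c(413.4, 413.4),
                       dry_mass_g = c(397.5, 397.5),
                       core_volume_cm3 = c(310, 310)),
            path, row.names = FALSE)
  cores <- read_sand_cores(path)
  expect_equal(cores$dry_bulk_density, 1000 * 397.5 / 310, tolerance = 1e-9)
  expect_equal(cores$moisture, (413.4 - 397.5) / 397.5, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_sand_cores(bad), "missing columns")
})
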