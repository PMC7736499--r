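test_that("scenario specifications carry the canonical multipliers", {
  b <- scenario_spec("baseline"); i <- scenario_spec("i")
  ii <- scenario_spec("ii"); iii <- scenario_spec("iii")
  expect_equal(c(b$density_multiplier, b$area_multiplier), c(1, 1))
  expect_equal(c(i$density_multiplier, i$area_multiplier), c(2, 0.5))
  expect_equal(c(ii$density_multiplier, ii$area_multiplier), c(1, 0.5))
  expect_equal(c(iii$density_multiplier, iii$area_multiplier), c(1, 1))
  expect_false(any(b$lateral_shift, i$lateral_shift, ii$lateral_shift))
  expect_true(iii$lateral_shift)
})

test_that("transporter counts honour the per-scenario contract", {
  m <- test_geometry()
  dens <- 7500
  n0 <- round(dens * 1e-6 * m$membrane_area_um2[1] * 1e6)
  base <- place_transporters(m, scenario_spec("baseline"), dens, seed = 5)
  si <- place_transporters(m, scenario_spec("i"), dens, seed = 5)
  sii <- place_transporters(m, scenario_spec("ii"), dens, seed = 5)
  siii <- place_transporters(m, scenario_spec("iii"), dens, seed = 5,
                             nmdar_side = "+u")
  expect_equal(base$counts, rep(n0, 4))
  expect_equal(si$counts, rep(n0, 4))
  expect_true(all(abs(sii$counts - n0 / 2) <= 1))
  expect_equal(siii$counts, rep(n0, 4))
  expect_equal(place_transporters(m, scenario_spec("none"), dens)$counts,
               rep(0L, 4))
})

test_that("scenario i doubles local density on half the area", {
  m <- test_geometry()
  si <- place_transporters(m, scenario_spec("i"), 7500, seed = 2)
  base <- place_transporters(m, scenario_spec("baseline"), 7500, seed = 2)
  area <- function(p) sum((p[, "umax"] - p[, "umin"]) *
                            (p[, "vmax"] - p[, "vmin"]))
  s1 <- si$patches[si$patches[, "sector"] == 1, , drop = FALSE]
  b1 <- base$patches[base$patches[, "sector"] == 1, , drop = FALSE]
  expect_equal(area(s1), area(b1) / 2)
  # equal counts on half the area => doubled local density
  expect_equal(si$counts[1], base$counts[1])
})

test_that("transporter positions lie on the occupied membrane patches", {
  m <- test_geometry()
  tr <- place_transporters(m, scenario_spec("baseline"), 7500, seed = 9)
  p <- tr$positions
  onwall <- pmax(abs(p$x), abs(p$y))
  expect_true(all(abs(onwall - m$wall_distance) < 1e-9))
  expect_true(all(abs(p$z) >= m$band_v[1] & abs(p$z) <= m$band_v[2]))
  expect_equal(sort(unique(p$sector)), 1:4)
})

test_that("degenerate and invalid transporter requests are handled", {
  m <- test_geometry()
  expect_equal(nrow(place_transporters(m, scenario_spec("baseline"),
                                       surface_density = 0)$positions), 0L)
  expect_error(place_transporters(m, scenario_spec("iii"), 7500),
               "NMDAR-cluster side")
  expect_error(place_transporters(m, scenario_spec("baseline"), -1), ">= 0")
})

test_that("NMDAR clusters sit in the radial band on the postsynaptic side", {
  m <- test_geometry()
  rc <- place_nmdars(m, n_receptors = 25, seed = 4)
  expect_true(all(rc$radial_distance >= 200 & rc$radial_distance <= 250))
  expect_true(all(rc$positions$z < 0))
  # on the postsynaptic sphere surface
  d <- sqrt(rc$positions$x^2 + rc$positions$y^2 + (rc$positions$z + m$zc)^2)
  expect_true(all(abs(d - m$hemisphere_radius) < 1e-6))
  # deterministic under a fixed seed; empty when no receptors requested
  rc2 <- place_nmdars(m, n_receptors = 25, seed = 4)
  expect_identical(rc$positions, rc2$positions)
  expect_equal(nrow(place_nmdars(m, n_receptors = 0)$positions), 0L)
  expect_error(place_nmdars(m, cluster_band = c(1000, 1200)),
               "configuration error")
})

test_that("kinetic schemes are validated and rates extracted", {
  expect_error(kinetic_scheme("x", c("a", "b"),
                              data.frame(from = "a", to = "b", rate = -1,
                                         glu_dependent = TRUE), "b"),
               "negative rate")
  expect_error(kinetic_scheme("x", c("a", "b"),
                              data.frame(from = "a", to = "b", rate = 1,
                                         glu_dependent = FALSE), "b"),
               "glutamate-dependent")
  expect_error(kinetic_scheme("x", c("a", "b", "c"),
                              data.frame(from = "a", to = "b", rate = 1,
                                         glu_dependent = TRUE), "b"),
               "not connected")
  sch <- default_schemes()
  r <- scheme_rates(sch)
  expect_true(all(r >= 0))
  expect_named(r, c("t_unbind", "t_uptake", "r_unbind1", "r_unbind2",
                    "r_open", "r_close"))
  # rates live in the scheme objects: modifying them reaches the engine input
  sch$transporter$transitions$rate[2] <- 99
  expect_equal(unname(scheme_rates(sch)["t_unbind"]), 99)
})
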