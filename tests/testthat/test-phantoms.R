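test_that("configuration geometry defaults are correct", {
  b <- make_configuration("B", "Lu177")
  sph <- b$compartments[[2]]
  expect_equal(4 / 3 * pi * sph$radius^3, 100, tolerance = 1e-10)
  cyl <- b$compartments[[1]]
  expect_equal(2 * cyl$radius, 20)

  # derived sphere radius for the 1-mL point source
  a <- make_configuration("A", "I131")
  expect_equal(a$compartments[[1]]$radius, (3 / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(round(a$compartments[[1]]$radius, 3), 0.620)

  c6 <- make_configuration("C", "Re188")
  act <- compartment_activities(c6)
  conc <- act$activity / act$volume_ml
  expect_equal(max(conc) / min(conc), 6, tolerance = 1e-10)

  expect_error(make_configuration("B", "Lu177",
                                  params = list(sphere_volume_ml = 5e4)),
               "does not fit")
  expect_error(make_configuration("C", "Lu177",
                                  params = list(concentration_ratio = -1)),
               "positive")
})

test_that("compartment activities give normalized decay weights", {
  b <- make_configuration("B", "Lu177")
  act <- compartment_activities(b)
  expect_equal(sum(act$weight), 1)
  expect_equal(act$weight[act$shape == "sphere"], 1)  # cold background

  # closed-form sphere activity fraction at 6:1 with 6-L cylinder
  cc <- make_configuration("C", "I131")
  act <- compartment_activities(cc)
  f_sphere <- act$weight[act$shape == "sphere"]
  expect_equal(f_sphere, 6 * 100 / (6 * 100 + 5900), tolerance = 2e-3)

  # explicit per-compartment decay budget (reference run, config C)
  act4 <- compartment_activities(cc, activities = c(1.2e10, 1.1e9))
  expect_equal(act4$weight, c(1.2e10, 1.1e9) / 1.31e10)
  expect_true(all(act4$weight >= 0))

  zero <- make_configuration("D", "Lu177")
  zero$compartments[[1]]$conc <- 0
  expect_error(compartment_activities(zero), "zero total activity")
})

test_that("attenuation maps hold narrow-beam coefficients and volumes", {
  # air-only phantom: all-zero map
  a <- make_configuration("A", "I131")
  m <- make_attenuation_map(a, grid_shape = 32, voxel_size = 19.16)
  expect_true(all(m$mu == 0))

  d <- make_configuration("D", "Lu177")
  m <- make_attenuation_map(d)  # 64^3 @ 9.58 mm, 208 keV
  expect_equal(max(m$mu), mu_linear("water", 208), tolerance = 1e-12)
  expect_equal(m$energy, 208)
  # interior voxel away from boundaries
  expect_equal(m$mu[32, 32, 32], mu_linear("water", 208))
  # water-equivalent volume ~6 L within 2%
  expect_equal(attenuation_map_volume(m), 6.0, tolerance = 0.02)

  expect_error(make_attenuation_map(d, grid_shape = 16, voxel_size = 9.58),
               "too small")
})

test_that("central rays through the map reproduce analytic line integrals", {
  d <- make_configuration("D", "Lu177")
  m <- make_attenuation_map(d)
  vs <- m$voxel_size / 10
  muw <- mu_linear("water", m$energy)
  for (i in c(32, 33)) for (k in c(32, 33)) {
    li <- sum(m$mu[i, , k]) * vs
    x <- (i - 0.5) * vs - m$grid_shape * vs / 2  # column offset from axis
    chord <- 2 * sqrt(10^2 - x^2)
    expect_equal(li, muw * chord, tolerance = 0.01)
  }
})
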