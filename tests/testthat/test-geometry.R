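test_that("sphere geometry reproduces the 12 um tumor cell", {
  g <- sphere_geometry(12)
  expect_equal(g$volume, 905, tolerance = 1e-3)
  expect_equal(g$surface_area, 452, tolerance = 1e-3)
  # unit-radius sphere
  expect_equal(sphere_geometry(2)$volume, 4 / 3 * pi)
  # capillary lumen cross-section by direct arithmetic
  expect_equal(capillary_geometry(13.94, 0.5)$lumen_cross_section,
               pi * 13.94^2 / 4)
  expect_error(sphere_geometry(-1), "positive")
  expect_error(sphere_geometry(0), "positive")
})

test_that("dodecahedral surface area follows the closed form", {
  expect_equal(dodecahedron_surface_from_volume(sphere_geometry(12)$volume),
               497, tolerance = 1e-3)
  # unit edge length: V = (15 + 7 sqrt 5)/4, A = 3 sqrt(25 + 10 sqrt 5)
  expect_equal(dodecahedron_surface_from_volume((15 + 7 * sqrt(5)) / 4),
               3 * sqrt(25 + 10 * sqrt(5)), tolerance = 1e-10)
  # scaling oracle: A(V) = A(905) * (V/905)^(2/3), cross-checked
  # against the sphere-area ratio which is volume-independent
  v0 <- sphere_geometry(12)$volume
  a0 <- dodecahedron_surface_from_volume(v0)
  expect_equal(dodecahedron_surface_from_volume(100),
               a0 * (100 / v0)^(2 / 3), tolerance = 1e-10)
  r_d <- dodecahedron_surface_from_volume(100) /
    (pi^(1 / 3) * (6 * 100)^(2 / 3))
  expect_equal(r_d, a0 / sphere_geometry(12)$surface_area,
               tolerance = 1e-10)
  expect_gt(r_d, 1)  # dodecahedron exceeds the equal-volume sphere
  expect_error(dodecahedron_surface_from_volume(0), "positive")
})

test_that("capillary density and perimeter derivations match print", {
  cap <- capillary_geometry(13.94, 0.5)
  expect_equal(cap$outer_cross_section, 175, tolerance = 2e-3)
  expect_equal(cap$outer_perimeter_circular, 46.9, tolerance = 1e-3)
  expect_equal(cap$true_perimeter, 57.7, tolerance = 1e-3)
  expect_equal(capillary_density(cap$lumen_cross_section, 0.10), 655,
               tolerance = 1e-3)
  expect_equal(capillary_density(500, 0), 0)
  expect_equal(capillary_density(100, 0.05), 500)
  expect_error(capillary_density(0, 0.1), "positive")
  # strictly increasing in vascular fraction, decreasing in lumen area
  f <- seq(0.02, 0.3, by = 0.02)
  expect_true(all(diff(capillary_density(150, f)) > 0))
  a <- seq(50, 300, by = 25)
  expect_true(all(diff(capillary_density(a, 0.1)) < 0))
})

test_that("surface densities and EC wall fraction match print", {
  g <- derive_tumor_geometry()
  comp <- g$composition
  expect_equal(comp$S_EC, 378, tolerance = 1e-3)
  expect_equal(comp$S_PC, 2939, tolerance = 1e-3)
  # EC wall occupies 1.5% of tissue (printed to one decimal)
  expect_equal(round(100 * comp$f_EC_wall, 1), 1.5)
  # volume closure: vascular + wall + cells + interstitium = 1
  expect_equal(comp$f_intravascular + comp$f_EC_wall +
                 comp$f_parenchymal + comp$f_interstitial, 1,
               tolerance = 0.005)
  # S_EC linear in capillary density, S_PC linear in cell fraction
  cell <- dodecahedron_geometry(sphere_geometry(12)$volume)
  cap <- capillary_geometry(13.94, 0.5)
  s1 <- surface_densities(cap, 300, cell, 0.2)
  s2 <- surface_densities(cap, 600, cell, 0.4)
  expect_equal(s2$S_EC / s1$S_EC, 2)
  expect_equal(s2$S_PC / s1$S_PC, 2)
  expect_equal(surface_densities(cap, 655, cell, 0)$S_PC, 0)
})

test_that("interstitial available fluid volumes are region products", {
  reg <- interstitial_partition(data.frame(
    region = c("ECM", "EBM", "PBM"),
    volume_fraction = c(0.3404, 0.0081, 0.0015),
    fluid_fraction = c(0.9318, 0.7, 0.7),
    partition_coefficient = c(0.9, 0.9, 0.9)), f_interstitial = 0.35)
  expect_equal(reg$available_fluid_volume[reg$region == "EBM"],
               0.0081 * 0.7 * 0.9)
  expect_equal(reg$available_fluid_volume[reg$region == "EBM"], 5.10e-3,
               tolerance = 0.01)
  expect_equal(reg$available_fluid_volume[reg$region == "ECM"], 0.2855,
               tolerance = 1e-3)
  # partition coefficient and fluid fraction of 1 leave the volume
  one <- interstitial_partition(data.frame(
    region = "ECM", volume_fraction = 0.3, fluid_fraction = 1,
    partition_coefficient = 1), f_interstitial = 0.35)
  expect_equal(one$available_fluid_volume, 0.3)
  expect_true(all(reg$available_fluid_volume <= reg$volume_fraction))
  expect_error(
    interstitial_partition(data.frame(
      region = "ECM", volume_fraction = 0.5, fluid_fraction = 0.9,
      partition_coefficient = 0.9), f_interstitial = 0.35),
    "sum above")
  expect_error(
    interstitial_partition(data.frame(
      region = "ECM", volume_fraction = 1.2, fluid_fraction = 0.9,
      partition_coefficient = 0.9)),
    "\\[0, 1\\]")
})

test_that("half-life to clearance conversion matches the printed rate", {
  expect_equal(half_life_to_clearance(72, "h", "min"), 1.6e-4,
               tolerance = 3e-3)
  expect_equal(half_life_to_clearance(72, "h", "min"), log(2) / (72 * 60))
  # alpha-2-macroglobulin: printed clearance 2.62e-3/min inverts to its
  # measured half-life
  expect_equal(half_life_to_clearance(log(2) / 2.62e-3, "min", "min"),
               2.62e-3)
})

test_that("geometry table exports every derived value", {
  tab <- geometry_table(derive_tumor_geometry())
  expect_true(all(c("S_EC", "S_PC", "capillary_density", "K_av") %in%
                    tab$quantity))
  expect_true(all(is.finite(tab$value)))
  path <- tempfile(fileext = ".csv")
  geometry_table(derive_tumor_geometry(), path)
  expect_equal(read.csv(path)$value, tab$value)
})
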