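test_that("isolated and well-separated spheres give analytic areas", {
  box <- new_box(10)
  # single atom: exactly 4*pi*(r+probe)^2 at any point count
  a1 <- shrake_rupley_area(matrix(c(5, 5, 5), 1), 0.15, box,
                           probe_radius = 0.1)
  expect_equal(a1, 4 * pi * 0.25^2)
  a1_dense <- shrake_rupley_area(matrix(c(5, 5, 5), 1), 0.15, box,
                                 probe_radius = 0.1, n_sphere_points = 1e4)
  expect_equal(a1_dense, 4 * pi * 0.25^2)
  # two atoms farther apart than 2(r+probe): exact additivity
  a2 <- shrake_rupley_area(rbind(c(2, 2, 2), c(4, 2, 2)), c(0.15, 0.15),
                           box, probe_radius = 0.1)
  expect_equal(a2, 2 * a1)
})

test_that("a fully enclosed atom exposes no area", {
  # central atom caged by six fat neighbors on the axes
  center <- c(5, 5, 5)
  shell <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 0.1, 0), c(0, -0.1, 0),
                 c(0, 0, 0.1), c(0, 0, -0.1))
  coords <- rbind(center, sweep(shell, 2, center, "+"))
  radii <- c(0.1, rep(0.4, 6))
  per <- shrake_rupley_area(coords, radii, new_box(10), probe_radius = 0.1,
                            per_atom = TRUE)
  expect_equal(per[1], 0)
})

test_that("areas converge in sphere-point count and match a dense oracle", {
  withr::with_seed(21, {
    coords <- matrix(runif(60, 0, 1.2), ncol = 3)
  })
  radii <- rep(0.15, 20)
  box <- new_box(2.5)
  a960 <- shrake_rupley_area(coords, radii, box, n_sphere_points = 960)
  a3840 <- shrake_rupley_area(coords, radii, box, n_sphere_points = 3840)
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
  a_oracle <- oracle_sasa(coords, radii, box, probe = 0.1, n_points = 4e4)
  expect_lt(abs(a960 - a_oracle) / a_oracle, 0.005)
})

test_that("periodic images bury surface across the box boundary", {
  box <- new_box(1.0)
  # two atoms touching only through the boundary image
  coords <- rbind(c(0.05, 0.5, 0.5), c(0.95, 0.5, 0.5))
  a_per <- shrake_rupley_area(coords, c(0.1, 0.1), box, probe_radius = 0.05)
  a_free <- shrake_rupley_area(coords, c(0.1, 0.1),
                               new_box(1.0, periodic = FALSE),
                               probe_radius = 0.05)
  expect_lt(a_per, a_free)
  expect_equal(a_free, 2 * 4 * pi * 0.15^2)
})

test_that("contact area is zero for disjoint groups and non-negative in contact", {
  # polymer cluster and water far apart: A_system = A_polymer + A_water
  cfg <- bead_water_config(rbind(c(1, 1, 1), c(1.4, 1, 1)),
                           c(6, 6, 6), box_len = 10)
  sa <- contact_area(cfg, n_sphere_points = 480)
  expect_equal(sa$A_contact, 0)
  expect_equal(sa$A_system, sa$A_polymer + sa$A_water)
  # water-free configuration
  dry <- bead_water_config(rbind(c(1, 1, 1), c(1.4, 1, 1)), box_len = 10)
  sa_dry <- suppressWarnings(contact_area(dry, n_sphere_points = 480))
  expect_equal(sa_dry$A_water, 0)
  expect_equal(sa_dry$A_contact, 0)
  # touching groups: positive contact area, identity holds by construction
  cfg2 <- bead_water_config(c(1, 1, 1), c(1.35, 1, 1), box_len = 10)
  sa2 <- contact_area(cfg2, n_sphere_points = 480)
  expect_gt(sa2$A_contact, 0)
  expect_equal(sa2$A_contact,
               sa2$A_polymer + sa2$A_water - sa2$A_system)
})

test_that("contact area grows while the first layer fills, then saturates", {
  # open coil (low density) so distant second-shell sites exist
  p <- generate_polymer_configuration(1, 30, target_density = 0.1,
                                      seed = 17)
  mp <- sum(p$atoms$mass)
  # shells: layer-1 waters hug the chain; layer-2 waters sit beyond reach of
  # the polymer surface (0.9 nm), so they cannot create new contact
  n_sat <- round(0.25 * mp / 18.015)
  area_at <- function(m, seed) {
    n_w <- round(m * mp / 18.015)
    w1 <- min(1, n_sat / n_w)
    sh <- shell_mixture(mean1 = 0.3, sd1 = 0.03, mean2 = 0.9, sd2 = 0.04,
                        weight1 = w1)
    h <- suppressWarnings(
      generate_hydrated_configuration(p, m, shells = sh, seed = seed))
    contact_area(h, n_sphere_points = 240)$A_contact
  }
  a_low <- area_at(0.10, 31)
  a_sat <- area_at(0.25, 32)
  a_high <- area_at(0.45, 33)
  expect_gt(a_sat, a_low * 1.5)          # filling regime: area still growing
  expect_lt(abs(a_high - a_sat) / a_sat, 0.15)  # saturated regime: plateau
})
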