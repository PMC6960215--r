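test_that("dry polymer generator hits the target density exactly and deterministically", {
  p <- generate_polymer_configuration(2, 40, target_density = 1.3, seed = 3)
  expect_equal(mass_density(p), 1.3, tolerance = 1e-3)
  expect_equal(moisture_content_of(p), 0)
  # same seed twice -> identical configuration
  p2 <- generate_polymer_configuration(2, 40, target_density = 1.3, seed = 3)
  expect_identical(p$atoms, p2$atoms)
  # halving the density scales the box edge by 2^(1/3)
  p_half <- generate_polymer_configuration(2, 40, target_density = 0.65,
                                           seed = 3)
  expect_equal(p_half$box$lengths / p$box$lengths, rep(2^(1 / 3), 3),
               tolerance = 1e-12)
  # chains are connected at the bond length
  d01 <- minimum_image_distance(as.numeric(p$atoms[1, c("x", "y", "z")]),
                                as.numeric(p$atoms[2, c("x", "y", "z")]),
                                p$box)
  expect_equal(d01, 0.5, tolerance = 1e-9)
})

test_that("infeasible packing densities are refused", {
  expect_error(
    generate_polymer_configuration(2, 500, target_density = 80, seed = 1,
                                   min_separation = 0.3),
    "infeasible")
})

test_that("hydration inserts the right number of waters with valid geometry", {
  p <- tiny_polymer()
  h <- suppressWarnings(generate_hydrated_configuration(p, 0.2, seed = 4))
  n_w <- sum(h$atoms$role == "water_O")
  mp <- sum(p$atoms$mass)
  expect_equal(n_w, round(0.2 * mp / 18.015))
  # moisture matches the request within one molecule's mass
  expect_lte(abs(h$moisture_content - 0.2), 18.015 / mp)
  # m = 0 returns the polymer untouched
  expect_identical(generate_hydrated_configuration(p, 0, seed = 4), p)
  # deterministic
  h2 <- suppressWarnings(generate_hydrated_configuration(p, 0.2, seed = 4))
  expect_identical(h$atoms, h2$atoms)
  # each water: one O, two H at 0.1 nm
  wo <- which(h$atoms$role == "water_O")[1]
  hw <- which(h$atoms$role == "water_H" &
                h$atoms$molecule_id == h$atoms$molecule_id[wo])
  expect_length(hw, 2)
  for (hi in hw) {
    expect_equal(minimum_image_distance(
      as.numeric(h$atoms[wo, c("x", "y", "z")]),
      as.numeric(h$atoms[hi, c("x", "y", "z")]), h$box), 0.1,
      tolerance = 1e-9)
  }
})

test_that("a degenerate first-shell-only mixture puts every water in layer 1", {
  p <- tiny_polymer()
  sh <- shell_mixture(mean1 = 0.28, sd1 = 0.005, mean2 = 0.56, sd2 = 0.15,
                      weight1 = 1)
  h <- generate_hydrated_configuration(p, 0.15, shells = sh, seed = 9)
  d <- polymer_water_distances(h)
  part <- assign_layers(d)
  expect_equal(part$n_w2 + part$n_beyond, 0)
  expect_equal(part$n_w1, sum(h$atoms$role == "water_O"))
})

test_that("realized nearest distances follow the requested truncated mixture", {
  # sparse polymer so the geometry hardly constrains placements
  p <- generate_polymer_configuration(1, 12, target_density = 0.02,
                                      seed = 2)
  sh <- shell_mixture()
  h <- suppressWarnings(
    generate_hydrated_configuration(p, 25, shells = sh, seed = 2))
  d <- polymer_water_distances(h)
  expect_gt(length(d), 2000)
  ks <- suppressWarnings(stats::ks.test(
    d, function(q) hydrolayers:::shell_mixture_cdf(q, sh, d_min = 0.15)))
  expect_gt(ks$p.value, 0.01)
})

test_that("fraction schedules close to 1, saturate at m_sat and stay in bounds", {
  m <- seq(0, 0.6, by = 0.025)
  sch <- generate_fraction_schedule(m, m_sat = 0.3)
  expect_equal(sch$f_p + sch$f_w1 + sch$f_w2, rep(1, nrow(sch)),
               tolerance = 1e-9)
  expect_true(all(sch$f_p >= 0 & sch$f_w1 >= 0 & sch$f_w2 >= 0))
  expect_true(all(diff(sch$f_w1) >= -1e-12))
  above <- sch$m >= 0.3 - 1e-9
  expect_equal(diff(range(sch$f_w1[above])), 0)
  expect_equal(as.numeric(sch[sch$m == 0, c("f_p", "f_w1", "f_w2")]),
               c(1, 0, 0))
  # explicit f_w1_max is honoured at the saturation point
  sch2 <- generate_fraction_schedule(m, m_sat = 0.3, f_w1_max = 0.1)
  expect_equal(sch2$f_w1[abs(sch2$m - 0.3) < 1e-9], 0.1)
  expect_error(generate_fraction_schedule(c(0.2, 0.1)), "increasing")
})

test_that("property curve generator matches composite models and seeds", {
  m <- seq(0, 0.5, length.out = 11)
  sch <- generate_fraction_schedule(m)
  # pure-polymer endpoint of a mixture curve
  cur <- generate_property_curve("mixture", 2.6, 4.6, 4.4, sch)
  expect_equal(cur$value[cur$m == 0], 2.6)
  # noise-free equals composite_predict everywhere
  expect_equal(cur$value,
               composite_predict("mixture", 2.6, 4.6, 4.4,
                                 sch$f_p, sch$f_w1, sch$f_w2))
  # series with a zero component is refused
  expect_error(generate_property_curve("series", 4, 0, 2, sch), "positive")
  # seeded noise is reproducible
  n1 <- generate_property_curve("mixture", 2.6, 4.6, 4.4, sch,
                                noise_sd = 0.1, seed = 7)
  n2 <- generate_property_curve("mixture", 2.6, 4.6, 4.4, sch,
                                noise_sd = 0.1, seed = 7)
  expect_identical(n1$value, n2$value)
})

test_that("linear series generator is exact at zero noise and reproducible", {
  s <- generate_linear_series(0, 3, 1:10)
  expect_equal(s$y, rep(3, 10))
  s2 <- generate_linear_series(-1.5, 2, seq(0, 1, 0.1))
  expect_equal(unname(coef(lm(s2$y ~ s2$x))[2]), -1.5, tolerance = 1e-12)
  a <- generate_linear_series(1, 0, 1:20, noise_sd = 1, seed = 3)
  b <- generate_linear_series(1, 0, 1:20, noise_sd = 1, seed = 3)
  expect_identical(a$y, b$y)
  expect_error(generate_linear_series(1, 0, numeric(0)), "non-empty")
})
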