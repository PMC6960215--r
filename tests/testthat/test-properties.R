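test_that("heat of adsorption is the per-mass binding energy against vapor", {
  # no binding: hydration energy equals dry + vapor reference
  expect_equal(heat_of_adsorption(-5000, -5000 + 100 * (-41), 100, -41), 0)
  # 4.07 kJ/mol binding per molecule -> 4.07 / 0.018015 kJ/kg
  q <- heat_of_adsorption(-5000, -5000 + 100 * (-41) - 100 * 4.07, 100, -41)
  expect_equal(q, 4.07 / 0.018015, tolerance = 1e-12)
  expect_equal(q, 225.9, tolerance = 1e-3)
  # intensive in the number of molecules at fixed per-molecule binding
  q2 <- heat_of_adsorption(-5000, -5000 + 200 * (-41) - 200 * 4.07, 200, -41)
  expect_equal(q2, q)
  expect_error(heat_of_adsorption(0, 0, 0, -41), "n_water")
})

test_that("thermal expansion coefficient is the normalized L(T) slope", {
  Tg <- seq(280, 320, by = 2)
  L <- observable_series(Tg, 5 * (1 + 2.3e-4 * (Tg - 300)),
                         kind = "length_vs_temperature")
  a <- thermal_expansion_coefficient(L, T0 = 300)
  expect_equal(a, 2.3e-4, tolerance = 1e-10)
  # constant length: zero expansion
  L0 <- observable_series(Tg, rep(5, length(Tg)),
                          kind = "length_vs_temperature")
  expect_equal(thermal_expansion_coefficient(L0, 300), 0)
  # invariant under rescaling of L
  L2 <- observable_series(Tg, 7.3 * 5 * (1 + 2.3e-4 * (Tg - 300)),
                          kind = "length_vs_temperature")
  expect_equal(thermal_expansion_coefficient(L2, 300), a,
               tolerance = 1e-12)
  expect_error(thermal_expansion_coefficient(L, T0 = 250), "outside")
  wrong <- observable_series(Tg, Tg, kind = "generic")
  expect_error(thermal_expansion_coefficient(wrong, 300), "kind")
})

test_that("heat capacity is the enthalpy slope per unit mass", {
  Tg <- seq(290, 310, by = 1)
  H <- observable_series(Tg, 4.594e-3 * Tg, kind = "enthalpy_vs_temperature")
  expect_equal(heat_capacity(H, mass = 1e-3), 4.594, tolerance = 1e-10)
  expect_equal(heat_capacity(H, mass = 2e-3), 4.594 / 2, tolerance = 1e-10)
  H0 <- observable_series(Tg, rep(1, length(Tg)),
                          kind = "enthalpy_vs_temperature")
  expect_equal(heat_capacity(H0, 1), 0)
  expect_error(heat_capacity(H, 0), "mass")
})

test_that("moduli come from the stress-strain slope inside the linear window", {
  eps <- seq(-0.05, 0.05, by = 0.005)
  ss <- observable_series(eps, 2.5 * eps, kind = "stress_vs_strain")
  expect_equal(modulus_from_stress_strain(ss), 2.5, tolerance = 1e-12)
  # offset stress does not change the slope
  ss_off <- observable_series(eps, 2.5 * eps + 0.7,
                              kind = "stress_vs_strain")
  expect_equal(modulus_from_stress_strain(ss_off), 2.5, tolerance = 1e-12)
  # zero stress everywhere
  ss0 <- observable_series(eps, rep(0, length(eps)),
                           kind = "stress_vs_strain")
  expect_equal(modulus_from_stress_strain(ss0), 0)
  # window restriction picks only the small-strain points
  y_nl <- 2.5 * eps + 40 * eps^3
  ss_nl <- observable_series(eps, y_nl, kind = "stress_vs_strain")
  expect_lt(abs(modulus_from_stress_strain(ss_nl, 0.01) - 2.5), 0.02)
  expect_error(modulus_from_stress_strain(ss, 1e-4), "fewer than 3")
})

test_that("Poisson's ratio is minus the transverse/axial strain slope", {
  ax <- seq(0, 0.02, by = 0.002)
  expect_equal(poissons_ratio(ax, -0.3 * ax), 0.3, tolerance = 1e-12)
  expect_equal(poissons_ratio(ax, -0.5 * ax), 0.5, tolerance = 1e-12)
  expect_equal(poissons_ratio(ax, rep(0, length(ax))), 0)
  expect_error(poissons_ratio(ax, c(1, 2)), "lengths differ")
})

test_that("estimators recover truth within three standard errors under noise", {
  Tg <- seq(280, 320, by = 2)
  n_rep <- 60
  alpha_true <- 2.3e-4
  hits <- 0
  withr::with_seed(99, {
    for (r in seq_len(n_rep)) {
      noisy <- 5 * (1 + alpha_true * (Tg - 300)) + rnorm(length(Tg), 0, 2e-4)
      fit <- lm(noisy ~ Tg)
      se_alpha <- summary(fit)$coefficients["Tg", "Std. Error"] / 5
      a <- thermal_expansion_coefficient(
        observable_series(Tg, noisy, kind = "length_vs_temperature"), 300)
      if (abs(a - alpha_true) <= 3 * se_alpha) hits <- hits + 1
    }
  })
  expect_gte(hits / n_rep, 0.9)
})

test_that("observable series validate their inputs", {
  expect_error(observable_series(c(1, 2, 2), c(1, 2, 3)), "monotone")
  expect_error(observable_series(1:3, 1:2), "equal length")
  expect_silent(observable_series(3:1, 1:3))
})
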