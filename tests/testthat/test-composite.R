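test_that("forward composite models evaluate their defining formulas", {
  # pure-polymer endpoint for every model
  for (k in c("mixture", "parallel", "series")) {
    expect_equal(composite_predict(k, 7.7, 1, 2, 1, 0, 0), 7.7)
  }
  # arithmetic mean with the adsorption-heat component triple
  expect_equal(composite_predict("mixture", 3340, 1110, 2660,
                                 0.8, 0.15, 0.05), 2971.5)
  # harmonic mean: 1/Xc = 0.5/4 + 0.25/2 + 0.25/2 = 0.375
  expect_equal(composite_predict("series", 4, 2, 2, 0.5, 0.25, 0.25),
               1 / 0.375)
  # harmonic-mean identity at equal components
  withr::with_seed(5, {
    for (i in 1:10) {
      f <- diff(sort(c(0, runif(2), 1)))
      expect_equal(composite_predict("series", 3.3, 3.3, 3.3,
                                     f[1], f[2], f[3]), 3.3,
                   tolerance = 1e-12)
    }
  })
  expect_error(composite_predict("series", 4, 0, 2, 0.5, 0.25, 0.25),
               "positive")
  expect_error(composite_predict("mixture", 1, 1, 1, 0.5, 0.2, 0.2),
               "sum to 1")
})

test_that("series predictions never exceed mixture predictions", {
  withr::with_seed(14, {
    for (i in 1:50) {
      X <- runif(3, 0.1, 10)
      f <- diff(sort(c(0, runif(2), 1)))
      s <- composite_predict("series", X[1], X[2], X[3], f[1], f[2], f[3])
      a <- composite_predict("mixture", X[1], X[2], X[3], f[1], f[2], f[3])
      expect_lte(s, a + 1e-12)
    }
  })
})

test_that("isotropic shear modulus follows G = 3KE/(9K - E)", {
  expect_equal(shear_from_isotropy(5.9, 4.6), 3 * 5.9 * 4.6 / (9 * 5.9 - 4.6))
  expect_equal(shear_from_isotropy(5.9, 4.6), 1.6787, tolerance = 1e-4)
  expect_equal(shear_from_isotropy(1.7, 0), 0)   # fluid limit
  expect_equal(shear_from_isotropy(1e9, 4.6), 4.6 / 3, tolerance = 1e-6)
  expect_error(shear_from_isotropy(0.1, 4.6), "positive")
})

test_that("composite fits round-trip generator truth exactly at zero noise", {
  m <- seq(0, 0.6, length.out = 13)
  sch <- generate_fraction_schedule(m)
  triples <- list(mixture = c(3340, 1110, 2660),
                  parallel = c(6.4e-5, 3.7e-4, 2.9e-4),
                  series = c(5.9, 1.9, 1.5))
  for (kind in names(triples)) {
    tr <- triples[[kind]]
    cur <- generate_property_curve(kind, tr[1], tr[2], tr[3], sch)
    fit <- fit_composite(kind, cur)
    expect_equal(c(fit$X_p, fit$X_w1, fit$X_w2), tr,
                 tolerance = 1e-6)
    expect_lt(fit$rss / sum(cur$value^2), 1e-12)
  }
})

test_that("constant fractions are reported as an identifiability failure", {
  m <- seq(0, 0.5, length.out = 8)
  sch <- data.frame(m = m, f_p = 0.7, f_w1 = 0.2, f_w2 = 0.1)
  cur <- property_curve(m, rep(2.5, 8), fractions = sch)
  expect_error(fit_composite("mixture", cur), "identifiable")
})

test_that("reported standard errors calibrate against noisy recovery", {
  m <- seq(0, 0.6, length.out = 25)
  sch <- generate_fraction_schedule(m)
  tr <- c(2.6, 4.6, 4.4)
  clean <- composite_predict("mixture", tr[1], tr[2], tr[3],
                             sch$f_p, sch$f_w1, sch$f_w2)
  noise_sd <- 0.02 * diff(range(clean))
  hits <- 0; n_rep <- 50
  for (r in seq_len(n_rep)) {
    cur <- generate_property_curve("mixture", tr[1], tr[2], tr[3], sch,
                                   noise_sd = noise_sd, seed = 1000 + r)
    fit <- fit_composite("mixture", cur)
    est <- c(fit$X_p, fit$X_w1, fit$X_w2)
    if (all(abs(est - tr) <= 3 * fit$se)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("default model kinds map properties as documented", {
  expect_equal(default_model_kind("K"), "series")
  expect_equal(default_model_kind("E"), "series")
  expect_equal(default_model_kind("G"), "series")
  expect_equal(default_model_kind("Q"), "mixture")
  expect_equal(default_model_kind("CP"), "mixture")
  expect_equal(default_model_kind("ALPHA"), "parallel")
  expect_error(default_model_kind("NU"), "no default")
})
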