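test_that("polymer-water distances take the nearest polymer atom under images", {
  # nearest of two polymer atoms
  cfg <- bead_water_config(rbind(c(0.01, 0.01, 0.01), c(0.5, 0.01, 0.01)),
                           c(1.0, 0.01, 0.01), box_len = 10)
  expect_equal(polymer_water_distances(cfg), 0.5, tolerance = 1e-9)
  # coincident water and polymer atom
  cfg0 <- bead_water_config(c(1, 1, 1), c(1, 1, 1), box_len = 10)
  expect_equal(polymer_water_distances(cfg0), 0)
  # minimum-image arithmetic across the boundary
  cfg_pbc <- bead_water_config(c(4.9, 1, 1), c(0.05, 1, 1), box_len = 5)
  expect_equal(polymer_water_distances(cfg_pbc), 0.15, tolerance = 1e-9)
  # no polymer -> error (construct with polymer then fake roles)
  cfg_bad <- bead_water_config(c(1, 1, 1), c(2, 2, 2))
  cfg_bad$atoms$role[1] <- "water_H"
  expect_error(polymer_water_distances(cfg_bad), "polymer")
})

test_that("population histogram bins, averages frames and reports truncation", {
  h <- population_histogram(c(0.27, 0.29), bin_width = 0.05, d_max = 1)
  expect_equal(h$population[abs(h$bin_edges[-1] - 0.30) < 1e-9], 2)
  expect_equal(sum(h$population), 2)
  # two identical frames average to the single-frame histogram
  h2 <- population_histogram(list(c(0.27, 0.29), c(0.27, 0.29)),
                             bin_width = 0.05, d_max = 1)
  expect_equal(h2$population, h$population)
  expect_equal(h2$n_frames, 2)
  # everything beyond d_max: empty histogram with a warning
  expect_warning(h3 <- population_histogram(c(2.5, 3), d_max = 2),
                 "beyond")
  expect_equal(sum(h3$population), 0)
  expect_equal(h3$truncated_fraction, 1)
})

test_that("double-Gaussian decomposition recovers noise-free constructions", {
  x <- seq(0.005, 1.995, by = 0.01)
  truth <- list(amp1 = 60, mean1 = 0.28, sd1 = 0.05,
                amp2 = 25, mean2 = 0.56, sd2 = 0.15)
  y <- truth$amp1 * exp(-(x - truth$mean1)^2 / (2 * truth$sd1^2)) +
    truth$amp2 * exp(-(x - truth$mean2)^2 / (2 * truth$sd2^2))
  h <- structure(list(bin_edges = seq(0, 2, 0.01), bin_centers = x,
                      population = y, m = 0.3, n_frames = 1,
                      truncated_fraction = 0),
                 class = "distance_histogram")
  fit <- fit_double_gaussian(h)
  expect_equal(fit$mean1, 0.28, tolerance = 1e-3)
  expect_equal(fit$mean2, 0.56, tolerance = 1e-3)
  expect_equal(fit$amp1, 60, tolerance = 1e-2)
  expect_false(fit$degenerate)
  expect_lt(fit$rss, 1e-8)
  # permuted initial means give the identical ordered answer
  fit_perm <- fit_double_gaussian(h, init = list(mean1 = 0.6, mean2 = 0.25,
                                                 amp1 = 20, amp2 = 50))
  expect_equal(fit_perm$mean1, fit$mean1, tolerance = 1e-6)
  expect_equal(fit_perm$mean2, fit$mean2, tolerance = 1e-6)
  # single-peak data flags a degenerate second component
  y1 <- truth$amp1 * exp(-(x - 0.28)^2 / (2 * 0.05^2))
  h1 <- h; h1$population <- y1
  fit1 <- fit_double_gaussian(h1)
  expect_equal(fit1$mean1, 0.28, tolerance = 5e-3)
  expect_true(fit1$degenerate)
  # too few informative bins
  h_thin <- h; h_thin$population <- c(1, 2, 3, rep(0, length(x) - 3))
  expect_error(fit_double_gaussian(h_thin), "6 nonzero")
})

test_that("layer assignment splits at the 4.5 and 20 Angstrom cutoffs", {
  part <- assign_layers(c(0.28, 0.56, 2.5))
  expect_equal(part$n_w1, 1)   # first-shell peak distance
  expect_equal(part$n_w2, 1)   # second-shell peak distance
  expect_equal(part$n_beyond, 1)
  # boundary is half-open: d == cutoff_12 belongs to layer 2
  part_b <- assign_layers(c(0.45))
  expect_equal(part_b$n_w1, 0)
  expect_equal(part_b$n_w2, 1)
  expect_error(assign_layers(0.3, cutoff_12 = 2, cutoff_2end = 1),
               "cutoff")
})

test_that("layer volume fractions close to one and reject unphysical input", {
  fr <- layer_volume_fractions(list(n_w1 = 100, n_w2 = 0), box_volume = 125)
  expect_equal(fr[["f_w1"]], 100 * 0.0299 / 125)
  expect_equal(fr[["f_w1"]], 0.02392)
  expect_equal(sum(fr), 1)
  fr0 <- layer_volume_fractions(list(n_w1 = 0, n_w2 = 0), box_volume = 125)
  expect_equal(unname(fr0), c(1, 0, 0))
  withr::with_seed(8, {
    for (i in 1:10) {
      fr_i <- layer_volume_fractions(list(n_w1 = runif(1, 0, 500),
                                          n_w2 = runif(1, 0, 500)),
                                     box_volume = 125)
      expect_equal(sum(fr_i), 1)
    }
  })
  expect_error(layer_volume_fractions(list(n_w1 = 1e6, n_w2 = 0), 125),
               "exceeds")
  expect_error(layer_volume_fractions(list(n_w1 = 1, n_w2 = 1), 0), "> 0")
})

test_that("layer counts are invariant under rigid translation", {
  cfg <- suppressWarnings(
    generate_hydrated_configuration(tiny_polymer(), 0.15, seed = 6))
  d0 <- polymer_water_distances(cfg)
  shifted <- cfg$atoms
  shifted[, c("x", "y", "z")] <-
    shifted[, c("x", "y", "z")] + rep(c(1.7, 0.4, -2.2), each = nrow(shifted))
  cfg_s <- configuration(shifted, cfg$box)
  d1 <- polymer_water_distances(cfg_s)
  expect_equal(d1, d0, tolerance = 1e-9)
  p0 <- assign_layers(d0); p1 <- assign_layers(d1)
  expect_equal(p1$n_w1, p0$n_w1)
  expect_equal(p1$n_w2, p0$n_w2)
})

test_that("histogram mass matches the per-frame water count up to truncation", {
  cfg <- suppressWarnings(
    generate_hydrated_configuration(tiny_polymer(), 0.25, seed = 13))
  d <- polymer_water_distances(cfg)
  h <- population_histogram(d, bin_width = 0.01, d_max = 2)
  n_w <- sum(cfg$atoms$role == "water_O")
  expect_equal(sum(h$population) + h$truncated_fraction * n_w, n_w,
               tolerance = 1e-9)
})
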