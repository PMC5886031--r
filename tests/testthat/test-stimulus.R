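# Dot kinematics: displacement conversion, field initialisation,
# wrap-around, per-update resampling, interval generation, rasterisation.

test_that("speed converts to per-update displacement exactly", {
  expect_equal(speed_to_displacement(31.25, 18.75), 5 / 3, tolerance = 1e-12)
  expect_equal(deg_to_arcmin(speed_to_displacement(31.25, 18.75)), 100,
               tolerance = 1e-9)
  expect_identical(speed_to_displacement(0, 18.75), 0)
  expect_equal(speed_to_displacement(18.75, 18.75), 1)
  expect_error(speed_to_displacement(-1), "negative")
})

test_that("dot fields start inside the aperture, uniformly over area", {
  spec <- stimulus_spec()
  f <- init_dot_field(spec, seed = 5)
  expect_length(f$x, 226)
  r <- sqrt(f$x^2 + f$y^2)
  expect_true(all(r <= 6))
  # area-uniform: r^2 / R^2 should be U(0,1), so its mean is ~1/2
  expect_gt(mean(r^2) / 36, 0.4)
  expect_lt(mean(r^2) / 36, 0.6)
  expect_identical(init_dot_field(spec, seed = 5), f)  # determinism
  f1 <- init_dot_field(stimulus_spec(n_dots = 1, dot_density = NULL), seed = 2)
  expect_length(f1$x, 1)
})

test_that("default spec matches the configured geometry and timing", {
  spec <- stimulus_spec()
  expect_equal(spec$n_dots / (pi * (spec$aperture_diameter / 2)^2), 2,
               tolerance = 0.01 * 2)
  expect_equal(spec$monitor_refresh / spec$update_rate, 4)
  expect_error(stimulus_spec(n_dots = 10), "dots/deg")
  expect_warning(stimulus_spec(update_rate = 17, dot_density = NULL), "divide")
})

test_that("wrapping reflects exiting dots to the opposite side, inside the rim", {
  w <- wrap_position(6.2, 0, 6)
  expect_lt(w$x, 0)                       # re-entry on the opposite side
  expect_lte(sqrt(w$x^2 + w$y^2), 6)
  expect_equal(w$x, -6, tolerance = 1e-6)
  inside <- wrap_position(c(1, -2), c(2, 1), 6)
  expect_identical(inside, list(x = c(1, -2), y = c(2, 1)))  # identity inside
  set.seed(9)
  px <- stats::runif(500, -12, 12); py <- stats::runif(500, -12, 12)
  ww <- wrap_position(px, py, 6)
  expect_true(all(sqrt(ww$x^2 + ww$y^2) <= 6))
})

test_that("advance resamples speeds per dot per update and keeps dots inside", {
  spec <- stimulus_spec()
  src <- build_uniform(0.4, 23.6, 1)
  set.seed(31)
  f <- init_dot_field(spec)
  draws <- c()
  for (i in 1:10) {
    f <- advance(f, src, 90, spec)
    expect_true(all(sqrt(f$x^2 + f$y^2) <= 6))
    draws <- c(draws, f$current_speeds)
  }
  # draws follow the source distribution (chi-squared on 2260 samples)
  obs <- table(factor(draws, levels = src$support))
  p <- suppressWarnings(stats::chisq.test(obs, p = src$probabilities))$p.value
  expect_gt(p, 0.001)
  # degenerate one-point distribution behaves as a fixed speed
  one <- discrete_distribution(5, 1, kind = "speed")
  f2 <- advance(init_dot_field(spec, seed = 1), one, 0, spec)
  expect_true(all(f2$current_speeds == 5))
  expect_error(advance(f2, src, build_direction_gapped(58, 30, 0, 1), spec),
               "only one of")
  expect_error(advance(f2, build_direction_gapped(58, 30, 0, 1), 90, spec), "kind")
})

test_that("intervals have the full frame count and are seed-reproducible", {
  spec <- stimulus_spec()
  src <- build_uniform(0.4, 23.6, 1)
  a <- generate_interval(spec, src, 90, seed = 7)
  expect_equal(dim(a$x), c(10, 226))
  expect_equal(dim(a$speeds), c(9, 226))
  b <- generate_interval(spec, src, 90, seed = 7)
  expect_identical(a$x, b$x)              # bit-identical trajectories
  expect_identical(a$speeds, b$speeds)
  c_ <- generate_interval(spec, src, 90, seed = 8)
  expect_false(identical(a$speeds, c_$speeds))
  # fast standard never approaches the displacement limit
  fast <- build_uniform(17.2, 24, 0.4)
  s <- generate_interval(spec, fast, 0, seed = 3)
  expect_lte(max(s$speeds), 24)
  expect_lt(max(s$speeds), 31.25)
  # draws-only mode produces the same shapes without positions
  s2 <- generate_interval(spec, src, 90, seed = 7, positions = FALSE)
  expect_null(s2$x)
  expect_equal(dim(s2$speeds), c(9, 226))
})

test_that("rasterisation draws dark disks of the expected area", {
  spec <- stimulus_spec(n_dots = 1, dot_density = NULL)
  ppd <- 44.4
  f <- structure(list(x = 0, y = 0, current_speeds = NA, current_directions = NA),
                 class = "dot_field")
  img <- rasterize(f, ppd, spec)
  dark <- sum(img < spec$background_luminance)
  expected <- pi * (0.05 * ppd)^2
  expect_gt(dark, expected - 2 * pi * 0.05 * ppd - 2)   # +/- one pixel ring
  expect_lt(dark, expected + 2 * pi * 0.05 * ppd + 2)
  empty <- structure(list(x = numeric(0), y = numeric(0)), class = "dot_field")
  expect_true(all(rasterize(empty, ppd, spec) == spec$background_luminance))
})

test_that("trajectory CSVs round-trip with documented units", {
  spec <- stimulus_spec(n_dots = 3, dot_density = NULL)
  s <- generate_interval(spec, build_uniform(1.2, 8, 0.4), 45, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(s, path, trial_id = 7, interval_index = 2)
  df <- read_trajectory_csv(path)
  expect_equal(nrow(df), 30)              # 3 dots x 10 updates
  expect_equal(unique(df$trial_id), 7)
  expect_equal(df$x_deg[df$dot_id == 2 & df$update_index == 1], s$x[1, 2])
  expect_true(all(is.na(df$speed_deg_per_s[df$update_index == 10])))
})
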