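# Mean-targeted, bandwidth, constant-distance, and directional-gap
# constructions, checked against brute-force expectations.

test_that("mean-targeted bands preserve the configured widths and hit targets", {
  # lambda = 0 reference: uniform bands give the natural mean distance
  d0 <- build_mean_targeted_notched(15.1, interval = 1)
  expect_equal(d0$tilt$lambda, c(0, 0))
  expect_equal(moments(d0)$band_means, c(4.45, 19.55), tolerance = 1e-9)
  expect_equal(moments(d0)$mean_distance, 15.1, tolerance = 1e-9)
  for (dd in c(13, 14, 15, 16, 17)) {
    d <- build_mean_targeted_notched(dd)
    m <- moments(d)
    expect_equal(m$band_means, 12 + c(-1, 1) * dd / 2, tolerance = 1e-6)
    expect_equal(m$global_mean, 12, tolerance = 1e-6)
    expect_equal(m$span, 2 * 8.1 + 7, tolerance = 1e-12)
    expect_equal(m$notch_width, 7, tolerance = 1e-12)
    # band endpoints anchored at range ends AND notch edges
    expect_equal(range(d$support[d$support < 12]), c(0.4, 8.5))
    expect_equal(range(d$support[d$support > 12]), c(15.5, 23.6))
    expect_equal(brute_band_means(d), m$band_means, tolerance = 1e-6)
  }
  expect_error(build_mean_targeted_notched(40), "infeasible")
})

test_that("bandwidth family shares span and mean between standard and comparison", {
  for (bw in c(8, 11, 14, 17, 20)) {
    fam <- build_bandwidth_family(bw, 7, 12, 0.2)
    expect_true(validate_matched(fam$standard, fam$comparison)$pass)
    ms <- moments(fam$standard); mc <- moments(fam$comparison)
    expect_equal(ms$span, bw, tolerance = 1e-12)
    expect_equal(ms$global_mean, 12, tolerance = 1e-9)
    expect_equal(mc$global_mean, 12, tolerance = 1e-9)
    expect_equal(mc$notch_width, 7, tolerance = 1e-12)
  }
  f20 <- build_bandwidth_family(20, 7, 12, 1)
  expect_equal(range(f20$standard$support), c(2, 22))
  expect_equal(max(f20$comparison$support[f20$comparison$support < 12]), 8.5,
               tolerance = 1e-9)
  expect_error(build_bandwidth_family(7, 7, 12, 1), "empty bands")
})

test_that("constant-distance construction is invariant to notch width", {
  for (rng in list(c(1.2, 8), c(17.2, 24))) {
    dists <- lapply(c(1.2, 2, 3.6, 5.2), function(w) {
      build_constant_distance_notched(rng[1], rng[2], w, 6, 0.4)
    })
    mds <- vapply(dists, function(d) moments(d)$mean_distance, 0)
    gms <- vapply(dists, function(d) moments(d)$global_mean, 0)
    expect_true(max(mds) - min(mds) < 1e-6)
    expect_equal(mds[1], 6, tolerance = 1e-6)
    expect_equal(gms, rep(mean(rng), 4), tolerance = 1e-6)
    for (d in dists) {
      expect_equal(brute_band_means(d), moments(d)$band_means, tolerance = 1e-6)
    }
  }
  expect_equal(moments(build_constant_distance_notched(17.2, 24, 2, 6, 0.4))$global_mean,
               20.6, tolerance = 1e-9)
  expect_error(build_constant_distance_notched(1.2, 8, 5.2, 7, 0.4), "infeasible")
  expect_error(build_constant_distance_notched(1.2, 8, 4, 3, 0.4), "infeasible")
})

test_that("directional gaps keep the 30-deg mean and the full span", {
  std <- build_direction_gapped(58, 30, 0, 1)
  expect_identical(std$kind, "direction")
  expect_equal(std$support, 1:59)
  expect_equal(moments(std)$global_mean, 30, tolerance = 1e-9)
  d50 <- build_direction_gapped(58, 30, 50, 1)
  expect_equal(d50$support, c(1:5, 55:59))
  expect_equal(moments(d50)$global_mean, 30, tolerance = 1e-9)
  for (g in c(2, 10, 18, 26, 34, 42, 50)) {
    d <- build_direction_gapped(58, 30, g, 1)
    expect_true(validate_matched(std, d)$pass)
    expect_equal(moments(d)$span, 58, tolerance = 1e-12)
  }
  expect_error(build_direction_gapped(58, 30, 58, 1), "smaller than the span")
})

test_that("every construction has unit mass and an empty notch interior", {
  dists <- c(
    lapply(c(1, 4, 7, 10, 13, 16, 19), build_symmetric_notched,
           range_lo = 0.4, range_hi = 23.6, interval = 1),
    lapply(c(13, 17), build_mean_targeted_notched),
    lapply(c(1.2, 5.2), build_constant_distance_notched,
           range_lo = 1.2, range_hi = 8, mean_distance = 6, interval = 0.4),
    lapply(c(2, 50), build_direction_gapped, span = 58, mean_dir = 30, interval = 1))
  for (d in dists) {
    expect_equal(sum(d$probabilities), 1, tolerance = 1e-9)
    expect_true(all(d$probabilities >= 0))
    inside <- d$support > d$notch[1] + 1e-9 & d$support < d$notch[2] - 1e-9
    expect_false(any(inside))   # exhaustive scan of the support
  }
})
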