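test_that("noiseless crossing recovers the whale to within a metre", {
  tr <- dogleg_track()
  whale <- c(2.0, 10)  # 2 km starboard of the first leg
  b <- bearings_to(tr, whale, seq(40, 120, by = 5))
  fx <- cross_bearings(tr, b)
  expect_equal(fx$chosen_side, "starboard")
  expect_lt(sqrt(sum((fx$position - whale)^2)), 1e-3)
  expect_gt(fx$residual_port, fx$residual_starboard)
})

test_that("mirror whales swap side but keep the perpendicular distance", {
  tr <- dogleg_track()
  leg1 <- rbind(c(0, 0), c(0, 20))
  # whale abeam of the course change; bearings span both legs around the
  # closest point of approach, where the mirror ambiguity stays coherent
  idx <- seq(30, 150, by = 6)
  fx1 <- cross_bearings(tr, bearings_to(tr, c(2.5, 19), idx), segment = leg1)
  fx2 <- cross_bearings(tr, bearings_to(tr, c(-2.5, 19), idx), segment = leg1)
  expect_equal(fx1$chosen_side, "starboard")
  expect_equal(fx2$chosen_side, "port")
  expect_lt(abs(fx1$perp_distance_km - fx2$perp_distance_km), 1e-3)
})

test_that("noisy bearings localize a 3-km whale to better than 150 m", {
  tr <- straight_track()
  set.seed(99)
  errs <- replicate(200, {
    yw <- 30; xw <- 3
    yv <- yw + seq(-3 * tan(pi / 6), 3 * tan(pi / 6),
                   length.out = 20)  # 60-degree aperture
    idx <- vapply(yv, function(y) which.min(abs(tr$y_km - y)), integer(1))
    b <- bearings_to(tr, c(xw, yw), idx, noise_deg = 2)
    fx <- cross_bearings(tr, b)
    abs(fx$perp_distance_km - xw)
  })
  expect_lt(median(errs), 0.15)
})

test_that("localization error shrinks with bearing aperture", {
  tr <- straight_track()
  med_err <- vapply(c(20, 50, 90), function(ap) {
    set.seed(ap)
    half <- 3 * tan(ap / 2 * pi / 180)
    median(replicate(150, {
      yv <- 30 + seq(-half, half, length.out = 15)
      idx <- vapply(yv, function(y) which.min(abs(tr$y_km - y)), integer(1))
      fx <- cross_bearings(tr, bearings_to(tr, c(3, 30), idx, noise_deg = 2),
                           min_aperture_deg = 5)
      abs(fx$perp_distance_km - 3)
    }))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("degenerate geometry is refused", {
  tr <- straight_track()
  b <- data.frame(t_s = c(0, 600, 1200), bearing_deg = c(45, 45.1, 45.2))
  expect_error(cross_bearings(tr, b[1, ]), "at least 2")
  expect_error(cross_bearings(tr, b, min_aperture_deg = 15), "aperture")
  bpar <- data.frame(t_s = c(0, 1), bearing_deg = c(45, 45))
  expect_error(cross_bearings(tr, bpar, min_aperture_deg = 0), "parallel")
})

test_that("perpendicular distance matches trivial and dense-sampling oracles", {
  seg <- rbind(c(-5, 0), c(5, 0))
  expect_equal(perpendicular_distance(c(2, 0), seg), 0)
  expect_equal(perpendicular_distance(c(0, 3), seg), 3)
  expect_error(perpendicular_distance(c(1, 1), rbind(c(0, 0), c(0, 0))),
               "zero-length")
  set.seed(21)
  for (i in 1:5) {
    p <- runif(2, -4, 4)
    sg <- matrix(runif(4, -3, 3), 2, 2)
    expect_equal(perpendicular_distance(p, sg), dense_perp(p, sg),
                 tolerance = 1e-6)
  }
})

test_that("perpendicular distance is rigid-motion invariant", {
  set.seed(22)
  for (i in 1:10) {
    p <- runif(2, -4, 4); sg <- matrix(runif(4, -3, 3), 2, 2)
    th <- runif(1, 0, 2 * pi); shift <- runif(2, -10, 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pr <- drop(R %*% p) + shift
    sgr <- t(apply(sg, 1, function(r) drop(R %*% r) + shift))
    expect_equal(perpendicular_distance(pr, sgr),
                 perpendicular_distance(p, sg), tolerance = 1e-9)
  }
})

test_that("surfacing-assumption bias follows the slant-range formula", {
  expect_equal(surface_assumption_bias(0, 4), 0)
  expect_equal(surface_assumption_bias(600, 4), sqrt(16.36) / 4 - 1,
               tolerance = 1e-12)
  x <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(surface_assumption_bias(600, x)) < 0))
})
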