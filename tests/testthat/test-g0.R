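test_that("an always-vocal whale field gives g(0) = 1 exactly", {
  g0 <- simulate_g0(list(t_e = rep(34, 50), t_ne = rep(0, 50)),
                    eshw_km = 4.168, speed_kmh = 11.8, n_runs = 50,
                    seed = 1)
  expect_identical(g0$g0_mean, 1)
})

test_that("silent phases shorter than the window cannot be missed", {
  set.seed(2)
  src <- list(t_e = rexp(500, 1 / 34), t_ne = runif(500, 1, 5))
  g0 <- simulate_g0(src, eshw_km = 4.168, speed_kmh = 11.8, n_runs = 100,
                    seed = 3)
  expect_gt(g0$window_min, max(src$t_ne))
  expect_identical(g0$g0_mean, 1)
})

test_that("zero echolocation mass warns and returns g(0) = 0", {
  expect_warning(
    g0 <- simulate_g0(list(t_e = rep(0, 10), t_ne = rep(24, 10)),
                      eshw_km = 4, speed_kmh = 12, n_runs = 10, seed = 1),
    "zero echolocation")
  expect_identical(g0$g0_mean, 0)
})

test_that("per-run estimates are proportions and sd is their spread", {
  g0 <- simulate_g0(phase_spec(), 4.168, 11.8, n_runs = 300, seed = 4)
  expect_true(all(g0$per_run >= 0 & g0$per_run <= 1))
  expect_equal(g0$g0_sd, sd(g0$per_run))
  expect_equal(g0$window_min, 2 * 4.168 / 11.8 * 60)
})

test_that("analytic exponential-phase g(0) behaves at its limits", {
  expect_equal(analytic_g0_exponential(34, 0, 10), 1)
  expect_equal(analytic_g0_exponential(34, 24, 0), 34 / 58)
  expect_equal(analytic_g0_exponential(34, 24, 42.4),
               1 - (24 / 58) * exp(-42.4 / 24), tolerance = 1e-12)
  expect_equal(round(analytic_g0_exponential(34, 24, 42.4), 3), 0.929)
})

test_that("interval-overlap detection agrees with a 1-s time stepper", {
  # same stationary starting state and phase stream, two detection rules:
  # the package's residual test vs brute-force rasterisation
  set.seed(5)
  m_e <- 20; m_ne <- 15
  for (run in 1:10) {
    window <- runif(1, 10, 60)
    n_wh <- 40
    p_avail <- m_e / (m_e + m_ne)
    pkg <- brute <- logical(n_wh)
    for (i in seq_len(n_wh)) {
      start_echo <- runif(1) < p_avail
      # length-biased current phase, uniform elapsed fraction
      d <- if (start_echo) rgamma(1, 2, 1 / m_e) else rgamma(1, 2, 1 / m_ne)
      resid <- d * runif(1)
      pkg[i] <- start_echo || resid < window
      brute[i] <- brute_force_detect(start_echo, resid, window,
                                     function(n) rexp(n, 1 / m_e),
                                     function(n) rexp(n, 1 / m_ne))
    }
    expect_lte(abs(sum(pkg) - sum(brute)), 1)
  }
})

test_that("simulation matches the exponential-phase closed form", {
  set.seed(6)
  src <- list(t_e = rexp(1e6, 1 / 34), t_ne = rexp(1e6, 1 / 24))
  g0 <- simulate_g0(src, eshw_km = 4.168, speed_kmh = 11.8,
                    n_runs = 2000, seed = 5)
  oracle <- analytic_g0_exponential(34, 24, g0$window_min)
  mc_se <- g0$g0_sd / sqrt(g0$n_runs)
  expect_lt(abs(g0$g0_mean - oracle), 3 * mc_se)
})

test_that("g(0) grid is monotone in strip width and speed", {
  gr <- g0_grid(phase_spec(), eshw_list = c(2, 4, 6),
                speed_list = c(8, 12, 16), n_runs = 400, seed = 3)
  expect_true(gr$mono_eshw)
  expect_true(gr$mono_speed)
  # wider strip raises availability; higher speed lowers it (2 MC se slack)
  expect_gt(gr$mean[3, 1] + 2 * gr$se[3, 1],
            gr$mean[1, 1] - 2 * gr$se[1, 1])
  expect_gt(gr$mean[1, 1] + 2 * gr$se[1, 1],
            gr$mean[1, 3] - 2 * gr$se[1, 3])
})

test_that("a grid cell reproduces a standalone run under the same seed", {
  ps <- phase_spec()
  gr <- g0_grid(ps, eshw_list = c(3, 4.168), speed_list = c(11.8),
                n_runs = 200, seed = 40)
  solo <- simulate_g0(ps, 4.168, 11.8, n_runs = 200, seed = 41)
  expect_equal(gr$mean[2, 1], solo$g0_mean)
})

test_that("empirical tag-derived phases drive the simulation directly", {
  ts <- generate_tag_series(tag_sim_config(n_cycles = 40, seed = 7))
  ps <- extract_phase_durations(segment_dive_cycles(ts))
  g0 <- simulate_g0(ps, 4.168, 11.8, n_runs = 200, seed = 8)
  expect_true(g0$g0_mean > 0.5 && g0$g0_mean <= 1)
})
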