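test_that("a record never crossing the dive threshold yields no cycles", {
  s <- data.frame(t_s = 0:99, depth_m = 0, clicking = 0L)
  expect_equal(nrow(segment_dive_cycles(s)), 0)
})

test_that("segmentation recovers the generator's phase durations exactly", {
  for (seed in c(11, 12, 13)) {
    ts <- generate_tag_series(tag_sim_config(n_cycles = 13, seed = seed))
    cy <- segment_dive_cycles(ts)
    expect_equal(nrow(cy), 13)
    expect_equal(sum(cy$complete), 12)
    ps <- extract_phase_durations(cy)
    dt_min <- 5 / 60
    expect_equal(length(ps$t_e), 11)  # first and incomplete last dropped
    expect_lt(max(abs(ps$t_e - ts$truth$t_e_min[2:12])), dt_min)
    expect_lt(max(abs(ps$t_ne - ts$truth$t_ne_min[2:11])), dt_min)
  }
})

test_that("a dive without clicking is kept but flagged for exclusion", {
  # two clicking dives bracketing one silent dive, built by hand
  mk_dive <- function(t0, click) {
    t <- seq(t0, t0 + 1800, by = 10)
    depth <- 500 * sin(pi * (t - t0) / 1800)
    clicking <- as.integer(click & depth > 400)
    data.frame(t_s = t, depth_m = depth, clicking = clicking)
  }
  surf <- function(t0) data.frame(t_s = seq(t0, t0 + 590, by = 10),
                                  depth_m = 0, clicking = 0L)
  s <- rbind(mk_dive(0, TRUE), surf(1810), mk_dive(2410, FALSE),
             surf(4220), mk_dive(4820, TRUE), surf(6630))
  s <- s[!duplicated(s$t_s), ]
  cy <- segment_dive_cycles(s)
  expect_equal(nrow(cy), 3)
  expect_equal(cy$has_echo, c(TRUE, FALSE, TRUE))
  ps <- extract_phase_durations(cy, exclude_first = FALSE,
                                require_complete = FALSE)
  expect_equal(length(ps$t_e), 2)  # silent dive contributes no t_e
})

test_that("the silent duration spans ascent + IDI + next descent", {
  # two rectangular dives with hand-computed phase boundaries
  tvals <- seq(0, 7200, by = 5)
  depth <- numeric(length(tvals)); click <- integer(length(tvals))
  # dive 1: 100-2000 s deep, clicking 400-1600 s
  depth[tvals >= 100 & tvals <= 2000] <- 600
  click[tvals >= 400 & tvals <= 1600] <- 1L
  # dive 2: 3000-5000 s deep, clicking 3500-4800 s
  depth[tvals >= 3000 & tvals <= 5000] <- 600
  click[tvals >= 3500 & tvals <= 4800] <- 1L
  s <- data.frame(t_s = tvals, depth_m = depth, clicking = click)
  cy <- segment_dive_cycles(s)
  ps <- extract_phase_durations(cy, exclude_first = FALSE,
                                require_complete = FALSE)
  expect_equal(ps$t_e, c(1200, 1300) / 60)
  expect_equal(ps$t_ne, (3500 - 1600) / 60)  # ascent + surface + descent
})

test_that("too few usable cycles is an error", {
  ts <- generate_tag_series(tag_sim_config(n_cycles = 2, seed = 5))
  cy <- segment_dive_cycles(ts)
  expect_error(extract_phase_durations(cy), "usable")
})

test_that("phase histograms are normalised 1-min bins", {
  one <- phase_duration_set(5.5, 5.5)
  h <- phase_histograms(one)
  expect_equal(h$echo$p[h$echo$bin_lo == 5], 1)
  expect_equal(sum(h$echo$p), 1)

  set.seed(6)
  ps <- phase_spec()
  big <- phase_duration_set(ps$r_e(10000), ps$r_ne(10000))
  h <- phase_histograms(big)
  hist_mean <- sum((h$echo$bin_lo + 0.5) * h$echo$p)
  expect_equal(hist_mean, mean(big$t_e), tolerance = 0.02)
  expect_equal(sum(h$silent$p), 1)
  expect_error(phase_duration_set(numeric(0), 1), "non-empty")
})

test_that("time budget is the pooled echolocating fraction", {
  expect_equal(time_budget(phase_duration_set(30, 30)), 0.5)
  set.seed(7)
  ps <- phase_spec()
  big <- phase_duration_set(ps$r_e(50000), ps$r_ne(50000))
  expect_equal(time_budget(big), 34.2 / (34.2 + 23.5), tolerance = 0.02)
})

test_that("phase CSV round-trips", {
  set.seed(8)
  ps <- phase_spec()
  set1 <- phase_duration_set(ps$r_e(20), ps$r_ne(19))
  p <- tempfile(fileext = ".csv")
  write_phase_csv(set1, p)
  set2 <- read_phase_csv(p)
  expect_equal(set2$t_e, set1$t_e)
  expect_equal(set2$t_ne, set1$t_ne)
})
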