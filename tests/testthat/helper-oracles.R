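# Shared fixtures and independent oracles, built in code at test time.

# straight northbound track: heading 0, along +y at speed_kmh
straight_track <- function(length_km = 60, speed_kmh = 11.8, n = 121) {
  data.frame(t_s = seq(0, length_km / speed_kmh * 3600, length.out = n),
             x_km = 0, y_km = seq(0, length_km, length.out = n),
             heading_deg = 0)
}

# track with a gentle course change at mid-track; heading varies so the
# port/starboard mirror solutions are no longer symmetric
dogleg_track <- function(length_km = 40, turn_deg = 20, speed_kmh = 11.8) {
  half <- length_km / 2
  s <- seq(0, length_km, length.out = 161)
  th <- ifelse(s <= half, 0, turn_deg) * pi / 180
  x <- ifelse(s <= half, 0, (s - half) * sin(th))
  y <- ifelse(s <= half, s, half + (s - half) * cos(th))
  data.frame(t_s = s / speed_kmh * 3600, x_km = x, y_km = y,
             heading_deg = ifelse(s <= half, 0, turn_deg))
}

# noiseless (or noisy) unsigned bearings from track rows `idx` to a whale
bearings_to <- function(track, whale_xy, idx, noise_deg = 0) {
  dx <- whale_xy[1] - track$x_km[idx]
  dy <- whale_xy[2] - track$y_km[idx]
  phi <- atan2(dx, dy) * 180 / pi            # compass angle of the LOS
  rel <- abs(((phi - track$heading_deg[idx] + 180) %% 360) - 180)
  if (noise_deg > 0) rel <- pmin(pmax(rel + rnorm(length(idx), 0, noise_deg),
                                      0), 180)
  data.frame(t_s = track$t_s[idx], bearing_deg = rel)
}

# 1-second time-stepped brute-force availability check: given the initial
# state, the residual time of the current phase and samplers for the
# following phases, rasterise the alternating sequence over the window and
# report whether any echolocating second falls inside it
brute_force_detect <- function(start_echo, resid_min, window_min,
                               r_e, r_ne) {
  durs <- resid_min
  states <- start_echo
  while (sum(durs) < window_min) {          # extend timeline past window
    states <- c(states, !states[length(states)])
    durs <- c(durs, if (states[length(states)]) r_e(1) else r_ne(1))
  }
  ends <- cumsum(durs) * 60
  tgrid <- seq(0, window_min * 60, by = 1)  # 1-s raster
  idx <- pmin(findInterval(tgrid, c(0, ends)), length(states))
  any(states[idx])
}

# dense-sampling oracle for point-to-line distance
dense_perp <- function(point, segment, n = 200001) {
  s <- seq(-2, 3, length.out = n)
  px <- segment[1, 1] + s * (segment[2, 1] - segment[1, 1])
  py <- segment[1, 2] + s * (segment[2, 2] - segment[1, 2])
  sqrt(min((point[1] - px)^2 + (point[2] - py)^2))
}
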