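# Resolve a phase_source into duration pools (minutes). Accepts an
# empirical phase_duration_set, a parametric phase_spec, or a plain list
# with elements t_e/t_ne (vectors) or r_e/r_ne (sampling functions).
phase_pools <- function(phase_source, pool_n) {
  if (inherits(phase_source, "phase_duration_set"))
    return(list(t_e = phase_source$t_e, t_ne = phase_source$t_ne))
  if (inherits(phase_source, "phase_spec"))
    return(list(t_e = phase_source$r_e(pool_n),
                t_ne = phase_source$r_ne(pool_n)))
  if (is.list(phase_source)) {
    if (!is.null(phase_source$t_e) && !is.null(phase_source$t_ne))
      return(list(t_e = phase_source$t_e, t_ne = phase_source$t_ne))
    if (is.function(phase_source$r_e) && is.function(phase_source$r_ne))
      return(list(t_e = phase_source$r_e(pool_n),
                  t_ne = phase_source$r_ne(pool_n)))
  }
  stop("phase_source must be a phase_duration_set, a phase_spec, or a list ",
       "with t_e/t_ne vectors or r_e/r_ne sampling functions")
}

#' Monte Carlo estimate of track-line detection probability g(0)
#'
#' Estimates the probability that a whale on the transect line is
#' acoustically available (echolocating) at least once while within
#' detection range of the passing vessel. Each run draws a track length L
#' (uniform on \code{L_range_km}) and a whale count N (uniform integer on
#' \code{N_range}), places stationary whales uniformly on the line, and
#' gives each whale an independent stationary alternating renewal process
#' of echolocating / silent phases drawn from \code{phase_source}. A whale
#' within range for a time window T = 2 ESHW / speed is detected unless it
#' is silent at window entry with residual silent time at least T: the
#' event-driven interval-overlap condition collapses to this single test,
#' because a silent phase is always followed by an echolocation phase.
#' The run estimate is n / N; the mean and across-run sd over
#' \code{n_runs} runs are returned.
#'
#' Stationary initialisation: each whale starts in the echolocating state
#' with probability m_e / (m_e + m_ne); its current phase duration is
#' drawn length-biased and the elapsed fraction uniformly, the
#' equilibrium state of the alternating renewal process. Length-biased
#' draws use a duration-weighted resample of the phase pool (exact for an
#' empirical pool; for parametric sources a pool of \code{pool_n} draws is
#' materialised first).
#'
#' @param phase_source a \code{\link{phase_duration_set}},
#'   \code{\link{phase_spec}}, or list with \code{t_e}/\code{t_ne} vectors
#'   or \code{r_e}/\code{r_ne} sampling functions (durations in minutes).
#' @param eshw_km effective strip half-width (km), the detection range
#'   ahead and behind the vessel.
#' @param speed_kmh survey speed (km/h).
#' @param n_runs number of simulation runs.
#' @param L_range_km range of per-run track lengths (km).
#' @param N_range integer range of per-run whale counts.
#' @param pool_n pool size materialised from parametric sources.
#' @param seed optional integer seed.
#' @return object of class \code{"g0_estimate"}: \code{g0_mean},
#'   \code{g0_sd} (sd of per-run n/N), \code{per_run}, \code{window_min}
#'   (= 2 eshw / speed, in minutes), plus the settings.
#' @examples
#' g0 <- simulate_g0(phase_spec(), eshw_km = 4.168, speed_kmh = 11.8,
#'                   n_runs = 200, seed = 1)
#' g0
#' @export
simulate_g0 <- function(phase_source, eshw_km, speed_kmh, n_runs = 2000,
                        L_range_km = c(100, 1000), N_range = c(1, 300),
                        pool_n = 20000, seed = NULL) {
  if (eshw_km <= 0 || speed_kmh <= 0) stop("eshw and speed must be positive")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pools <- phase_pools(phase_source, pool_n)
  if (any(pools$t_e < 0) || any(pools$t_ne < 0))
    stop("phase durations must be non-negative")
  window_min <- 2 * eshw_km / speed_kmh * 60

  m_e <- mean(pools$t_e)
  m_ne <- mean(pools$t_ne)
  if (m_e == 0) {
    warning("phase source has zero echolocation mass; g(0) = 0")
    return(structure(list(g0_mean = 0, g0_sd = 0,
                          per_run = rep(0, n_runs),
                          window_min = window_min, n_runs = n_runs,
                          eshw_km = eshw_km, speed_kmh = speed_kmh),
                     class = "g0_estimate"))
  }
  p_avail <- m_e / (m_e + m_ne)

  L <- stats::runif(n_runs, L_range_km[1], L_range_km[2])
  N <- sample(N_range[1]:N_range[2], n_runs, replace = TRUE)
  run_id <- rep(seq_len(n_runs), N)
  total <- length(run_id)
  pos <- stats::runif(total) * L[run_id]  # placement; detection window is
  # the same for every whale on the line, so positions are bookkeeping only

  in_echo <- stats::runif(total) < p_avail
  detected <- in_echo
  ns <- which(!in_echo)
  if (length(ns) > 0) {
    if (m_ne == 0) {
      detected[ns] <- TRUE
    } else {
      d <- sample(pools$t_ne, length(ns), replace = TRUE, prob = pools$t_ne)
      resid <- d * stats::runif(length(ns))
      detected[ns] <- resid < window_min
    }
  }
  n_det <- as.vector(rowsum(as.integer(detected), run_id))
  per_run <- n_det / N
  structure(list(g0_mean = mean(per_run), g0_sd = stats::sd(per_run),
                 per_run = per_run, window_min = window_min,
                 n_runs = n_runs, eshw_km = eshw_km, speed_kmh = speed_kmh,
                 positions = pos),
            class = "g0_estimate")
}

#' @export
print.g0_estimate <- function(x, ...) {
  cat(sprintf(
    "g(0) = %.3f (sd %.3f) over %d runs; detection window %.1f min\n",
    x$g0_mean, x$g0_sd, x$n_runs, x$window_min))
  invisible(x)
}

#' Closed-form g(0) for exponential phase durations
#'
#' For a stationary alternating renewal process with exponential silent
#' phases (mean \code{m_ne_min}) and any echolocating phases (mean
#' \code{m_e_min}), a whale is missed exactly when it is silent at window
#' entry and its (memoryless) residual silent time exceeds the window:
#' g(0) = 1 - (m_ne / (m_e + m_ne)) exp(-window / m_ne). Serves as an
#' independent oracle for \code{\link{simulate_g0}}.
#'
#' @param m_e_min,m_ne_min mean phase durations (min), > 0.
#' @param window_min detection time window (min).
#' @return probability in [0, 1].
#' @examples
#' analytic_g0_exponential(34, 24, 42.4)
#' @export
analytic_g0_exponential <- function(m_e_min, m_ne_min, window_min) {
  if (m_e_min <= 0) stop("m_e must be > 0")
  if (m_ne_min < 0) stop("m_ne must be >= 0")
  if (m_ne_min == 0) return(1)
  1 - (m_ne_min / (m_e_min + m_ne_min)) * exp(-window_min / m_ne_min)
}

#' g(0) over a grid of strip widths and survey speeds
#'
#' Runs \code{\link{simulate_g0}} for every combination of ESHW and speed,
#' returning matrices of means and sds plus monotonicity flags: for a
#' fixed phase source g(0) should not decrease with ESHW (longer window)
#' nor increase with speed (shorter window), within Monte Carlo noise.
#'
#' @param phase_source as in \code{\link{simulate_g0}}.
#' @param eshw_list ESHW values (km).
#' @param speed_list speeds (km/h).
#' @param n_runs runs per cell.
#' @param seed integer seed; cell (i, j) uses \code{seed + (j-1)*length(
#'   eshw_list) + i - 1}, so a cell reproduces a standalone
#'   \code{simulate_g0} call with that seed.
#' @param ... passed to \code{\link{simulate_g0}}.
#' @return object of class \code{"g0_grid"}: matrices \code{mean} and
#'   \code{sd} (rows = ESHW, cols = speed), \code{se} (Monte Carlo
#'   standard errors), and logical flags \code{mono_eshw},
#'   \code{mono_speed} (monotone within 2 Monte Carlo se per adjacent
#'   pair).
#' @export
g0_grid <- function(phase_source, eshw_list, speed_list, n_runs = 500,
                    seed = 1, ...) {
  if (length(eshw_list) == 0 || length(speed_list) == 0)
    stop("grids must be non-empty")
  ne <- length(eshw_list); nv <- length(speed_list)
  m <- s <- matrix(NA_real_, ne, nv,
                   dimnames = list(paste0("eshw_", eshw_list),
                                   paste0("speed_", speed_list)))
  for (j in seq_len(nv)) for (i in seq_len(ne)) {
    est <- simulate_g0(phase_source, eshw_list[i], speed_list[j],
                       n_runs = n_runs,
                       seed = seed + (j - 1) * ne + i - 1, ...)
    m[i, j] <- est$g0_mean
    s[i, j] <- est$g0_sd
  }
  se <- s / sqrt(n_runs)
  tol <- function(a, b) 2 * sqrt(a^2 + b^2)
  mono_eshw <- ne < 2 ||
    all(diff(m) >= -tol(se[-1, , drop = FALSE], se[-ne, , drop = FALSE]))
  mono_speed <- nv < 2 ||
    all(m[, -1, drop = FALSE] - m[, -nv, drop = FALSE] <=
          tol(se[, -1, drop = FALSE], se[, -nv, drop = FALSE]))
  structure(list(mean = m, sd = s, se = se, n_runs = n_runs,
                 mono_eshw = mono_eshw, mono_speed = mono_speed),
            class = "g0_grid")
}

#' @export
print.g0_grid <- function(x, ...) {
  cat("g(0) grid (rows ESHW km, cols speed km/h):\n")
  print(round(x$mean, 3))
  cat(sprintf("monotone in ESHW: %s; monotone in speed: %s\n",
              x$mono_eshw, x$mono_speed))
  invisible(x)
}
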