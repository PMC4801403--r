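#' Segment a tag record into dive cycles
#'
#' A foraging dive is a maximal excursion with depth exceeding
#' \code{dive_threshold_m}; each cycle pairs a dive with the following
#' surface interval, ending at the start of the next dive. Within a dive
#' the echolocation period runs from the first to the last clicking sample.
#' A cycle is \code{complete} only when it is bounded by an observed
#' following dive. Dives containing no clicking samples are retained with
#' zero echolocation duration and flagged by \code{has_echo = FALSE} for
#' exclusion downstream.
#'
#' The default threshold of 100 m separates foraging dives (where clicking
#' begins at a few hundred metres depth) from surface behaviour and shallow
#' excursions.
#'
#' @param series a \code{\link{generate_tag_series}} result, or a data
#'   frame with columns \code{t_s}, \code{depth_m}, \code{clicking}.
#' @param dive_threshold_m depth (m) defining a foraging dive.
#' @return a data frame of class \code{"dive_cycles"}, one row per cycle:
#'   \code{dive_start_s, echo_start_s, echo_end_s, dive_end_s, idi_end_s,
#'   complete, has_echo}. Empty (zero rows) if the record never crosses
#'   the threshold.
#' @export
segment_dive_cycles <- function(series, dive_threshold_m = 100) {
  s <- if (inherits(series, "tag_series")) series$samples else series
  if (!all(c("t_s", "depth_m", "clicking") %in% names(s)))
    stop("series must have columns t_s, depth_m, clicking")
  if (nrow(s) == 0) stop("empty series")
  if (is.unsorted(s$t_s, strictly = TRUE)) stop("time must strictly increase")

  deep <- s$depth_m > dive_threshold_m
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  di <- which(r$values)
  out <- data.frame(dive_start_s = numeric(0), echo_start_s = numeric(0),
                    echo_end_s = numeric(0), dive_end_s = numeric(0),
                    idi_end_s = numeric(0), complete = logical(0),
                    has_echo = logical(0))
  if (length(di) == 0) return(structure(out, class = c("dive_cycles",
                                                       "data.frame")))
  n <- length(di)
  for (j in seq_len(n)) {
    i0 <- starts[di[j]]; i1 <- ends[di[j]]
    clk <- which(s$clicking[i0:i1] == 1)
    has_echo <- length(clk) > 0
    es <- if (has_echo) s$t_s[i0 + clk[1] - 1] else NA_real_
    ee <- if (has_echo) s$t_s[i0 + clk[length(clk)] - 1] else NA_real_
    nxt <- if (j < n) s$t_s[starts[di[j + 1]]] else s$t_s[nrow(s)]
    out[j, ] <- list(s$t_s[i0], es, ee, s$t_s[i1], nxt, j < n, has_echo)
  }
  structure(out, class = c("dive_cycles", "data.frame"))
}

#' Extract echolocating / silent phase durations from dive cycles
#'
#' Builds the paired duration samples that drive the availability
#' simulation: \code{t_e}, the duration of each usable echolocation period,
#' and \code{t_ne}, the combined silent stretch between consecutive
#' echolocation periods (silent ascent + inter-dive interval + next silent
#' descent) — the time over which the whale cannot be detected
#' acoustically. The first cycle after tagging can be excluded (behavioural
#' reaction), as can incomplete cycles and dives without clicking.
#'
#' @param cycles a \code{\link{segment_dive_cycles}} result.
#' @param exclude_first drop the first cycle after tag-on?
#' @param require_complete drop incomplete and echolocation-free cycles?
#' @return a \code{\link{phase_duration_set}}.
#' @export
extract_phase_durations <- function(cycles, exclude_first = TRUE,
                                    require_complete = TRUE) {
  cy <- as.data.frame(cycles)
  idx <- seq_len(nrow(cy))
  if (exclude_first && nrow(cy) > 0) idx <- idx[-1]
  if (require_complete) {
    idx <- idx[cy$complete[idx] & cy$has_echo[idx] &
                 (cy$echo_end_s[idx] > cy$echo_start_s[idx])]
  } else {
    idx <- idx[cy$has_echo[idx]]
  }
  if (length(idx) < 2)
    stop("fewer than 2 usable dive cycles; cannot derive silent durations")
  t_e <- (cy$echo_end_s[idx] - cy$echo_start_s[idx]) / 60
  # t_ne spans successive echolocation periods; a gap is usable when every
  # intervening cycle (if any) is a dive without clicking — real silence —
  # not a cycle dropped for data reasons (the excluded first cycle)
  ok <- vapply(seq_len(length(idx) - 1), function(k) {
    lo <- idx[k] + 1; hi <- idx[k + 1] - 1
    lo > hi || all(!cy$has_echo[lo:hi])
  }, logical(1))
  t_ne <- (cy$echo_start_s[idx[which(ok) + 1]] -
             cy$echo_end_s[idx[which(ok)]]) / 60
  if (length(t_ne) < 1)
    stop("no usable cycle pair; cannot derive silent durations")
  phase_duration_set(t_e, t_ne)
}

#' Paired phase-duration samples
#'
#' Container for the empirical distributions of echolocating (\code{t_e})
#' and non-echolocating (\code{t_ne}) phase durations, in minutes. Used as
#' the empirical \code{phase_source} of \code{\link{simulate_g0}}.
#'
#' @param t_e echolocation-period durations (min), all > 0.
#' @param t_ne silent-period durations (min), all > 0.
#' @return object of class \code{"phase_duration_set"}.
#' @export
phase_duration_set <- function(t_e, t_ne) {
  if (length(t_e) == 0 || length(t_ne) == 0)
    stop("t_e and t_ne must be non-empty")
  if (any(!is.finite(t_e)) || any(!is.finite(t_ne)) ||
      any(t_e <= 0) || any(t_ne <= 0))
    stop("all phase durations must be positive and finite")
  structure(list(t_e = as.numeric(t_e), t_ne = as.numeric(t_ne)),
            class = "phase_duration_set")
}

#' @export
print.phase_duration_set <- function(x, ...) {
  cat(sprintf(paste0(
    "Phase durations: %d echolocating (mean %.1f min), ",
    "%d silent (mean %.1f min)\n"),
    length(x$t_e), mean(x$t_e), length(x$t_ne), mean(x$t_ne)))
  invisible(x)
}

#' Pool phase-duration sets across whales
#'
#' Concatenates per-whale duration samples into one pooled set (per-cycle
#' pooling: every cycle contributes equally, so whales with more recorded
#' cycles carry proportionally more weight).
#'
#' @param sets list of \code{\link{phase_duration_set}} objects.
#' @return a pooled \code{\link{phase_duration_set}}.
#' @export
pool_phases <- function(sets) {
  phase_duration_set(unlist(lapply(sets, `[[`, "t_e")),
                     unlist(lapply(sets, `[[`, "t_ne")))
}

#' Probability histograms of phase durations
#'
#' Normalised 1-minute-bin histograms of the echolocating and silent
#' duration samples; each histogram's probabilities sum to one.
#'
#' @param set a \code{\link{phase_duration_set}}.
#' @param bin_min bin width in minutes.
#' @return list with data frames \code{echo} and \code{silent}
#'   (\code{bin_lo, bin_hi, p}).
#' @export
phase_histograms <- function(set, bin_min = 1) {
  if (!inherits(set, "phase_duration_set")) stop("need a phase_duration_set")
  one <- function(x) {
    breaks <- seq(0, ceiling(max(x) / bin_min) * bin_min, by = bin_min)
    h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE)
    data.frame(bin_lo = h$breaks[-length(h$breaks)], bin_hi = h$breaks[-1],
               p = h$counts / length(x))
  }
  list(echo = one(set$t_e), silent = one(set$t_ne))
}

#' Fraction of time spent echolocating
#'
#' The pooled time budget: total echolocating time over total time,
#' \code{sum(t_e) / (sum(t_e) + sum(t_ne))}.
#'
#' @param set a \code{\link{phase_duration_set}}.
#' @return scalar fraction in (0, 1).
#' @export
time_budget <- function(set) {
  if (!inherits(set, "phase_duration_set")) stop("need a phase_duration_set")
  sum(set$t_e) / (sum(set$t_e) + sum(set$t_ne))
}
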