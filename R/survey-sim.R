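#' Configuration for a synthetic acoustic line-transect survey
#'
#' Describes a planar survey strip: the vessel steams north along the
#' track line x = 0 from (0, 0) to (0, \code{track_length_km}); whales are
#' placed by a homogeneous Poisson process in the strip of half-width
#' \code{strip_halfwidth_km} either side and thinned by the configured
#' detection function evaluated at their true perpendicular distance.
#'
#' @param strip_halfwidth_km half-width of the simulated strip (km).
#' @param track_length_km length of the (single, straight) track line (km).
#' @param whale_density_per_km2 true whale density (animals / km^2).
#' @param df_key detection-function key used to thin the whale field.
#' @param df_sigma,df_shape key parameters (see \code{\link{detection_g}}).
#' @param bearing_noise_deg sd of Gaussian noise added to bearings.
#' @param n_bearings number of bearings recorded per retained whale.
#' @param speed_kmh vessel speed (km/h), used only to timestamp the track.
#' @param whale_depth_m nominal whale depth, recorded in the truth table
#'   (bearings are taken to the surface-projected position).
#' @param seed optional integer seed.
#' @return an object of class \code{"survey_sim_config"}.
#' @export
survey_sim_config <- function(strip_halfwidth_km = 9, track_length_km = 200,
                              whale_density_per_km2 = 0.02,
                              df_key = c("hazard-rate", "half-normal",
                                         "uniform"),
                              df_sigma = 2, df_shape = 3,
                              bearing_noise_deg = 0, n_bearings = 15,
                              speed_kmh = 11.8, whale_depth_m = 0,
                              seed = NULL) {
  df_key <- match.arg(df_key)
  if (strip_halfwidth_km <= 0 || track_length_km <= 0)
    stop("strip dimensions must be positive")
  if (whale_density_per_km2 < 0) stop("density must be >= 0")
  if (df_key != "uniform" && df_sigma <= 0) stop("sigma must be > 0")
  if (df_key == "hazard-rate" && df_shape <= 1)
    stop("hazard-rate shape must be > 1")
  if (speed_kmh <= 0) stop("speed must be positive")
  structure(list(strip_halfwidth_km = strip_halfwidth_km,
                 track_length_km = track_length_km,
                 whale_density_per_km2 = whale_density_per_km2,
                 df_key = df_key, df_sigma = df_sigma, df_shape = df_shape,
                 bearing_noise_deg = bearing_noise_deg,
                 n_bearings = as.integer(n_bearings),
                 speed_kmh = speed_kmh, whale_depth_m = whale_depth_m,
                 seed = seed),
            class = "survey_sim_config")
}

#' Simulate a whale field and the bearings a towed array would record
#'
#' Whales are dropped by a homogeneous Poisson process in the survey strip,
#' retained with probability g(x) of the configured key at their true
#' perpendicular distance, and, for each retained whale, a series of
#' unsigned (side-ambiguous) bearings relative to the vessel heading is
#' generated from vessel positions bracketing the whale's abeam point, with
#' optional Gaussian angular noise. The truth table records every whale,
#' its true position, perpendicular distance and retention, enabling
#' end-to-end recovery tests of the localization and detection-function
#' stages.
#'
#' @param cfg a \code{\link{survey_sim_config}}.
#' @return a list of class \code{"survey_scenario"} with elements
#'   \item{track}{data frame \code{t_s, x_km, y_km, heading_deg};}
#'   \item{truth}{data frame, one row per simulated whale (\code{whale_id,
#'     x_km, y_km, perp_km, depth_m, retained});}
#'   \item{bearings}{data frame \code{whale_id, t_s, bearing_deg,
#'     side_unknown} for retained whales;}
#'   \item{distances}{true perpendicular distances (km) of retained whales.}
#' @export
generate_survey_scenario <- function(cfg) {
  if (!inherits(cfg, "survey_sim_config"))
    stop("cfg must be a survey_sim_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$track_length_km
  hw <- cfg$strip_halfwidth_km
  v <- cfg$speed_kmh

  track <- data.frame(t_s = seq(0, L / v * 3600, length.out = 201),
                      x_km = 0,
                      y_km = seq(0, L, length.out = 201),
                      heading_deg = 0)

  n_true <- stats::rpois(1, cfg$whale_density_per_km2 * 2 * hw * L)
  if (n_true == 0) {
    truth <- data.frame(whale_id = character(), x_km = numeric(),
                        y_km = numeric(), perp_km = numeric(),
                        depth_m = numeric(), retained = logical())
    bearings <- data.frame(whale_id = character(), t_s = numeric(),
                           bearing_deg = numeric(), side_unknown = integer())
    return(structure(list(track = track, truth = truth, bearings = bearings,
                          distances = numeric()),
                     class = "survey_scenario"))
  }
  x <- stats::runif(n_true, -hw, hw)
  y <- stats::runif(n_true, 0, L)
  perp <- abs(x)
  g <- detection_g(perp, cfg$df_key, cfg$df_sigma, cfg$df_shape)
  retained <- stats::runif(n_true) < g
  truth <- data.frame(whale_id = sprintf("w%03d", seq_len(n_true)),
                      x_km = x, y_km = y, perp_km = perp,
                      depth_m = cfg$whale_depth_m, retained = retained)

  blist <- vector("list", sum(retained))
  k <- 0
  for (i in which(retained)) {
    k <- k + 1
    span <- max(1, perp[i])  # along-track span giving >= 90 deg aperture
    yv <- y[i] + seq(-span, span, length.out = cfg$n_bearings)
    yv <- pmin(pmax(yv, 0), L)
    phi <- atan2(x[i] - 0, y[i] - yv) * 180 / pi  # compass angle, heading 0
    brg <- abs(phi)                               # unsigned relative bearing
    if (cfg$bearing_noise_deg > 0) {
      brg <- brg + stats::rnorm(length(brg), 0, cfg$bearing_noise_deg)
      brg <- pmin(pmax(brg, 0), 180)
    }
    blist[[k]] <- data.frame(whale_id = truth$whale_id[i],
                             t_s = yv / v * 3600,
                             bearing_deg = brg, side_unknown = 1L)
  }
  bearings <- if (k > 0) do.call(rbind, blist) else
    data.frame(whale_id = character(), t_s = numeric(),
               bearing_deg = numeric(), side_unknown = integer())
  structure(list(track = track, truth = truth, bearings = bearings,
                 distances = perp[retained]),
            class = "survey_scenario")
}

#' @export
print.survey_scenario <- function(x, ...) {
  cat(sprintf(
    "Survey scenario: %.0f km track, %d whales simulated, %d retained\n",
    max(x$track$y_km), nrow(x$truth), length(x$distances)))
  invisible(x)
}

#' Draw perpendicular distances from a detection density
#'
#' Samples i.i.d. perpendicular distances from the normalised detection
#' density f(x) = g(x) / mu on [0, w] by rejection sampling (uniform
#' proposal, acceptance probability g(x), valid because g <= 1 for all
#' supported keys).
#'
#' @param key,sigma,shape detection key, see \code{\link{detection_g}}.
#' @param w truncation distance (km), > 0.
#' @param n number of draws, > 0.
#' @param seed optional integer seed.
#' @return numeric vector of \code{n} distances in [0, w].
#' @examples
#' d <- generate_perp_distances("hazard-rate", sigma = 2, shape = 3,
#'                              w = 9, n = 100, seed = 1)
#' @export
generate_perp_distances <- function(key, sigma = NULL, shape = NULL, w, n,
                                    seed = NULL) {
  if (w <= 0) stop("truncation distance w must be > 0")
  if (n <= 0) stop("n must be > 0")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling((n - length(out)) * 1.6))
    x <- stats::runif(m, 0, w)
    keep <- stats::runif(m) < detection_g(x, key, sigma, shape)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}
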