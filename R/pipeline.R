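#' Published constants of the Canary Islands sperm-whale survey
#'
#' The headline quantities of the 2009--2010 passive-acoustic line-transect
#' survey of the Canary Islands territorial waters: detections after 9-km
#' truncation, the selected hazard-rate ESHW, total effort, the
#' corner-overlap fraction of the zigzag design, the survey area, the
#' Monte Carlo g(0) with its sd, the g(0)=1 coefficient of variation, the
#' sperm-whale maximum rate of increase and the observed ship-strike
#' stranding rate. Useful for re-deriving the published density, abundance
#' and sustainability chain with \code{\link{abundance_estimate}} and
#' \code{\link{sustainability}}.
#'
#' @return a named list: \code{n}, \code{mu_km}, \code{mu_ci_km},
#'   \code{w_km}, \code{L_km}, \code{overlap}, \code{A_km2}, \code{g0},
#'   \code{g0_sd}, \code{cv_er}, \code{speed_knots}, \code{speed_kmh},
#'   \code{r_max}, \code{mortality}.
#' @examples
#' cs <- canary_survey()
#' abundance_estimate(cs$n, cs$mu_km, cs$L_km, cs$overlap, cs$g0,
#'                    cs$g0_sd, cs$A_km2, cv_er = cs$cv_er)
#' @export
canary_survey <- function() {
  list(n = 83, mu_km = 4.168, mu_ci_km = c(3.599, 4.826), w_km = 9,
       L_km = 2668, overlap = 0.042, A_km2 = 52933,
       g0 = 0.92, g0_sd = 0.031, cv_er = 0.320,
       speed_knots = 6.4, speed_kmh = 6.4 * 1.852,
       r_max = 0.011, mortality = 2)
}

#' Write a complete synthetic survey + tag dataset to disk
#'
#' Generates every input the pipeline consumes — tag records for several
#' whales, a survey scenario (track, bearings, truth) thinned by a known
#' hazard-rate detection function, a per-transect effort table and a flat
#' JSON run configuration — sized to run end-to-end in well under two
#' minutes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the whole dataset is deterministic in it.
#' @param n_whales number of tagged whales to simulate.
#' @param survey_cfg optional \code{\link{survey_sim_config}} override.
#' @return \code{dir}, invisibly; files written: \code{tag_<k>.csv},
#'   \code{track.csv}, \code{bearings.csv}, \code{truth.csv},
#'   \code{effort.csv}, \code{config.json}.
#' @export
make_fixtures <- function(dir, seed = 1, n_whales = 3, survey_cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  for (k in seq_len(n_whales)) {
    ts <- generate_tag_series(tag_sim_config(n_cycles = 13,
                                             seed = seed + 100 + k),
                              whale_id = sprintf("tag_%d", k))
    write_tag_csv(ts, file.path(dir, sprintf("tag_%d.csv", k)))
  }
  if (is.null(survey_cfg)) {
    survey_cfg <- survey_sim_config(strip_halfwidth_km = 9,
                                    track_length_km = 400,
                                    whale_density_per_km2 = 0.03,
                                    df_key = "hazard-rate",
                                    df_sigma = 2, df_shape = 3,
                                    bearing_noise_deg = 1.5,
                                    seed = seed + 200)
  }
  sc <- generate_survey_scenario(survey_cfg)
  utils::write.csv(sc$track, file.path(dir, "track.csv"), row.names = FALSE)
  utils::write.csv(sc$bearings, file.path(dir, "bearings.csv"),
                   row.names = FALSE)
  utils::write.csv(sc$truth, file.path(dir, "truth.csv"), row.names = FALSE)

  # carve the single track into equal-length transects for the
  # encounter-rate variance; detections assigned by along-track position
  K <- 8
  L <- survey_cfg$track_length_km
  edges <- seq(0, L, length.out = K + 1)
  det_y <- sc$truth$y_km[sc$truth$retained]
  effort <- data.frame(transect = seq_len(K),
                       length_km = diff(edges),
                       detections = as.vector(
                         table(cut(det_y, edges, include.lowest = TRUE))))
  utils::write.csv(effort, file.path(dir, "effort.csv"), row.names = FALSE)

  cfg <- list(tags = sprintf("tag_%d.csv", seq_len(n_whales)),
              track = "track.csv", bearings = "bearings.csv",
              effort = "effort.csv",
              w_km = survey_cfg$strip_halfwidth_km,
              speed_kmh = survey_cfg$speed_kmh,
              A_km2 = 2 * survey_cfg$strip_halfwidth_km * L,
              overlap = 0, r_max = 0.011, mortality = 2,
              g0_runs = 500, seed = seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full survey-analysis pipeline
#'
#' Chains every stage on a directory of input CSVs and a JSON run
#' configuration (as written by \code{\link{make_fixtures}}): tag records
#' are segmented into dive cycles and pooled phase durations; bearings are
#' crossed into whale fixes and perpendicular distances; half-normal and
#' hazard-rate detection functions are fitted to the truncated distances
#' and the minimum-AIC model selected; g(0) is simulated from the pooled
#' phases at the fitted ESHW and the survey speed; and the density,
#' abundance, CV and sustainability chain is assembled. Outputs
#' (\code{phases.csv}, \code{fixes.csv}, \code{report.json}) are written
#' to \code{out_dir}. The run is deterministic in the configured seed.
#'
#' @param dir input directory containing the files named in
#'   \code{config.json}.
#' @param out_dir output directory (default \code{dir}).
#' @return the report, invisibly: a list with elements \code{phases},
#'   \code{fit}, \code{g0}, \code{estimate}, \code{sustainability}.
#' @export
run_pipeline <- function(dir, out_dir = dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("[config] run configuration not found: ",
                                   cfg_path)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  # --- tag processing -----------------------------------------------------
  sets <- lapply(cfg$tags, function(f) {
    ts <- tryCatch(read_tag_csv(file.path(dir, f)),
                   error = function(e) stop("[tag_processing] ",
                                            conditionMessage(e)))
    extract_phase_durations(segment_dive_cycles(ts))
  })
  phases <- pool_phases(sets)
  write_phase_csv(phases, file.path(out_dir, "phases.csv"))

  # --- localization -------------------------------------------------------
  track <- read_required_csv(file.path(dir, cfg$track),
                             "[localization] track")
  bearings <- read_required_csv(file.path(dir, cfg$bearings),
                                "[localization] bearings")
  fixes <- lapply(split(bearings, bearings$whale_id), function(b) {
    tryCatch(cross_bearings(track, b), error = function(e) NULL)
  })
  fixes <- Filter(Negate(is.null), fixes)
  if (length(fixes) == 0) stop("[localization] no whale could be fixed")
  fix_df <- data.frame(
    whale_id = names(fixes),
    x_km = vapply(fixes, function(f) f$position[1], numeric(1)),
    y_km = vapply(fixes, function(f) f$position[2], numeric(1)),
    side = vapply(fixes, `[[`, character(1), "chosen_side"),
    perp_km = vapply(fixes, `[[`, numeric(1), "perp_distance_km"))
  utils::write.csv(fix_df, file.path(out_dir, "fixes.csv"),
                   row.names = FALSE)

  # --- detection function -------------------------------------------------
  d <- truncate_distances(fix_df$perp_km, cfg$w_km)
  fits <- list(fit_detection(d, "half-normal", cfg$w_km),
               fit_detection(d, "hazard-rate", cfg$w_km))
  fit <- select_model(fits)

  # --- g(0) ---------------------------------------------------------------
  g0 <- simulate_g0(phases, eshw_km = fit$mu, speed_kmh = cfg$speed_kmh,
                    n_runs = cfg$g0_runs, seed = cfg$seed + 1)

  # --- abundance ----------------------------------------------------------
  effort <- read_required_csv(file.path(dir, cfg$effort),
                              "[abundance] effort")
  er <- encounter_rate_cv(effort)
  est <- abundance_estimate(n = length(d), mu_km = fit$mu,
                            L_km = sum(effort$length_km),
                            overlap = cfg$overlap,
                            g0 = g0$g0_mean, g0_sd = g0$g0_sd,
                            A = cfg$A_km2, cv_er = er$cv,
                            cv_mu = fit$cv_mu)
  sus <- sustainability(est$N, cfg$r_max, cfg$mortality)

  report <- list(
    n_detections = length(d),
    phases = list(n_echo = length(phases$t_e),
                  n_silent = length(phases$t_ne),
                  mean_echo_min = mean(phases$t_e),
                  mean_silent_min = mean(phases$t_ne),
                  time_budget = time_budget(phases)),
    detection = list(key = fit$key, par = as.list(fit$par),
                     w_km = fit$w, AIC = fit$AIC,
                     eshw_km = fit$mu, cv_eshw = fit$cv_mu),
    g0 = list(mean = g0$g0_mean, sd = g0$g0_sd,
              window_min = g0$window_min),
    density_per_1000km2 = 1000 * est$D,
    abundance = est$N,
    cv_total = est$cv_total,
    ci_abundance = est$ci_N,
    sustainability = list(recruitment = sus$recruitment,
                          mortality = sus$mortality,
                          verdict = sus$verdict),
    seed = cfg$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(phases = phases, fixes = fix_df, fit = fit, g0 = g0,
                 estimate = est, sustainability = sus, report = report))
}
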