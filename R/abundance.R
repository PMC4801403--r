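#' Line-transect density of whales
#'
#' The conventional distance-sampling estimator
#' D = n / (2 mu L) x 1 / g(0), with an optional correction for effort
#' counted twice where consecutive zigzag transects overlap at corners:
#' the overlapping fraction o of the surveyed area deflates the effective
#' effort, so the estimator divides by (1 - o).
#'
#' @param n number of animals detected.
#' @param mu_km effective strip half-width (km).
#' @param L_km total transect length (km).
#' @param overlap fraction o of the surveyed area counted twice
#'   (0 <= o < 1).
#' @param g0 track-line detection probability (0 < g0 <= 1).
#' @return density in animals per km^2 (multiply by 1000 for the
#'   conventional animals per 1000 km^2).
#' @examples
#' 1000 * estimate_density(83, 4.168, 2668, overlap = 0.042)  # 3.90
#' @export
estimate_density <- function(n, mu_km, L_km, overlap = 0, g0 = 1) {
  if (n < 0) stop("n must be >= 0")
  if (mu_km <= 0 || L_km <= 0) stop("mu and L must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (g0 <= 0 || g0 > 1) stop("g0 must be in (0, 1]")
  n / (2 * mu_km * L_km * (1 - overlap)) / g0
}

#' Abundance from density and area
#'
#' @param D density (animals / km^2).
#' @param A survey area (km^2).
#' @return expected number of animals in the area.
#' @export
estimate_abundance <- function(D, A) {
  if (D < 0) stop("D must be >= 0")
  if (A <= 0) stop("A must be > 0")
  D * A
}

#' Empirical between-transect encounter-rate variance
#'
#' The standard design-based estimator of the variance of the encounter
#' rate n/L for systematic line placement, treating transects as the
#' sampling unit: var(n/L) = K / (L^2 (K-1)) * sum l_k^2 (n_k/l_k - n/L)^2.
#'
#' @param effort data frame with columns \code{length_km} and
#'   \code{detections}, one row per transect (K >= 2 rows).
#' @return list with \code{encounter_rate} (per km), \code{var_er},
#'   \code{cv} (NA when no detections).
#' @export
encounter_rate_cv <- function(effort) {
  if (!all(c("length_km", "detections") %in% names(effort)))
    stop("effort needs columns length_km and detections")
  K <- nrow(effort)
  if (K < 2) stop("need at least 2 transects for a variance estimate")
  l <- effort$length_km
  if (any(l <= 0)) stop("transect lengths must be positive")
  n <- sum(effort$detections)
  L <- sum(l)
  er <- n / L
  v <- K / (L^2 * (K - 1)) * sum(l^2 * (effort$detections / l - er)^2)
  list(encounter_rate = er, var_er = v,
       cv = if (er > 0) sqrt(v) / er else NA_real_)
}

#' Combine coefficients of variation
#'
#' Delta-method combination of independent multiplicative error sources:
#' cv_total = sqrt(sum cv_i^2).
#'
#' @param components numeric vector of CVs, all >= 0.
#' @return combined CV.
#' @examples
#' combine_cv(c(0.320, 0.031 / 0.92))  # 0.322
#' @export
combine_cv <- function(components) {
  if (any(components < 0)) stop("CVs must be >= 0")
  sqrt(sum(components^2))
}

#' Log-normal confidence interval
#'
#' The standard distance-sampling interval (est / C, est x C) with
#' C = exp(z sqrt(log(1 + cv^2))); the bounds satisfy lo x hi = est^2.
#' Plain z-based intervals are used (no degrees-of-freedom correction).
#'
#' @param estimate point estimate, > 0.
#' @param cv coefficient of variation, >= 0.
#' @param z normal quantile (1.96 for 95%).
#' @return numeric length-2, (lower, upper).
#' @export
lognormal_ci <- function(estimate, cv, z = 1.96) {
  if (estimate <= 0) stop("estimate must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(estimate / C, estimate * C)
}

#' Full density/abundance estimate with propagated uncertainty
#'
#' Chains \code{\link{estimate_density}} and
#' \code{\link{estimate_abundance}} and propagates the CVs of the
#' encounter rate, the ESHW and g(0) (as g0_sd / g0) into a total CV and
#' log-normal intervals for density and abundance.
#'
#' @inheritParams estimate_density
#' @param g0_sd Monte Carlo sd of the g(0) estimate.
#' @param A survey area (km^2).
#' @param cv_er encounter-rate CV (from \code{\link{encounter_rate_cv}},
#'   or as published; may already bundle the ESHW CV, in which case leave
#'   \code{cv_mu} at 0).
#' @param cv_mu ESHW CV.
#' @param z normal quantile for the intervals.
#' @return object of class \code{"density_estimate"} with the inputs, the
#'   density \code{D} (per km^2), abundance \code{N}, CV components,
#'   \code{cv_total} and the interval bounds.
#' @examples
#' est <- abundance_estimate(n = 83, mu_km = 4.168, L_km = 2668,
#'                           overlap = 0.042, g0 = 0.92, g0_sd = 0.031,
#'                           A = 52933, cv_er = 0.320)
#' est
#' @export
abundance_estimate <- function(n, mu_km, L_km, overlap = 0, g0 = 1,
                               g0_sd = 0, A, cv_er = 0, cv_mu = 0,
                               z = 1.96) {
  D <- estimate_density(n, mu_km, L_km, overlap, g0)
  N <- estimate_abundance(D, A)
  cv_g0 <- if (g0 > 0) g0_sd / g0 else 0
  cv_total <- combine_cv(c(cv_er, cv_mu, cv_g0))
  ci_D <- if (D > 0) lognormal_ci(D, cv_total, z) else c(0, 0)
  ci_N <- if (N > 0) lognormal_ci(N, cv_total, z) else c(0, 0)
  structure(list(n = n, mu_km = mu_km, L_km = L_km, overlap = overlap,
                 g0 = g0, g0_sd = g0_sd, A = A, D = D, N = N,
                 cv_er = cv_er, cv_mu = cv_mu, cv_g0 = cv_g0,
                 cv_total = cv_total, ci_D = ci_D, ci_N = ci_N, z = z),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density  D = %.2f whales/1000 km^2 (95%% CI %.2f-%.2f)\n",
              1000 * x$D, 1000 * x$ci_D[1], 1000 * x$ci_D[2]))
  cat(sprintf("Abundance N = %.0f whales in %.0f km^2 (95%% CI %.0f-%.0f)\n",
              x$N, x$A, x$ci_N[1], x$ci_N[2]))
  cat(sprintf("CV %.1f%% (encounter %.1f%%, ESHW %.1f%%, g0 %.1f%%)\n",
              100 * x$cv_total, 100 * x$cv_er, 100 * x$cv_mu,
              100 * x$cv_g0))
  cat(sprintf("Inputs: n = %d, ESHW = %.3f km, L = %.0f km, overlap %.1f%%",
              x$n, x$mu_km, x$L_km, 100 * x$overlap))
  cat(sprintf(", g(0) = %.2f\n", x$g0))
  invisible(x)
}

#' @export
summary.density_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
confint.density_estimate <- function(object, parm = c("D", "N"),
                                     level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- t(vapply(parm, function(p)
    lognormal_ci(object[[p]], object$cv_total, z), numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Sustainability of anthropogenic mortality
#'
#' Compares an observed annual mortality (e.g. ship-strike strandings per
#' year) with the recruitment capability of the estimated stock,
#' r_max x N, where r_max is the stock's maximum annual rate of increase
#' (about 1.1%/yr for sperm whales). Recruitment is reported to one
#' decimal place; the verdict is \code{"exceeds"} when mortality is at
#' least the recruitment.
#'
#' @param N abundance estimate.
#' @param r_max maximum rate of increase (per year).
#' @param mortality observed mortality (whales per year).
#' @return object of class \code{"sustainability_report"} with
#'   \code{recruitment} (whales/yr, 1 dp), \code{verdict} and
#'   \code{margin}.
#' @examples
#' sustainability(224, 0.011, 2)
#' @export
sustainability <- function(N, r_max = 0.011, mortality = 0) {
  if (N < 0 || r_max < 0 || mortality < 0)
    stop("N, r_max and mortality must be >= 0")
  rec <- round(r_max * N, 1)
  verdict <- if (mortality >= rec) "exceeds" else "within"
  structure(list(N = N, r_max = r_max, recruitment = rec,
                 mortality = mortality, verdict = verdict,
                 margin = abs(rec - mortality)),
            class = "sustainability_report")
}

#' @export
print.sustainability_report <- function(x, ...) {
  cat(sprintf(
    "Recruitment %.1f whales/yr (N = %.0f, r_max = %.1f%%/yr)\n",
    x$recruitment, x$N, 100 * x$r_max))
  cat(sprintf("Observed mortality %.1f whales/yr: %s recruitment",
              x$mortality,
              if (x$verdict == "exceeds") "meets or exceeds" else "within"))
  cat(sprintf(" (margin %.1f)\n", x$margin))
  invisible(x)
}
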