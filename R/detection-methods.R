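#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s key, w = %g km, n = %d\n",
              x$key, x$w, x$n_used))
  if (length(x$par)) {
    cat("  ", paste(sprintf("%s = %.4g", names(x$par), x$par),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$AIC))
  cat(sprintf("  ESHW mu = %.4f km (CV %.1f%%)\n", x$mu, 100 * x$cv_mu))
  invisible(x)
}

#' @export
summary.detection_fit <- function(object, ...) {
  se <- if (length(object$par)) sqrt(diag(object$vcov)) else numeric(0)
  out <- list(fit = object,
              coefficients = cbind(Estimate = object$par, `Std. Error` = se),
              eshw = eshw(object))
  class(out) <- "summary.detection_fit"
  out
}

#' @export
print.summary.detection_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$coefficients)) {
    cat("Coefficients:\n")
    print(round(x$coefficients, 4))
  }
  cat(sprintf("ESHW 95%% log-normal CI: %.3f - %.3f km\n",
              x$eshw$ci[1], x$eshw$ci[2]))
  invisible(x)
}

#' @export
coef.detection_fit <- function(object, ...) object$par

#' @export
vcov.detection_fit <- function(object, ...) object$vcov

#' @export
logLik.detection_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n_used,
            class = "logLik")
}

#' Wald confidence intervals for detection-function parameters
#'
#' Intervals are computed on the optimisation scale (log sigma,
#' log(shape - 1)) and back-transformed, which respects the parameter
#' bounds and is standard practice in distance-sampling software.
#'
#' @param object a \code{\link{fit_detection}} result.
#' @param parm parameter names (default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
confint.detection_fit <- function(object, parm = names(object$par),
                                  level = 0.95, ...) {
  if (!length(object$par)) stop("uniform key has no parameters")
  z <- stats::qnorm(1 - (1 - level) / 2)
  th <- if (object$key == "half-normal") log(object$par[1]) else
    c(log(object$par[1]), log(object$par[2] - 1))
  se <- sqrt(diag(object$vcov_trans))
  lo_t <- th - z * se
  hi_t <- th + z * se
  back <- function(v) {
    if (object$key == "half-normal") exp(v[1]) else c(exp(v[1]), 1 + exp(v[2]))
  }
  out <- cbind(lower = back(lo_t), upper = back(hi_t))
  rownames(out) <- names(object$par)
  out[parm, , drop = FALSE]
}

#' Predict detection probability or detection density
#'
#' @param object a \code{\link{fit_detection}} result.
#' @param x perpendicular distances (km) at which to evaluate.
#' @param type \code{"detection"} for g(x), \code{"pdf"} for the sampling
#'   density f(x) = g(x) / mu on [0, w] (zero outside).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.detection_fit <- function(object, x, type = c("detection", "pdf"),
                                  ...) {
  type <- match.arg(type)
  g <- detection_g(x, object$key, object$par["sigma"],
                   if (object$key == "hazard-rate") object$par["shape"])
  if (type == "detection") return(g)
  out <- g / object$mu
  out[x > object$w] <- 0
  out
}

#' Simulate perpendicular-distance datasets from a fitted detection function
#'
#' @param object a \code{\link{fit_detection}} result.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param n distances per replicate (default the fitted sample size).
#' @param ... unused.
#' @return data frame with \code{nsim} columns of \code{n} distances.
#' @export
simulate.detection_fit <- function(object, nsim = 1, seed = NULL,
                                   n = object$n_used, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, generate_perp_distances(
    object$key, object$par["sigma"],
    if (object$key == "hazard-rate") object$par["shape"],
    w = object$w, n = n))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot a detection-function fit
#'
#' Histogram of the fitted perpendicular distances (0.6-km bins by
#' default, the conventional plotting resolution for acoustic sperm-whale
#' surveys) with the expected counts under the fitted key overlaid.
#'
#' @param x a \code{\link{fit_detection}} result.
#' @param bin_km histogram bin width (km).
#' @param ... passed to \code{hist}.
#' @export
plot.detection_fit <- function(x, bin_km = 0.6, ...) {
  breaks <- seq(0, ceiling(x$w / bin_km) * bin_km, by = bin_km)
  h <- graphics::hist(x$distances, breaks = breaks,
                      xlab = "Perpendicular distance (km)",
                      main = sprintf("%s detection function", x$key), ...)
  xs <- seq(0, x$w, length.out = 200)
  graphics::lines(xs, predict(x, xs, "pdf") * x$n_used * bin_km,
                  lwd = 2)
  invisible(h)
}
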