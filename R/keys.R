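#' Detection-function keys
#'
#' Evaluate a line-transect detection function g(x), the probability of
#' detecting an animal at perpendicular distance \code{x} (km) from the
#' track line. Three standard keys are supported: \code{"uniform"}
#' (g(x) = 1), \code{"half-normal"} (g(x) = exp(-x^2 / 2 sigma^2)) and
#' \code{"hazard-rate"} (g(x) = 1 - exp(-(x/sigma)^-b)), the last having a
#' "shoulder" near zero that suits long-range acoustic detection.
#'
#' @param x numeric vector of perpendicular distances (km), non-negative.
#' @param key one of \code{"hazard-rate"}, \code{"half-normal"},
#'   \code{"uniform"}.
#' @param sigma scale parameter (km); unused for the uniform key.
#' @param shape hazard-rate shape parameter b (> 1); unused otherwise.
#' @return numeric vector of detection probabilities in [0, 1].
#' @examples
#' detection_g(c(0, 2, 4), "hazard-rate", sigma = 2, shape = 3)
#' @export
detection_g <- function(x, key = c("hazard-rate", "half-normal", "uniform"),
                        sigma = NULL, shape = NULL) {
  key <- match.arg(key)
  if (any(x < 0)) stop("perpendicular distances must be non-negative")
  switch(key,
    "uniform" = rep(1, length(x)),
    "half-normal" = {
      if (is.null(sigma) || sigma <= 0) stop("half-normal key needs sigma > 0")
      exp(-x^2 / (2 * sigma^2))
    },
    "hazard-rate" = {
      if (is.null(sigma) || sigma <= 0) stop("hazard-rate key needs sigma > 0")
      if (is.null(shape) || shape <= 1) stop("hazard-rate key needs shape > 1")
      g <- 1 - exp(-(x / sigma)^(-shape))
      g[x == 0] <- 1  # limit of the key as x -> 0+
      g
    })
}

# Effective strip half-width of a key on [0, w]: mu = integral of g.
# Adaptive quadrature; the keys are smooth so the default tolerance is ample.
key_mu <- function(key, sigma = NULL, shape = NULL, w) {
  if (key == "uniform") return(w)
  stats::integrate(function(x) detection_g(x, key, sigma, shape),
                   lower = 0, upper = w, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

n_key_params <- function(key) {
  switch(key, "uniform" = 0L, "half-normal" = 1L, "hazard-rate" = 2L)
}
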