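test_that("truncation keeps order and reports removals", {
  set.seed(31)
  d <- c(runif(83, 0, 9), 9.8, 11)[sample(85)]
  kept <- truncate_distances(d, 9)
  expect_length(kept, 83)
  expect_equal(attr(kept, "n_removed"), 2)
  expect_equal(as.numeric(kept), d[d <= 9])  # order preserved

  expect_equal(as.numeric(truncate_distances(c(1, 2), 9)), c(1, 2))
  expect_warning(out <- truncate_distances(c(10, 12), 9), "exceed")
  expect_length(out, 0)
})

test_that("half-normal fit on flat data pushes the ESHW to the strip edge", {
  set.seed(32)
  x <- runif(5000, 0, 9)
  f <- fit_detection(x, "half-normal", 9)
  expect_gte(f$mu, 0.95 * 9)
})

test_that("hazard-rate MLE beats a parameter grid around it", {
  x <- generate_perp_distances("hazard-rate", 2, 3, w = 9, n = 5000,
                               seed = 13)
  f <- fit_detection(x, "hazard-rate", 9)
  negll <- function(s, b) {
    g <- detection_g(x, "hazard-rate", s, b)
    mu <- integrate(function(y) detection_g(y, "hazard-rate", s, b),
                    0, 9, rel.tol = 1e-10)$value
    -sum(log(pmax(g, 1e-300))) + length(x) * log(mu)
  }
  sg <- seq(f$par[["sigma"]] * 0.8, f$par[["sigma"]] * 1.2, length.out = 50)
  bg <- seq(f$par[["shape"]] * 0.8, f$par[["shape"]] * 1.2, length.out = 50)
  grid_min <- min(outer(sg, bg, Vectorize(negll)))
  expect_lte(-f$loglik, grid_min + 1e-6)
})

test_that("likelihood is invariant to distance order", {
  x <- generate_perp_distances("hazard-rate", 2, 3, w = 9, n = 400,
                               seed = 33)
  f1 <- fit_detection(x, "hazard-rate", 9)
  f2 <- fit_detection(rev(x), "hazard-rate", 9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$par, f2$par, tolerance = 1e-6)
})

test_that("ESHW quadrature matches closed forms and a trapezoid oracle", {
  fu <- fit_detection(runif(50, 0, 9), "uniform", 9)
  expect_identical(fu$mu, 9)
  expect_identical(fu$var_mu, 0)

  # half-normal with w >> sigma: mu -> sigma * sqrt(pi / 2)
  xh <- generate_perp_distances("half-normal", 1, w = 20, n = 2000, seed = 1)
  fh <- fit_detection(xh, "half-normal", 20)
  expect_equal(fh$mu, fh$par[["sigma"]] * sqrt(pi / 2), tolerance = 1e-6)

  f <- fit_detection(generate_perp_distances("hazard-rate", 2, 3, w = 9,
                                             n = 500, seed = 2),
                     "hazard-rate", 9)
  xs <- seq(0, 9, length.out = 1e6 + 1)
  gg <- detection_g(xs, "hazard-rate", f$par[["sigma"]], f$par[["shape"]])
  mu_trap <- sum((gg[-1] + gg[-length(gg)]) / 2) * 9 / 1e6
  expect_equal(f$mu, mu_trap, tolerance = 1e-6)
})

test_that("the detection pdf integrates to one and mu grows with w", {
  x <- generate_perp_distances("hazard-rate", 2, 3, w = 9, n = 800, seed = 3)
  f <- fit_detection(x, "hazard-rate", 9)
  total <- integrate(function(y) predict(f, y, type = "pdf"), 0, 9,
                     rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-6)
  mus <- vapply(c(3, 6, 9), function(w)
    integrate(function(y)
      detection_g(y, "hazard-rate", f$par[["sigma"]], f$par[["shape"]]),
      0, w)$value, numeric(1))
  expect_true(all(diff(mus) >= 0))
})

test_that("AIC selection recovers the generating key and breaks ties", {
  sel <- vapply(1:25, function(s) {
    x <- generate_perp_distances("hazard-rate", 2, 3, w = 9, n = 5000,
                                 seed = 100 + s)
    fits <- list(fit_detection(x, "half-normal", 9),
                 fit_detection(x, "hazard-rate", 9))
    select_model(fits)$key
  }, character(1))
  expect_gte(mean(sel == "hazard-rate"), 0.8)

  f1 <- fit_detection(runif(50, 0, 9), "uniform", 9)
  f2 <- f1; f2$AIC <- f1$AIC; f2$npar <- 2L; f2$key <- "hazard-rate"
  expect_equal(select_model(list(f2, f1))$key, "uniform")  # fewer params
  expect_equal(select_model(f1)$key, "uniform")
  expect_error(select_model(list()), "no converged")
})

test_that("fit contract: bounds, sample size, and accessor methods", {
  x <- generate_perp_distances("hazard-rate", 2, 3, w = 9, n = 500, seed = 4)
  expect_error(fit_detection(x, "hazard-rate", -1), "w must")
  expect_error(fit_detection(x[1:5], "hazard-rate", 9), "at least 10")
  expect_error(fit_detection(c(x, 12), "hazard-rate", 9), "truncate")
  f <- fit_detection(x, "hazard-rate", 9)
  expect_equal(f$AIC, 2 * 2 - 2 * f$loglik)
  expect_equal(f$cv_mu, sqrt(f$var_mu) / f$mu)
  expect_equal(unname(coef(f)), unname(f$par))
  expect_equal(dim(vcov(f)), c(2, 2))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  expect_equal(AIC(f), f$AIC)
  e <- eshw(f)
  expect_equal(e$mu_hat, f$mu)
  expect_true(e$ci[1] < f$mu && f$mu < e$ci[2])
  sims <- simulate(f, nsim = 2, seed = 1, n = 50)
  expect_equal(dim(sims), c(50, 2))
  expect_true(all(sims >= 0 & sims <= 9))
})
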