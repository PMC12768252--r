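mc <- membrane_constants()
sig5 <- mN_per_m(c(5, 6, 7, 8, 10))

test_that("noiseless Arrhenius rates give exact edge-tension recovery", {
  k <- rupture_rate(A = 100, Gamma = pN(5), sigma_e = sig5, constants = mc)
  fit <- fit_edge_tension(data.frame(sigma_e = sig5, k_r = k), constants = mc)
  expect_equal(fit$Gamma, pN(5), tolerance = 1e-10)
  expect_equal(fit$A, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # slope carries the barrier scale: Gamma = sqrt(-slope kBT / pi)
  expect_equal(fit$slope, -pi * (5e-12)^2 / (mc$k_B * mc$T), tolerance = 1e-10)
})

test_that("edge tension estimate is unbiased under lognormal rate noise", {
  set.seed(61)
  k0 <- rupture_rate(A = 100, Gamma = pN(5), sigma_e = sig5, constants = mc)
  gammas <- replicate(500, {
    k <- k0 * exp(rnorm(5, 0, 0.1))
    fit_edge_tension(data.frame(sigma_e = sig5, k_r = k), constants = mc)$Gamma
  })
  expect_lt(abs(mean(gammas) - pN(5)) / pN(5), 0.02)
  # delta-method se agrees with the Monte-Carlo spread within 20%
  fit <- fit_edge_tension(
    data.frame(sigma_e = sig5, k_r = k0 * exp(rnorm(5, 0, 0.1))),
    constants = mc)
  mc_se <- sd(gammas)
  expect_lt(abs(fit$Gamma_se - mc_se) / mc_se, 0.5)
  # the average delta-method se is the sharper 20% check
  ses <- replicate(200, {
    k <- k0 * exp(rnorm(5, 0, 0.1))
    fit_edge_tension(data.frame(sigma_e = sig5, k_r = k),
                     constants = mc)$Gamma_se
  })
  expect_lt(abs(mean(ses) - mc_se) / mc_se, 0.2)
})

test_that("non-physical (rising) rate trends are rejected", {
  k_rising <- c(0.01, 0.02, 0.05, 0.1, 0.3) # increases with 1/(sigma+B)
  expect_error(
    fit_edge_tension(data.frame(sigma_e = rev(sig5), k_r = k_rising),
                     constants = mc),
    "non-physical")
  expect_error(
    fit_edge_tension(data.frame(sigma_e = mN_per_m(c(8, 8, 8)),
                                k_r = c(0.1, 0.11, 0.12)), constants = mc),
    "3 distinct tensions")
  expect_error(
    fit_edge_tension(data.frame(sigma_e = sig5, k_r = c(1, 1, 1, 1, 1),
                                gra_mole_percent = c(0, 0, 0, 1, 1)),
                     constants = mc),
    "mix compositions")
})

test_that("Gamma is invariant to rescaling the attempt frequency", {
  k <- rupture_rate(A = 100, Gamma = pN(7), sigma_e = sig5, constants = mc)
  f1 <- fit_edge_tension(data.frame(sigma_e = sig5, k_r = k), constants = mc)
  f2 <- fit_edge_tension(data.frame(sigma_e = sig5, k_r = 10 * k),
                         constants = mc)
  expect_equal(f1$Gamma, f2$Gamma, tolerance = 1e-12)
  expect_equal(f2$A, 10 * f1$A, tolerance = 1e-8)
})

test_that("inverse-variance weighting uses ln-scale weights", {
  k <- rupture_rate(A = 100, Gamma = pN(5), sigma_e = sig5, constants = mc)
  d <- data.frame(sigma_e = sig5, k_r = k, k_r_se = 0.1 * k)
  fw <- fit_edge_tension(d, constants = mc, weighting = "inverse_variance")
  # equal relative errors reduce to the unweighted fit
  fu <- fit_edge_tension(d, constants = mc)
  expect_equal(fw$Gamma, fu$Gamma, tolerance = 1e-10)
  d$k_r_se <- NULL
  expect_error(fit_edge_tension(d, constants = mc,
                                weighting = "inverse_variance"), "k_r_se")
})

test_that("predicted rate curves reproduce and round-trip the fit", {
  k <- rupture_rate(A = 100, Gamma = pN(5), sigma_e = sig5, constants = mc)
  fit <- fit_edge_tension(data.frame(sigma_e = sig5, k_r = k), constants = mc)
  # at the fitted points the prediction lies on the fitted line in ln space
  x <- 1 / (sig5 + fit$B)
  expect_equal(log(predict(fit)), fit$intercept + fit$slope * x,
               tolerance = 1e-10)
  # strictly increasing in tension
  grid <- mN_per_m(seq(4, 11, by = 0.5))
  expect_true(all(diff(predict(fit, grid)) > 0))
  # idempotence: refitting the predictions returns the same parameters
  refit <- fit_edge_tension(data.frame(sigma_e = grid,
                                       k_r = predict(fit, grid)),
                            constants = mc)
  expect_equal(refit$Gamma, fit$Gamma, tolerance = 1e-10)
  expect_equal(refit$A, fit$A, tolerance = 1e-8)
})

test_that("confidence interval is a t-based delta-method interval", {
  set.seed(71)
  k0 <- rupture_rate(A = 100, Gamma = pN(6), sigma_e = sig5, constants = mc)
  fit <- fit_edge_tension(
    data.frame(sigma_e = sig5, k_r = k0 * exp(rnorm(5, 0, 0.05))),
    constants = mc)
  ci <- confint(fit)
  tq <- qt(0.975, df = 3)
  expect_equal(unname(ci["upper"] - ci["lower"]), 2 * tq * fit$Gamma_se,
               tolerance = 1e-10)
  expect_true(ci["lower"] < fit$Gamma && fit$Gamma < ci["upper"])
})

test_that("biphasic quadratic is recovered exactly from exact points", {
  # Gamma(phi) = 9.6 - 50 phi + 400 phi^2 pN, i.e. a = -50, b = -400
  ph <- c(0, 0.02, 0.05)
  g <- pN(9.6 - 50 * ph + 400 * ph^2)
  fit <- fit_biphasic(ph, g)
  expect_equal(fit$Gamma0, pN(9.6), tolerance = 1e-10)
  expect_equal(fit$a, pN(-50), tolerance = 1e-8)
  expect_equal(fit$b, pN(-400), tolerance = 1e-6)
  # a fourth consistent point changes nothing and leaves zero residual
  ph4 <- c(ph, 0.04)
  fit4 <- fit_biphasic(ph4, pN(9.6 - 50 * ph4 + 400 * ph4^2))
  expect_equal(coef(fit4), coef(fit), tolerance = 1e-8)
  expect_equal(fit4$rss, 0, tolerance = 1e-40)
  expect_error(fit_biphasic(c(0, 0.1), pN(c(9, 8))), "3 distinct")
})

test_that("biphasic fit minimizes the residual sum of squares", {
  # seven (phi, Gamma) pairs shaped like a biphasic composition series
  ph <- c(0, 0.0001, 0.0005, 0.001, 0.01, 0.03, 0.05)
  g <- pN(c(9.6, 5.6, 3.4, 4.5, 6.5, 6.3, 6.8))
  fit <- fit_biphasic(ph, g)
  rss <- function(p) sum((g - (p[1] + p[2] * ph - p[3] * ph^2))^2)
  base <- rss(coef(fit))
  expect_equal(base, fit$rss, tolerance = 1e-10)
  # brute-force refinement around the solution finds nothing better
  set.seed(81)
  for (i in 1:200) {
    perturbed <- coef(fit) * (1 + runif(3, -0.05, 0.05))
    expect_gte(rss(perturbed), base - 1e-40)
  }
  # nearby optim start converges back to the same coefficients
  opt <- optim(coef(fit) * 1.2, rss, control = list(reltol = 1e-14,
                                                    maxit = 5000))
  expect_lte(base, opt$value + 1e-30)
})

test_that("weighted biphasic fit honors measurement uncertainty", {
  ph <- c(0, 0.01, 0.03, 0.05)
  g_true <- pN(9.6 - 60 * ph + 500 * ph^2)
  g <- g_true; g[2] <- g[2] * 1.5 # one wild, very uncertain point
  se <- pN(c(0.1, 10, 0.1, 0.1))
  fw <- fit_biphasic(ph, g, Gamma_se = se)
  # the down-weighted outlier barely moves the curve
  expect_equal(predict(fw, ph)[c(1, 3, 4)], g_true[c(1, 3, 4)],
               tolerance = 0.02)
})
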