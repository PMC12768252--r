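des_small <- experiment_design(sigma_targets = mN_per_m(8),
                               n_vesicles = c(12, 18), n_trials = c(2, 4))

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_condition(des_small, gra = 0, sigma = mN_per_m(8),
                           rate = 0.1, seed = 9)
  s2 <- simulate_condition(des_small, gra = 0, sigma = mN_per_m(8),
                           rate = 0.1, seed = 9)
  expect_identical(s1, s2)
  d1 <- simulate_tension_grid(
    experiment_design(gra_mole_percents = c(0, 1),
                      sigma_targets = mN_per_m(c(6, 8))),
    truth = list(Gamma = pN(8), A = 300), seed = 13)
  d2 <- simulate_tension_grid(
    experiment_design(gra_mole_percents = c(0, 1),
                      sigma_targets = mN_per_m(c(6, 8))),
    truth = list(Gamma = pN(8), A = 300), seed = 13)
  expect_identical(d1, d2)
})

test_that("adding a condition does not perturb existing cells", {
  base <- simulate_tension_grid(
    experiment_design(sigma_targets = mN_per_m(c(6, 8))),
    truth = list(Gamma = pN(8), A = 300), seed = 17)
  wider <- simulate_tension_grid(
    experiment_design(sigma_targets = mN_per_m(c(6, 8, 10))),
    truth = list(Gamma = pN(8), A = 300), seed = 17)
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "truth") <- attr(d, "design") <- attr(d, "seed") <- NULL
    rownames(d) <- NULL
    d
  }
  for (s in mN_per_m(c(6, 8))) {
    expect_identical(strip(base[base$sigma_e == s, ]),
                     strip(wider[wider$sigma_e == s, ]))
  }
})

test_that("degenerate rates behave as limits demand", {
  # zero rate: every vesicle survives the window
  s0 <- simulate_condition(des_small, 0, mN_per_m(8), rate = 0, seed = 3)
  expect_true(all(s0$censored))
  # enormous rate: rupture at the first frame with probability ~ 1
  sfast <- simulate_condition(des_small, 0, mN_per_m(8), rate = 100, seed = 3)
  expect_true(all(!sfast$censored))
  expect_true(all(sfast$rupture_time == 1))
})

test_that("trial structure and condition labels are honored", {
  set.seed(23)
  recs <- simulate_condition(des_small, gra = 3, sigma = mN_per_m(8),
                             rate = 0.05, seed = 29)
  counts <- table(recs$trial_id)
  expect_equal(nrow(recs), sum(counts))
  expect_true(all(counts >= 12 & counts <= 18))
  expect_true(length(counts) >= 2 && length(counts) <= 4)
  expect_true(all(recs$gra_mole_percent == 3))
  expect_true(all(recs$sigma_e == mN_per_m(8)))
  expect_true(all(recs$radius >= 14e-6 & recs$radius <= 16e-6))
  # grid covers the full factorial
  grid <- simulate_tension_grid(
    experiment_design(gra_mole_percents = c(0, 1, 3),
                      sigma_targets = mN_per_m(c(6, 8))),
    truth = list(Gamma = pN(8), A = 300), seed = 31)
  cells <- unique(grid[, c("gra_mole_percent", "sigma_e")])
  expect_equal(nrow(cells), 3 * 2)
})

test_that("rupture fraction matches the exponential CDF at large n", {
  des_big <- experiment_design(sigma_targets = mN_per_m(8),
                               n_vesicles = 10000, n_trials = 1)
  recs <- simulate_condition(des_big, 0, mN_per_m(8), rate = 0.05, seed = 37)
  p_hat <- rupture_probability(recs, 60)
  p_true <- 1 - exp(-0.05 * 60)
  se <- sqrt(p_true * (1 - p_true) / nrow(recs))
  expect_lt(abs(p_hat - p_true), 3 * se)
  # censoring fraction is the survival complement
  expect_lt(abs(mean(recs$censored) - exp(-0.05 * 60)), 3 * se)
})

test_that("latent rupture times are exponential before quantization", {
  # a fine frame grid makes quantization negligible
  des_fine <- experiment_design(sigma_targets = mN_per_m(8),
                                n_vesicles = 5000, n_trials = 1,
                                window = 60, frame_step = 0.001)
  recs <- simulate_condition(des_fine, 0, mN_per_m(8), rate = 0.1, seed = 41)
  t_obs <- recs$rupture_time[!recs$censored]
  # compare observed quantiles with the window-truncated exponential
  probs <- seq(0.05, 0.95, by = 0.1)
  q_emp <- quantile(t_obs, probs, names = FALSE)
  trunc_cdf_inv <- function(p) -log(1 - p * (1 - exp(-0.1 * 60))) / 0.1
  q_theory <- trunc_cdf_inv(probs)
  expect_lt(max(abs(q_emp - q_theory) / q_theory), 0.1)
})

test_that("simulated survival data carry the generating rate", {
  des <- experiment_design(sigma_targets = mN_per_m(8),
                           n_vesicles = 2000, n_trials = 2)
  recs <- simulate_condition(des, 0, mN_per_m(8), rate = 0.08, seed = 43)
  fit <- fit_rate(recs, method = "ls")
  expect_lt(abs(fit$k_r - 0.08) / 0.08, 0.05)
})

test_that("biphasic truth yields a non-monotonic recovered edge-tension series", {
  # truth: minimum edge tension at phi = 0.025 within the sampled range
  G0 <- pN(9.6); a <- pN(-200); b <- pN(-4000)
  truth_gamma <- function(phi) biphasic_edge_tension(phi, G0, a, b)
  gras <- c(0, 1, 2.5, 5) # mole percent
  recovered <- vapply(seq_along(gras), function(i) {
    g_true <- truth_gamma(gras[i] / 100)
    des <- experiment_design(
      gra_mole_percents = gras[i],
      sigma_targets = design_tensions(g_true, A = 300),
      n_vesicles = 18, n_trials = 4)
    sim <- simulate_tension_grid(des,
                                 truth = list(Gamma0 = G0, a = a, b = b,
                                              A = 300), seed = 47 + i)
    fit_tension_scan(sim)$gamma$Gamma
  }, numeric(1))
  truth_series <- truth_gamma(gras / 100)
  # the recovered series dips and rises exactly where the truth does
  expect_identical(sign(diff(recovered)), sign(diff(truth_series)))
})

test_that("tension jitter spreads applied tensions around the target", {
  des_j <- experiment_design(sigma_targets = mN_per_m(8),
                             n_vesicles = 500, n_trials = 1,
                             tension_jitter = 0.05)
  recs <- simulate_condition(des_j, 0, mN_per_m(8), rate = 0.05, seed = 53)
  expect_gt(sd(recs$sigma_e), 0)
  expect_lt(abs(mean(log(recs$sigma_e / mN_per_m(8)))), 0.01)
})

test_that("design constructor rejects malformed designs", {
  expect_error(experiment_design(window = 60, frame_step = 7), "whole number")
  expect_error(experiment_design(n_vesicles = c(18, 12)), "count range")
  expect_error(experiment_design(diameter_range = c(32e-6, 28e-6)), "ordered")
  expect_error(simulate_tension_grid(des_small, truth = list(A = 100),
                                     seed = 1), "Gamma")
})
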