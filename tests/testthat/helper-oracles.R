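# Independent oracles used across tests. These deliberately avoid the
# package's closed forms: barriers by grid scan, fits by brute-force search.

# numeric maximizer of the prepore free energy over a dense radius grid
grid_scan_barrier <- function(Gamma, sigma_e, B, r_max = NULL, n = 20001) {
  if (is.null(r_max)) r_max <- 4 * Gamma / (sigma_e + B)
  r <- seq(0, r_max, length.out = n)
  u <- 2 * pi * r * Gamma - pi * (sigma_e + B) * r^2
  list(Ub = max(u), r_c = r[which.max(u)], dr = r[2] - r[1])
}

# brute-force 1-D least squares for the exponential survival fit
grid_search_rate <- function(times, p, lo = 1e-4, hi = 2, tol = 1e-8) {
  sse <- function(k) sum((exp(-k * times) - p)^2)
  while (hi - lo > tol) {
    ks <- seq(lo, hi, length.out = 201)
    vals <- vapply(ks, sse, numeric(1))
    i <- which.min(vals)
    lo <- ks[max(i - 1, 1)]
    hi <- ks[min(i + 1, length(ks))]
  }
  (lo + hi) / 2
}

# censored-exponential log-likelihood, maximized on a grid
grid_search_mle <- function(times, censored, window, lo = 1e-4, hi = 1) {
  loglik <- function(k) {
    sum(ifelse(censored, -k * window, log(k) - k * times))
  }
  ks <- seq(lo, hi, length.out = 200001)
  ks[which.max(vapply(ks, loglik, numeric(1)))]
}

# quick builder for a survival_curve object from an analytic intact fraction
analytic_curve <- function(k, times = 0:60, n_total = 100) {
  p <- exp(-k * times)
  structure(
    list(times = times, p_intact = p, n_total = n_total,
         n_ruptured_by_end = round(n_total * (1 - p[length(p)])),
         window = max(times), sigma_e = 8e-3, gra_mole_percent = 0),
    class = "survival_curve"
  )
}

records_from_times <- function(times, n_censored = 0, window = 60,
                               sigma_e = 8e-3, gra = 0, trial = "t1") {
  n <- length(times) + n_censored
  vesicle_records(
    vesicle_id = seq_len(n), trial_id = trial, gra_mole_percent = gra,
    radius = 15e-6, sigma_e = sigma_e,
    rupture_time = c(times, rep(NA_real_, n_censored)),
    censored = c(rep(FALSE, length(times)), rep(TRUE, n_censored)),
    window = window
  )
}
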