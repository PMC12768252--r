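#' Design of a simulated rupture experiment
#'
#' Collects the experimental-design parameters that the stochastic simulator
#' reproduces: compositions, target tensions, trial structure, the 60 s
#' observation window, the 1 s acquisition frame, and the 28-32 um vesicle
#' diameter range typical of single-vesicle electroporation work.
#'
#' @param gra_mole_percents gramicidin A contents to simulate (mole %).
#' @param sigma_targets target lateral tensions (N/m).
#' @param n_vesicles vesicles per trial: a single count, or a length-2 range
#'   from which each trial's count is drawn uniformly (default `c(12, 18)`).
#' @param n_trials independent trials per condition: count or length-2 range
#'   (default `c(2, 4)`).
#' @param window observation window (s), default 60.
#' @param frame_step acquisition frame interval (s), default 1; the window
#'   must be a whole number of frames.
#' @param diameter_range vesicle diameter range (m), default 28-32 um.
#' @param tension_jitter lognormal sd of multiplicative per-vesicle tension
#'   error (models radius-measurement error); default 0 (tension exact at
#'   target, as when the field is set from the measured radius).
#' @return Object of class `"experiment_design"` (a named list).
#' @export
experiment_design <- function(gra_mole_percents = 0,
                              sigma_targets = mN_per_m(8),
                              n_vesicles = c(12, 18),
                              n_trials = c(2, 4),
                              window = 60, frame_step = 1,
                              diameter_range = c(28e-6, 32e-6),
                              tension_jitter = 0) {
  n_vesicles <- range_or_count(n_vesicles, "n_vesicles")
  n_trials <- range_or_count(n_trials, "n_trials")
  if (window <= 0 || frame_step <= 0 ||
      abs(window / frame_step - round(window / frame_step)) > 1e-9) {
    stop("window must be a positive whole number of frame steps",
         call. = FALSE)
  }
  if (length(diameter_range) != 2 || any(diameter_range <= 0) ||
      diff(diameter_range) < 0) {
    stop("diameter_range must be an ordered positive pair", call. = FALSE)
  }
  structure(
    list(gra_mole_percents = gra_mole_percents,
         sigma_targets = sigma_targets,
         n_vesicles = n_vesicles, n_trials = n_trials,
         window = window, frame_step = frame_step,
         diameter_range = diameter_range,
         tension_jitter = tension_jitter),
    class = "experiment_design"
  )
}

range_or_count <- function(x, name) {
  if (length(x) == 1) x <- c(x, x)
  if (length(x) != 2 || any(x < 1) || x[2] < x[1] ||
      any(x != round(x))) {
    stop(name, " must be a positive count or an ordered count range",
         call. = FALSE)
  }
  as.integer(x)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Simulated rupture experiment design\n")
  cat(sprintf("  GrA levels (mole%%): %s\n",
              paste(x$gra_mole_percents, collapse = ", ")))
  cat(sprintf("  tensions (mN/m): %s\n",
              paste(signif(to_mN_per_m(x$sigma_targets), 4), collapse = ", ")))
  cat(sprintf("  %d-%d vesicles/trial, %d-%d trials, window %g s @ %g s/frame\n",
              x$n_vesicles[1], x$n_vesicles[2], x$n_trials[1], x$n_trials[2],
              x$window, x$frame_step))
  invisible(x)
}

#' Choose tensions so expected kinetics are observable
#'
#' Single-vesicle rupture experiments pick tensions that make rupture
#' observable within the acquisition window: fast enough that a useful
#' fraction of vesicles ruptures in 60 s, slow enough that rupture is not
#' complete within the first frame. This helper inverts the Arrhenius law to
#' find the tensions at which the expected rate constant takes `n` values
#' log-spaced across `k_range` (default 0.02-0.22 1/s, the span typically
#' reported for this system).
#'
#' @param Gamma edge tension of the membrane being designed for (N).
#' @param A frequency factor (1/s).
#' @param B electrostatic tension component (N/m).
#' @param constants a [membrane_constants()] object.
#' @param k_range target rate-constant range (1/s), default `c(0.02, 0.22)`.
#' @param n number of tensions, default 5.
#' @return Numeric vector of tensions (N/m), increasing.
#' @examples
#' to_mN_per_m(design_tensions(pN(6), A = 100))
#' @export
design_tensions <- function(Gamma, A, B = 1.76e-3,
                            constants = membrane_constants(),
                            k_range = c(0.02, 0.22), n = 5) {
  constants <- as_membrane_constants(constants)
  stopifnot(length(k_range) == 2, all(k_range > 0), all(k_range < A))
  k <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n))
  kBT <- constants$k_B * constants$T
  sigma <- pi * Gamma^2 / (kBT * log(A / k)) - B
  if (any(sigma <= 0)) {
    stop("requested rates unreachable at positive tension; raise k_range ",
         "or lower Gamma", call. = FALSE)
  }
  sort(sigma)
}

#' Simulate one vesicle's rupture record
#'
#' Draws a radius uniformly on the design's diameter range, sets the field
#' so the vesicle experiences the target tension (mirroring the
#' measure-then-set-field protocol), draws a latent exponential rupture time
#' at the supplied rate, censors it against the observation window, and
#' quantizes observed times up to the acquisition frame grid. Censoring is
#' applied to the latent time: a rupture after the window closes is never
#' observed.
#'
#' @param design an [experiment_design()].
#' @param gra composition label (mole %).
#' @param sigma target lateral tension (N/m).
#' @param rate generating rupture rate constant (1/s); `rate = 0` yields an
#'   always-censored vesicle.
#' @param vesicle_id,trial_id labels for the record.
#' @param constants a [membrane_constants()] object (for the field map).
#' @return One-row [vesicle_records()] table. Uses and advances the current
#'   RNG state; seed control belongs to the callers
#'   ([simulate_condition()], [simulate_tension_grid()]).
#' @export
simulate_vesicle <- function(design, gra, sigma, rate,
                             vesicle_id = "v1", trial_id = "t1",
                             constants = membrane_constants()) {
  stopifnot(inherits(design, "experiment_design"), rate >= 0)
  radius <- stats::runif(1, design$diameter_range[1] / 2,
                         design$diameter_range[2] / 2)
  sigma_applied <- sigma
  if (design$tension_jitter > 0) {
    sigma_applied <- sigma * stats::rlnorm(1, 0, design$tension_jitter)
  }
  # the field is set per measured radius; recorded for provenance only
  field <- field_for_target_tension(radius, sigma_applied, constants)
  latent <- if (rate > 0) stats::rexp(1, rate) else Inf
  censored <- latent > design$window
  t_obs <- if (censored) NA_real_ else
    ceiling(latent / design$frame_step) * design$frame_step
  rec <- vesicle_records(
    vesicle_id = vesicle_id, trial_id = trial_id,
    gra_mole_percent = gra, radius = radius, sigma_e = sigma_applied,
    rupture_time = t_obs, censored = censored, window = design$window
  )
  rec$field <- field
  rec
}

#' Simulate all trials of one experimental condition
#'
#' Batches [simulate_vesicle()] into the trial structure of the design:
#' trial counts and per-trial vesicle counts are drawn from the design
#' ranges, and every record is labelled by trial.
#'
#' @inheritParams simulate_vesicle
#' @param seed optional integer; when supplied, the condition is simulated
#'   under its own RNG stream so results are reproducible in isolation.
#' @return A [vesicle_records()] table.
#' @export
simulate_condition <- function(design, gra, sigma, rate, seed = NULL,
                               constants = membrane_constants()) {
  run <- function() {
    n_tr <- sample_count(design$n_trials)
    recs <- lapply(seq_len(n_tr), function(tr) {
      n_v <- sample_count(design$n_vesicles)
      rows <- lapply(seq_len(n_v), function(v) {
        simulate_vesicle(design, gra, sigma, rate,
                         vesicle_id = sprintf("g%s_s%.3g_t%d_v%d",
                                              gra, to_mN_per_m(sigma), tr, v),
                         trial_id = sprintf("trial%d", tr),
                         constants = constants)
      })
      do.call(rbind, rows)
    })
    do.call(rbind, recs)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  validate_records(out)
}

sample_count <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-condition substream: adding a condition to the grid must
# not perturb the draws of existing ones.
condition_seed <- function(seed, i_gra, i_sigma) {
  as.integer((as.numeric(seed) + 100003 * i_gra + 1009 * i_sigma) %%
               2147483629)
}

#' Simulate a full composition-by-tension rupture dataset
#'
#' Generates the full factorial dataset behind a multi-tension,
#' multi-composition rupture study: for every (GrA%, tension) cell the
#' generating rate constant is computed from the supplied truth via the
#' Arrhenius law (with the edge tension either fixed or given by the
#' biphasic model), and the cell is simulated under its own deterministic
#' substream of the global seed.
#'
#' @param design an [experiment_design()].
#' @param truth a named list describing the generating model:
#'   `A` (frequency factor, 1/s), `B` (N/m, default 1.76e-3), and either
#'   `Gamma` (fixed edge tension, N) or `Gamma0`, `a`, `b` (biphasic model
#'   coefficients, N, applied to phi = mole%/100).
#' @param seed integer seed for the whole dataset.
#' @param constants a [membrane_constants()] object.
#' @return A [vesicle_records()] table with attributes `truth`, `design`,
#'   and `seed` (the provenance block written alongside the data by
#'   [write_simulation()]).
#' @examples
#' des <- experiment_design(sigma_targets = design_tensions(pN(6), 100),
#'                          n_vesicles = 15, n_trials = 3)
#' sim <- simulate_tension_grid(des, truth = list(Gamma = pN(6), A = 100),
#'                              seed = 1)
#' @export
simulate_tension_grid <- function(design, truth, seed,
                                  constants = membrane_constants()) {
  stopifnot(inherits(design, "experiment_design"))
  truth <- validate_truth(truth)
  cells <- expand.grid(i_gra = seq_along(design$gra_mole_percents),
                       i_sigma = seq_along(design$sigma_targets))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ig <- cells$i_gra[i]; is <- cells$i_sigma[i]
    gra <- design$gra_mole_percents[ig]
    sigma <- design$sigma_targets[is]
    rate <- truth_rate(truth, gra, sigma, constants)
    simulate_condition(design, gra, sigma, rate,
                       seed = condition_seed(seed, ig, is),
                       constants = constants)
  })
  recs <- validate_records(do.call(rbind, out))
  attr(recs, "truth") <- truth
  attr(recs, "design") <- design
  attr(recs, "seed") <- seed
  recs
}

validate_truth <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth[["A"]]), truth[["A"]] > 0)
  if (is.null(truth[["B"]])) truth$B <- 1.76e-3
  # [[ avoids partial matching: truth$Gamma must never pick up Gamma0
  has_fixed <- !is.null(truth[["Gamma"]])
  has_biphasic <- all(c("Gamma0", "a", "b") %in% names(truth))
  if (!has_fixed && !has_biphasic) {
    stop("truth must contain either Gamma, or Gamma0/a/b", call. = FALSE)
  }
  truth
}

truth_rate <- function(truth, gra, sigma, constants) {
  Gamma <- if (!is.null(truth[["Gamma"]])) truth[["Gamma"]] else
    biphasic_edge_tension(gra / 100, truth$Gamma0, truth$a, truth$b)
  rupture_rate(A = truth[["A"]], Gamma = Gamma, sigma_e = sigma, B = truth$B,
               constants = constants)
}
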