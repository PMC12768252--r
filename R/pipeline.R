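#' Full rupture-kinetics analysis of a composition-by-tension dataset
#'
#' Runs the whole inference chain on a per-vesicle record table: for every
#' (GrA%, tension) cell a rupture rate constant is fitted
#' ([fit_rate()]), for every GrA level the rates across tensions are
#' linearized to an edge tension ([fit_edge_tension()]), and when three or
#' more compositions are present the edge tensions are fitted to the
#' biphasic quadratic ([fit_biphasic()]).
#'
#' @param records a [vesicle_records()] table spanning one or more GrA
#'   levels, each at three or more tensions.
#' @param B electrostatic tension component (N/m), default 1.76e-3.
#' @param constants a [membrane_constants()] object.
#' @param rate_method `"ls"` (default; curve fit) or `"mle"`.
#' @param by_trial fit rates per trial and average (see [fit_rate()]).
#' @param weighting passed to [fit_edge_tension()]; `"inverse_variance"`
#'   requires rate standard errors, so it needs `by_trial = TRUE` or
#'   `rate_method = "mle"`.
#' @return Object of class `"tension_scan"`: list with
#'   `rates` (data frame: gra_mole_percent, sigma_e, k_r, k_r_se,
#'   r_squared, n, n_ruptured, p_rup_end), `edge_fits` (named list of
#'   [fit_edge_tension()] results per GrA level), `gamma` (data frame:
#'   gra_mole_percent, Gamma, Gamma_se), and `biphasic`
#'   ([fit_biphasic()] result or `NULL`).
#' @examples
#' des <- experiment_design(sigma_targets = design_tensions(pN(6), 100),
#'                          n_vesicles = 15, n_trials = 3)
#' sim <- simulate_tension_grid(des, truth = list(Gamma = pN(6), A = 100),
#'                              seed = 7)
#' scan <- fit_tension_scan(sim)
#' to_pN(scan$gamma$Gamma)
#' @export
fit_tension_scan <- function(records, B = 1.76e-3,
                             constants = membrane_constants(),
                             rate_method = c("ls", "mle"),
                             by_trial = FALSE,
                             weighting = c("none", "inverse_variance")) {
  rate_method <- match.arg(rate_method)
  weighting <- match.arg(weighting)
  records <- validate_records(as.data.frame(records))
  cells <- unique(records[, c("gra_mole_percent", "sigma_e")])
  cells <- cells[order(cells$gra_mole_percent, cells$sigma_e), ]
  rates <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$gra_mole_percent == cells$gra_mole_percent[i] &
      records$sigma_e == cells$sigma_e[i]
    cell <- records[sel, ]
    fit <- fit_rate(cell, method = rate_method, by_trial = by_trial)
    data.frame(gra_mole_percent = cells$gra_mole_percent[i],
               sigma_e = cells$sigma_e[i],
               k_r = fit$k_r, k_r_se = fit$k_r_se,
               r_squared = fit$r_squared,
               n = fit$n_used, n_ruptured = fit$n_ruptured,
               p_rup_end = fit$n_ruptured / fit$n_used)
  }))
  edge_fits <- list()
  gamma_rows <- list()
  for (g in unique(rates$gra_mole_percent)) {
    pts <- rates[rates$gra_mole_percent == g, ]
    if (length(unique(pts$sigma_e)) < 3) next
    fit <- fit_edge_tension(pts, B = B, constants = constants,
                            weighting = weighting)
    edge_fits[[as.character(g)]] <- fit
    gamma_rows[[as.character(g)]] <- data.frame(
      gra_mole_percent = g, Gamma = fit$Gamma, Gamma_se = fit$Gamma_se,
      A = fit$A, r_squared = fit$r_squared)
  }
  gamma <- if (length(gamma_rows) > 0) do.call(rbind, gamma_rows) else NULL
  biphasic <- NULL
  if (!is.null(gamma) && length(unique(gamma$gra_mole_percent)) >= 3) {
    biphasic <- fit_biphasic(gamma$gra_mole_percent, gamma$Gamma,
                             Gamma_se = gamma$Gamma_se, percent = TRUE)
  }
  structure(
    list(rates = rates, edge_fits = edge_fits, gamma = gamma,
         biphasic = biphasic, B = B, constants = constants,
         rate_method = rate_method, by_trial = by_trial,
         seed = attr(records, "seed"), truth = attr(records, "truth")),
    class = "tension_scan"
  )
}

#' @export
print.tension_scan <- function(x, ...) {
  cat(sprintf("Rupture-kinetics scan: %d condition cells, rate method %s\n",
              nrow(x$rates), x$rate_method))
  if (!is.null(x$gamma)) {
    cat("Edge tensions per composition:\n")
    g <- x$gamma
    for (i in seq_len(nrow(g))) {
      cat(sprintf("  GrA %g%%: Gamma = %.3g +/- %.2g pN (A = %.3g 1/s)\n",
                  g$gra_mole_percent[i], to_pN(g$Gamma[i]),
                  to_pN(g$Gamma_se[i]), g$A[i]))
    }
  }
  if (!is.null(x$biphasic)) print(x$biphasic)
  invisible(x)
}

#' Condition-level summary report
#'
#' Renders the scan as one row per condition cell — rate constant with its
#' uncertainty, cumulative rupture probability at the window end, and (per
#' composition) the inferred edge tension — as text or JSON. Reports embed
#' the package version, the simulation seed when the input carried one, and
#' a digest of the analysis settings, for provenance.
#'
#' @param scan a `"tension_scan"` from [fit_tension_scan()].
#' @param format `"text"` or `"json"`.
#' @param path optional file to write to; otherwise the report is returned
#'   (and printed, for text).
#' @return The rendered report, invisibly when printed/written: a character
#'   string (text) or a JSON string.
#' @export
report <- function(scan, format = c("text", "json"), path = NULL) {
  stopifnot(inherits(scan, "tension_scan"))
  format <- match.arg(format)
  config <- sprintf("B=%g;method=%s;by_trial=%s;T=%g",
                    scan$B, scan$rate_method, scan$by_trial,
                    scan$constants$T)
  digest <- sprintf("%08x", sum(utf8ToInt(config) *
                                  seq_along(utf8ToInt(config))) %% 0xffffffff)
  version <- as.character(utils::packageVersion("guvpore"))
  if (format == "json") {
    obj <- list(
      version = version, seed = scan$seed, config = config,
      config_digest = digest,
      conditions = transform(scan$rates,
                             sigma_mn_per_m = to_mN_per_m(sigma_e),
                             sigma_e = NULL),
      edge_tension = if (!is.null(scan$gamma)) transform(
        scan$gamma, Gamma_pN = to_pN(Gamma), Gamma_se_pN = to_pN(Gamma_se),
        Gamma = NULL, Gamma_se = NULL) else NULL,
      biphasic = if (!is.null(scan$biphasic)) list(
        Gamma0_pN = to_pN(scan$biphasic$Gamma0),
        a_pN = to_pN(scan$biphasic$a), b_pN = to_pN(scan$biphasic$b),
        rss = scan$biphasic$rss) else NULL
    )
    out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
    if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
    return(out)
  }
  lines <- c(
    sprintf("guvpore %s rupture-kinetics report", version),
    sprintf("config: %s  digest: %s  seed: %s", config, digest,
            if (is.null(scan$seed)) "none" else scan$seed),
    "",
    sprintf("%8s %12s %22s %10s", "GrA %", "sigma (mN/m)",
            "k_r (1/s)", "P_rup(end)")
  )
  r <- scan$rates
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%8g %12.3g %12.4g +/- %-7.2g %10.2f",
      r$gra_mole_percent[i], to_mN_per_m(r$sigma_e[i]),
      r$k_r[i], r$k_r_se[i], r$p_rup_end[i]))
  }
  if (!is.null(scan$gamma)) {
    lines <- c(lines, "", "edge tension per composition:")
    g <- scan$gamma
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf(
        "  GrA %g%%: Gamma = %.3g +/- %.2g pN, A = %.3g 1/s, R^2 = %.3f",
        g$gra_mole_percent[i], to_pN(g$Gamma[i]), to_pN(g$Gamma_se[i]),
        g$A[i], g$r_squared[i]))
    }
  }
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  cat(out, "\n")
  invisible(out)
}
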