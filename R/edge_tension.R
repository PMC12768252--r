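#' Infer pore-edge tension from rate constants at multiple tensions
#'
#' Linearizes the Arrhenius rupture law: taking logs of
#' \eqn{k_r = A\exp[-\pi\Gamma^2/((\sigma_e+B)k_BT)]} gives
#' \deqn{\ln k_r = \ln A - \frac{\pi\Gamma^2}{k_B T}\cdot\frac{1}{\sigma_e+B},}
#' an affine relation in \eqn{x = 1/(\sigma_e + B)}. An ordinary (or
#' inverse-variance weighted) least-squares line then yields the edge tension
#' from the slope, \eqn{\Gamma = \sqrt{-\mathrm{slope}\cdot k_B T/\pi}}, and
#' the attempt frequency from the intercept, \eqn{A = e^{\mathrm{intercept}}}.
#' The standard error of \eqn{\Gamma} follows by the delta method,
#' \eqn{se_\Gamma = |k_B T/(2\pi\Gamma)|\,se_{\mathrm{slope}}}.
#'
#' @param data data frame with columns `sigma_e` (N/m) and `k_r` (1/s),
#'   optionally `k_r_se` (needed for `weighting = "inverse_variance"`).
#'   All rows must belong to one composition.
#' @param B electrostatic tension component (N/m), default 1.76e-3. Passed
#'   explicitly (not absorbed into `sigma_e`) so sensitivity of the inferred
#'   edge tension to `B` can be scanned.
#' @param constants a [membrane_constants()] object (supplies `k_B T`).
#' @param weighting `"none"` (default; the conventional unweighted fit) or
#'   `"inverse_variance"`, which weights each point by
#'   \eqn{(k_r/se_{k_r})^2}, the inverse variance of \eqn{\ln k_r}.
#' @return Object of class `"edge_tension_fit"`: list with `slope`,
#'   `slope_se`, `intercept`, `Gamma` (N), `Gamma_se` (N), `A` (1/s),
#'   `r_squared`, `n_points`, `df`, the underlying `lm` fit and inputs.
#' @examples
#' mc <- membrane_constants()
#' sig <- mN_per_m(c(5, 6, 7, 8, 10))
#' k <- rupture_rate(A = 100, Gamma = pN(5), sigma_e = sig, constants = mc)
#' fit <- fit_edge_tension(data.frame(sigma_e = sig, k_r = k), constants = mc)
#' to_pN(fit$Gamma) # 5
#' @seealso [confint.edge_tension_fit()], [predict.edge_tension_fit()]
#' @export
fit_edge_tension <- function(data, B = 1.76e-3,
                             constants = membrane_constants(),
                             weighting = c("none", "inverse_variance")) {
  constants <- as_membrane_constants(constants)
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data), all(c("sigma_e", "k_r") %in% names(data)))
  if (any(!is.finite(data$sigma_e)) || any(data$sigma_e <= 0)) {
    stop("sigma_e must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(data$k_r)) || any(data$k_r <= 0)) {
    stop("k_r must be finite and strictly positive (its log is taken)",
         call. = FALSE)
  }
  if ("gra_mole_percent" %in% names(data) &&
      length(unique(data$gra_mole_percent)) > 1) {
    stop("points mix compositions; fit one GrA level at a time", call. = FALSE)
  }
  if (length(unique(signif(data$sigma_e, 10))) < 3) {
    stop("need at least 3 distinct tensions to fit the line", call. = FALSE)
  }
  x <- 1 / (data$sigma_e + B)
  y <- log(data$k_r)
  w <- NULL
  if (weighting == "inverse_variance") {
    if (!("k_r_se" %in% names(data)) || any(!is.finite(data$k_r_se)) ||
        any(data$k_r_se <= 0)) {
      stop("inverse-variance weighting needs positive k_r_se for every point",
           call. = FALSE)
    }
    w <- (data$k_r / data$k_r_se)^2
  }
  dfit <- data.frame(x = x, y = y)
  lmfit <- if (is.null(w)) stats::lm(y ~ x, data = dfit)
           else stats::lm(y ~ x, data = dfit, weights = w)
  # noiseless (validation) inputs fit perfectly; summary.lm warns about it
  sm <- withCallingHandlers(
    summary(lmfit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- sm$coefficients
  slope <- cf["x", "Estimate"]
  slope_se <- cf["x", "Std. Error"]
  if (slope >= 0) {
    stop("non-physical fit: rupture rate must decrease with 1/(sigma_e + B)",
         call. = FALSE)
  }
  kBT <- constants$k_B * constants$T
  Gamma <- sqrt(-slope * kBT / pi)
  Gamma_se <- abs(kBT / (2 * pi * Gamma)) * slope_se
  structure(
    list(slope = slope, slope_se = slope_se,
         intercept = cf["(Intercept)", "Estimate"],
         intercept_se = cf["(Intercept)", "Std. Error"],
         Gamma = Gamma, Gamma_se = Gamma_se,
         A = exp(cf["(Intercept)", "Estimate"]),
         r_squared = sm$r.squared,
         n_points = nrow(data), df = lmfit$df.residual,
         B = B, constants = constants, weighting = weighting,
         data = data, lm = lmfit),
    class = "edge_tension_fit"
  )
}

#' @export
print.edge_tension_fit <- function(x, ...) {
  cat("Pore-edge tension fit (Arrhenius linearization)\n")
  cat(sprintf("  %d tensions, weighting: %s, R^2 = %.4f\n",
              x$n_points, x$weighting, x$r_squared))
  cat(sprintf("  Gamma = %.3g +/- %.2g pN,  A = %.3g 1/s\n",
              to_pN(x$Gamma), to_pN(x$Gamma_se), x$A))
  invisible(x)
}

#' @export
summary.edge_tension_fit <- function(object, ...) {
  ci <- confint(object)
  out <- c(object[c("slope", "slope_se", "intercept", "Gamma", "Gamma_se",
                    "A", "r_squared", "n_points", "B", "weighting")],
           list(Gamma_ci = ci))
  class(out) <- "summary.edge_tension_fit"
  out
}

#' @export
print.summary.edge_tension_fit <- function(x, ...) {
  cat("Arrhenius linearization of rupture rates\n")
  cat(sprintf("  slope     %.4g +/- %.2g (ln k_r per (N/m)^-1)\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept %.4g (A = %.4g 1/s)\n", x$intercept, x$A))
  cat(sprintf("  Gamma     %.4g +/- %.2g pN  [95%% CI %.4g, %.4g]\n",
              to_pN(x$Gamma), to_pN(x$Gamma_se),
              to_pN(x$Gamma_ci[1]), to_pN(x$Gamma_ci[2])))
  cat(sprintf("  R^2 = %.4f on %d points (B = %g mN/m, %s weights)\n",
              x$r_squared, x$n_points, to_mN_per_m(x$B), x$weighting))
  invisible(x)
}

#' @export
coef.edge_tension_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    Gamma = object$Gamma, A = object$A)
}

#' Confidence interval for the inferred edge tension
#'
#' Delta-method interval on \eqn{\Gamma} using the t distribution with the
#' regression's residual degrees of freedom.
#'
#' @param object an `"edge_tension_fit"`.
#' @param parm ignored (only `Gamma` is interval-ized).
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return Length-2 numeric vector (lower, upper), in newtons.
#' @export
confint.edge_tension_fit <- function(object, parm = "Gamma", level = 0.95,
                                     ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df)
  lo <- max(object$Gamma - tq * object$Gamma_se, 0)
  hi <- object$Gamma + tq * object$Gamma_se
  c(lower = lo, upper = hi)
}

#' Predicted rupture rates from an edge-tension fit
#'
#' Evaluates the Arrhenius law with the fitted edge tension and attempt
#' frequency on a grid of applied tensions, e.g. to render fitted
#' rate-versus-tension curves.
#'
#' @param object an `"edge_tension_fit"`.
#' @param sigma_e tensions (N/m) at which to predict; defaults to the fitted
#'   points.
#' @param ... unused.
#' @return Numeric vector of rate constants (1/s).
#' @export
predict.edge_tension_fit <- function(object, sigma_e = NULL, ...) {
  if (is.null(sigma_e)) sigma_e <- object$data$sigma_e
  rupture_rate(A = object$A, Gamma = object$Gamma, sigma_e = sigma_e,
               B = object$B, constants = object$constants)
}

#' @export
plot.edge_tension_fit <- function(x, ...,
                                  xlab = expression(1 / (sigma[e] + B) ~ (m / N)),
                                  ylab = expression(ln ~ k[r])) {
  xx <- 1 / (x$data$sigma_e + x$B)
  graphics::plot(xx, log(x$data$k_r), xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Fit the biphasic edge-tension model over peptide content
#'
#' Least-squares fit of the quadratic
#' \eqn{\Gamma(\phi) = \Gamma_0 + a\phi - b\phi^2} to edge tensions measured
#' at several peptide mole fractions. Note the sign convention: the
#' coefficient reported as `b` multiplies \eqn{-\phi^2}, so the fitted
#' polynomial is `Gamma0 + a*phi - b*phi^2`. A non-monotonic (biphasic)
#' dependence shows up as an interior vertex at \eqn{\phi^* = a/(2b)}.
#'
#' @param phi peptide mole fractions in \[0, 1\] (at least 3 distinct
#'   values). Use `percent = TRUE` to pass mole percent instead.
#' @param Gamma edge tensions (N), one per `phi`.
#' @param Gamma_se optional standard errors (N); when supplied the fit is
#'   weighted by `1/Gamma_se^2`.
#' @param percent if `TRUE`, `phi` is interpreted as mole percent and
#'   divided by 100.
#' @return Object of class `"biphasic_fit"`: list with `Gamma0`, `a`, `b`
#'   (all N, Eq.-convention signs), `rss`, `n_points`, `phi`, `Gamma`,
#'   and the underlying `lm` fit.
#' @examples
#' ph <- c(0, 0.02, 0.05)
#' g <- biphasic_edge_tension(ph, Gamma0 = pN(9.6), a = pN(-50), b = pN(-400))
#' coef(fit_biphasic(ph, g)) # recovers 9.6e-12, -5e-11, -4e-10
#' @export
fit_biphasic <- function(phi, Gamma, Gamma_se = NULL, percent = FALSE) {
  if (percent) phi <- phi / 100
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    stop("mole fractions must lie in [0, 1] (use percent = TRUE for mole %)",
         call. = FALSE)
  }
  if (length(phi) != length(Gamma)) {
    stop("phi and Gamma must have equal length", call. = FALSE)
  }
  if (length(unique(phi)) < 3) {
    stop("need at least 3 distinct mole fractions for the quadratic",
         call. = FALSE)
  }
  d <- data.frame(phi = phi, Gamma = Gamma)
  w <- if (!is.null(Gamma_se)) 1 / Gamma_se^2 else NULL
  lmfit <- if (is.null(w)) stats::lm(Gamma ~ phi + I(phi^2), data = d)
           else stats::lm(Gamma ~ phi + I(phi^2), data = d, weights = w)
  if (any(is.na(stats::coef(lmfit)))) {
    stop("degenerate design: quadratic coefficients not identifiable",
         call. = FALSE)
  }
  cf <- stats::coef(lmfit)
  structure(
    list(Gamma0 = unname(cf[1]), a = unname(cf[2]), b = -unname(cf[3]),
         rss = sum(stats::residuals(lmfit)^2),
         n_points = length(phi), phi = phi, Gamma = Gamma, lm = lmfit),
    class = "biphasic_fit"
  )
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("Biphasic edge-tension fit: Gamma(phi) = Gamma0 + a*phi - b*phi^2\n")
  cat(sprintf("  Gamma0 = %.3g pN, a = %.3g pN, b = %.3g pN\n",
              to_pN(x$Gamma0), to_pN(x$a), to_pN(x$b)))
  if (x$b != 0) {
    v <- x$a / (2 * x$b)
    cat(sprintf("  vertex at phi* = %.4g (%.3g mole%%)\n", v, 100 * v))
  }
  cat(sprintf("  RSS = %.3g N^2 on %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(Gamma0 = object$Gamma0, a = object$a, b = object$b)
}

#' @export
predict.biphasic_fit <- function(object, phi = NULL, ...) {
  if (is.null(phi)) phi <- object$phi
  object$Gamma0 + object$a * phi - object$b * phi^2
}
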