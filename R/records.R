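#' Per-vesicle rupture records
#'
#' Builds the atomic observation table of a rupture experiment: one row per
#' vesicle, carrying its identity, composition, geometry, applied tension,
#' and a possibly right-censored rupture time. A vesicle still intact when
#' the observation window closes is `censored = TRUE` and has no rupture
#' time; its time is known only to exceed the window.
#'
#' @param vesicle_id vesicle labels (coerced to character).
#' @param trial_id independent-experiment labels (coerced to character).
#' @param gra_mole_percent gramicidin A content, mole percent (0-5 typical).
#' @param radius vesicle radius (m). A warning is issued for radii outside
#'   10-20 um, the plausible range for vesicles of 28-32 um diameter.
#' @param sigma_e applied lateral tension (N/m).
#' @param rupture_time rupture time (s), `NA` for censored vesicles.
#' @param censored logical; `TRUE` if intact at the end of the window.
#' @param window observation window (s), default 60.
#'
#' @return A `data.frame` of class `"vesicle_records"` with the columns
#'   above.
#' @examples
#' vesicle_records(1:3, trial_id = 1, gra_mole_percent = 0,
#'                 radius = um(15), sigma_e = mN_per_m(8),
#'                 rupture_time = c(2, 4, NA), censored = c(FALSE, FALSE, TRUE))
#' @export
vesicle_records <- function(vesicle_id, trial_id, gra_mole_percent, radius,
                            sigma_e, rupture_time, censored, window = 60) {
  df <- data.frame(
    vesicle_id = as.character(vesicle_id),
    trial_id = as.character(trial_id),
    gra_mole_percent = as.numeric(gra_mole_percent),
    radius = as.numeric(radius),
    sigma_e = as.numeric(sigma_e),
    rupture_time = as.numeric(rupture_time),
    censored = as.logical(censored),
    window = as.numeric(window),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

validate_records <- function(df, context = "record") {
  required <- c("vesicle_id", "trial_id", "gra_mole_percent", "radius",
                "sigma_e", "rupture_time", "censored", "window")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no records", call. = FALSE)
  if (any(is.na(df$censored))) {
    stop(bad_rows(df, is.na(df$censored), context,
                  "censored flag must be true/false"), call. = FALSE)
  }
  contradiction <- !df$censored & is.na(df$rupture_time)
  if (any(contradiction)) {
    stop(bad_rows(df, contradiction, context,
                  "uncensored record lacks a rupture time"), call. = FALSE)
  }
  contradiction <- df$censored & !is.na(df$rupture_time)
  if (any(contradiction)) {
    stop(bad_rows(df, contradiction, context,
                  "censored record must not carry a rupture time"),
         call. = FALSE)
  }
  if (any(!is.finite(df$window)) || any(df$window <= 0)) {
    stop("observation window must be finite and positive", call. = FALSE)
  }
  obs <- !df$censored
  bad_time <- obs & (df$rupture_time <= 0 | df$rupture_time > df$window)
  if (any(bad_time, na.rm = TRUE)) {
    stop(bad_rows(df, bad_time, context,
                  "rupture time must lie in (0, window]"), call. = FALSE)
  }
  if (any(!is.finite(df$radius)) || any(df$radius <= 0)) {
    stop("vesicle radius must be finite and positive", call. = FALSE)
  }
  if (any(df$radius < 10e-6 | df$radius > 20e-6)) {
    warning("some radii fall outside the plausible 10-20 um range",
            call. = FALSE)
  }
  if (any(!is.finite(df$sigma_e)) || any(df$sigma_e < 0)) {
    stop("applied tension sigma_e must be finite and non-negative",
         call. = FALSE)
  }
  if (any(df$gra_mole_percent < 0 | df$gra_mole_percent > 100)) {
    stop("gra_mole_percent must lie in [0, 100]", call. = FALSE)
  }
  class(df) <- c("vesicle_records", "data.frame")
  df
}

bad_rows <- function(df, which, context, msg) {
  rows <- utils::head(which(which), 5)
  sprintf("%s (%s rows: %s)", msg, context, paste(rows, collapse = ", "))
}

#' @export
print.vesicle_records <- function(x, ...) {
  d <- sum(!x$censored)
  cat(sprintf("Vesicle rupture records: %d vesicles, %d ruptured, %d censored\n",
              nrow(x), d, nrow(x) - d))
  cat(sprintf("  conditions: %d GrA level(s) x %d tension(s), window %s s\n",
              length(unique(x$gra_mole_percent)),
              length(unique(signif(x$sigma_e, 8))),
              paste(unique(x$window), collapse = "/")))
  NextMethod()
  invisible(x)
}
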