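#' Read and write per-vesicle rupture tables
#'
#' The on-disk schema is a plain CSV with header
#' `vesicle_id, trial_id, gra_mole_percent, radius_um, sigma_mn_per_m,
#' rupture_time_s, censored`, using boundary units (um, mN/m); censored rows
#' leave `rupture_time_s` empty and set `censored` to `true`. `read_records`
#' converts to SI and validates every row, reporting offending row numbers;
#' `write_records` is its inverse.
#'
#' @param path file path.
#' @param window observation window (s) to attach to the records, default 60.
#' @return `read_records`: a [vesicle_records()] table.
#'   `write_records`: the path, invisibly.
#' @examples
#' path <- system.file("extdata", "synthetic_rupture_records.csv",
#'                     package = "guvpore")
#' read_records(path)
#' @export
read_records <- function(path, window = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("vesicle_id", "trial_id", "gra_mole_percent", "radius_um",
                "sigma_mn_per_m", "rupture_time_s", "censored")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("gra_mole_percent", "radius_um", "sigma_mn_per_m",
                "rupture_time_s")) {
    v <- df[[col]]
    if (is.character(v)) {
      blank <- !nzchar(trimws(v))
      num <- suppressWarnings(as.numeric(v))
      bad <- !blank & is.na(num)
      if (any(bad)) {
        stop(sprintf("non-numeric %s at row(s) %s of %s", col,
                     paste(utils::head(which(bad), 5), collapse = ", "), path),
             call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  cens <- parse_flag(df$censored, path)
  out <- data.frame(
    vesicle_id = as.character(df$vesicle_id),
    trial_id = as.character(df$trial_id),
    gra_mole_percent = df$gra_mole_percent,
    radius = um(df$radius_um),
    sigma_e = mN_per_m(df$sigma_mn_per_m),
    rupture_time = df$rupture_time_s,
    censored = cens,
    window = window,
    stringsAsFactors = FALSE
  )
  validate_records(out, context = "file row")
}

parse_flag <- function(x, path) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (any(is.na(out))) {
    stop(sprintf("unparseable censored flag at row(s) %s of %s",
                 paste(utils::head(which(is.na(out)), 5), collapse = ", "),
                 path), call. = FALSE)
  }
  out
}

#' @rdname read_records
#' @param records a [vesicle_records()] table.
#' @export
write_records <- function(records, path) {
  records <- validate_records(as.data.frame(records))
  out <- data.frame(
    vesicle_id = records$vesicle_id,
    trial_id = records$trial_id,
    gra_mole_percent = records$gra_mole_percent,
    radius_um = records$radius / 1e-6,
    sigma_mn_per_m = to_mN_per_m(records$sigma_e),
    rupture_time_s = records$rupture_time,
    censored = tolower(as.character(records$censored)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a simulated dataset with its provenance sidecar
#'
#' Persists a [simulate_tension_grid()] result as the standard CSV plus a
#' JSON sidecar (`<path>.meta.json`) holding the generating truth, the
#' design, and the seed, so a simulated dataset is always reproducible from
#' its files alone.
#'
#' @param sim result of [simulate_tension_grid()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_simulation`: the path, invisibly. `read_simulation`: the
#'   records with `truth`, `design` and `seed` attributes restored.
#' @export
write_simulation <- function(sim, path) {
  write_records(sim, path)
  meta <- list(
    truth = attr(sim, "truth"),
    design = unclass(attr(sim, "design")),
    seed = attr(sim, "seed"),
    package_version = as.character(utils::packageVersion("guvpore"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulation
#' @export
read_simulation <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  recs <- read_records(path, window = meta$design$window)
  attr(recs, "truth") <- meta$truth
  attr(recs, "design") <- do.call(experiment_design, meta$design)
  attr(recs, "seed") <- meta$seed
  recs
}
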