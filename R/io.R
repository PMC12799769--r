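STATION_COLS <- c("station_id", "lat", "lon", "timestamp", "temp_c", "rh_pct",
                  "pm25", "pm10", "so2", "no2", "o3", "co")
PATIENT_COLS <- c("patient_id", "onset_time", "lat", "lon", "age", "sex",
                  "smoking", "alcohol", "gcs", "ich_location")

#' Write station / patient tables to CSV
#'
#' Comma-separated, UTF-8, ISO-8601 timestamps, "." decimal separator.
#'
#' @param x Tibble to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(x, path) {
  x <- dplyr::mutate(x, timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(x[, STATION_COLS], path)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
write_patient_csv <- function(x, path) {
  x <- dplyr::mutate(x, onset_time = format(.data$onset_time, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(x[, PATIENT_COLS], path)
  invisible(path)
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0(what, " file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
}

parse_time_col <- function(x, what) {
  out <- tryCatch(
    as.POSIXct(x, tz = CC_TZ,
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")),
    error = function(e) rep(as.POSIXct(NA), length(x)))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(paste0("unparseable ", what, " timestamp at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' Read and validate a station series CSV
#'
#' Checks required columns, parses ISO-8601 timestamps, and reports
#' row-level invariant violations (relative humidity outside \[0, 100\],
#' negative pollutant values) in an `issues` attribute without dropping
#' the rows.
#'
#' @param path CSV path.
#' @return Station tibble with attribute `"issues"` (tibble `row`,
#'   `problem`).
#' @export
read_station_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, STATION_COLS, "station")
  df$timestamp <- parse_time_col(df$timestamp, "station")
  issues <- list()
  bad_rh <- which(df$rh_pct < 0 | df$rh_pct > 100)
  if (length(bad_rh)) {
    issues <- c(issues, list(tibble::tibble(row = bad_rh,
                                            problem = "rh_pct outside [0, 100]")))
  }
  for (p in c("pm25", "pm10", "so2", "no2", "o3", "co")) {
    bad <- which(df[[p]] < 0)
    if (length(bad)) {
      issues <- c(issues, list(tibble::tibble(row = bad,
                                              problem = paste0(p, " negative"))))
    }
  }
  attr(df, "issues") <- if (length(issues)) purrr::list_rbind(issues) else
    tibble::tibble(row = integer(), problem = character())
  df
}

#' Read and validate a patient (onset record) CSV
#'
#' Checks required columns, parses onset timestamps (which must sit on
#' the hour), and reports row-level invariant violations (GCS outside
#' 3..15, age below 18, unknown hemorrhage location) in an `issues`
#' attribute.
#'
#' @param path CSV path.
#' @return Patient tibble with attribute `"issues"`.
#' @export
read_patient_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, PATIENT_COLS, "patient")
  df$onset_time <- parse_time_col(df$onset_time, "onset")
  issues <- list()
  add <- function(rows, problem) {
    if (length(rows)) list(tibble::tibble(row = rows, problem = problem))
  }
  issues <- c(issues,
              add(which(df$gcs < 3 | df$gcs > 15), "gcs outside [3, 15]"),
              add(which(df$age < 18), "age below 18"),
              add(which(!df$ich_location %in%
                          c("deep", "infratentorial", "lobar")),
                  "unknown ich_location"),
              add(which(as.numeric(df$onset_time) %% 3600 != 0),
                  "onset_time not on the hour"))
  attr(df, "issues") <- if (length(issues)) purrr::list_rbind(issues) else
    tibble::tibble(row = integer(), problem = character())
  df
}

#' Serialize / restore a basis-coefficient ground truth
#'
#' Writes the coefficient matrix, both basis specs, the reference value
#' and the baseline rate of a [simulation_truth()] whose surface was
#' built with [surface_from_basis()], so a simulation is reproducible
#' from the sidecar alone.
#'
#' @param theta Coefficient matrix handed to [surface_from_basis()].
#' @param exposure_spec,lag_spec The basis specs.
#' @param x_ref Reference exposure.
#' @param baseline_rate Constant baseline rate (events/hour).
#' @param path JSON path.
#' @return `path` invisibly (write) / a `simulation_truth` (read).
#' @export
write_truth_json <- function(theta, exposure_spec, lag_spec, x_ref,
                             baseline_rate, path) {
  spec_to_list <- function(s) {
    list(kind = s$kind, df = s$df, knots = s$knots,
         boundary = s$boundary, intercept = s$intercept)
  }
  jsonlite::write_json(
    list(theta = as.matrix(theta),
         exposure_spec = spec_to_list(exposure_spec),
         lag_spec = spec_to_list(lag_spec),
         x_ref = x_ref, baseline_rate = baseline_rate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @param max_lag Maximum lag for the restored truth.
#' @export
read_truth_json <- function(path, max_lag = 24) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list_to_spec <- function(l) {
    basis_spec(l$kind, knots = l$knots, boundary = l$boundary,
               intercept = isTRUE(l$intercept))
  }
  es <- list_to_spec(j$exposure_spec)
  ls_ <- list_to_spec(j$lag_spec)
  simulation_truth(
    surface_from_basis(matrix(j$theta, nrow = es$df), es, ls_, j$x_ref),
    x_ref = j$x_ref, baseline_rate = j$baseline_rate, max_lag = max_lag
  )
}

#' Serialize a fitted conditional-logistic model to JSON
#'
#' @param fit A [fit_clogit()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cc_fit"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         vcov = fit$vcov, loglik = fit$loglik,
         loglik_null = fit$loglik_null,
         n_strata = fit$n_strata, n_events = fit$n_events,
         converged = fit$converged, separation = fit$separation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Centred moving average
#'
#' Mean over a symmetric window of `floor(n/2)` points on each side of
#' every position (so an `n = 10` "10-day" smoother spans five days
#' either side of the centre).  The symmetric window reproduces a linear
#' ramp exactly at interior points.  Ends where the window is truncated
#' use the available points.
#'
#' @param x Numeric vector.
#' @param n Nominal window length (default 10).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, n = 10) {
  h <- floor(n / 2)
  idx <- seq_along(x)
  vapply(idx, function(i) {
    w <- max(1, i - h):min(length(x), i + h)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
}

#' Descriptive statistics of pooled case-window exposures
#'
#' Mean, SD and the 1st/25th/50th/75th/99th percentiles of each
#' variable over the pooled backward-window values of the case hours,
#' plus daily case counts and daily mean exposures smoothed with a
#' centred 10-day moving average.
#'
#' @param records Onset records tibble.
#' @param lag_matrices Named list of [build_lag_matrix()] objects (or
#'   trimmed copies), rows = case hours, one per variable.
#' @return List: `summary` (tibble variable/mean/sd/p1/p25/p50/p75/p99),
#'   `daily` (tibble date/n_cases plus smoothed daily means per
#'   variable).
#' @export
descriptive_summary <- function(records, lag_matrices) {
  if (nrow(records) == 0) abort("no records")
  summ <- purrr::imap(lag_matrices, function(m, nm) {
    v <- as.numeric(m$Q)
    v <- v[!is.na(v)]
    p <- pctl(v, c(0.01, 0.25, 0.5, 0.75, 0.99))
    tibble::tibble(variable = nm, mean = mean(v), sd = stats::sd(v),
                   p1 = p[1], p25 = p[2], p50 = p[3], p75 = p[4], p99 = p[5])
  }) |> purrr::list_rbind()

  onset_date <- as.Date(floor_hour(records$onset_time), tz = CC_TZ)
  all_days <- seq(min(onset_date), max(onset_date), by = "day")
  daily <- tibble::tibble(
    date = all_days,
    n_cases = as.integer(table(factor(onset_date, levels = as.character(all_days))))
  )
  daily$n_cases_smooth <- moving_average(daily$n_cases, 10)
  for (nm in names(lag_matrices)) {
    m <- lag_matrices[[nm]]
    ev_date <- as.Date(m$event_hours, tz = CC_TZ)
    lag0 <- m$Q[, 1]
    dm <- tapply(lag0, factor(ev_date, levels = as.character(all_days)),
                 mean, na.rm = TRUE)
    daily[[paste0(nm, "_daily_mean")]] <- as.numeric(dm)
    daily[[paste0(nm, "_smooth")]] <- moving_average(as.numeric(dm), 10)
  }
  list(summary = summ, daily = daily)
}

#' Export tidy effect estimates to CSV
#'
#' One row per effect estimate, in the long layout used by the result
#' tables: exposure, contrast, window/lag label, OR and CI bounds.
#'
#' @param effects A `cc_effect`/`cc_surface` tibble (or [tidy.cc_dlnm()]
#'   output).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(effects, path) {
  readr::write_csv(as.data.frame(effects), path)
  invisible(path)
}
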