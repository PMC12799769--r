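#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised,
#'   recycled).
#' @return Numeric vector of distances (km).
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)    # ~111.195 km, one degree along the equator
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) abort("latitudes must lie in [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360)) abort("longitudes out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0)
}

#' Match each patient to the nearest admissible weather station
#'
#' Assigns each record the nearest station by great-circle distance;
#' records farther than `max_km` from every station are marked excluded
#' (a data outcome, not an error).  Exact distance ties go to the
#' lexicographically smallest `station_id`.
#'
#' @param patients Tibble of onset records with `patient_id`, `lat`, `lon`.
#' @param stations Station series tibble (or any tibble with
#'   `station_id`, `lat`, `lon`; repeated rows per station are fine).
#' @param max_km Maximum admissible distance in km (default 50).
#' @return A tibble `patient_id`, `station_id`, `distance_km`, `excluded`;
#'   excluded rows carry the nearest station's id and distance for the
#'   exclusion report.
#' @export
match_station <- function(patients, stations, max_km = 50) {
  st <- dplyr::distinct(stations, .data$station_id, .data$lat, .data$lon) |>
    dplyr::arrange(.data$station_id)     # tie-break: first hit wins
  if (nrow(st) < 1) abort("at least one station is required")
  D <- vapply(seq_len(nrow(st)), function(j) {
    haversine_km(patients$lat, patients$lon, st$lat[j], st$lon[j])
  }, numeric(nrow(patients)))
  D <- matrix(D, nrow = nrow(patients))
  best <- max.col(-D, ties.method = "first")
  dist <- D[cbind(seq_len(nrow(patients)), best)]
  tibble::tibble(
    patient_id = patients$patient_id,
    station_id = st$station_id[best],
    distance_km = dist,
    excluded = dist > max_km
  )
}

#' Backward lag matrix of hourly exposures
#'
#' For each event hour t builds the row `x_t, x_{t-1}, ..., x_{t-L}`
#' (moving backward L hours from the event hour) from one station's
#' hourly series.  Hours absent from the series yield `NA` cells;
#' trimming later masks further cells.  Masked (NA) cells are never
#' silently imputed.
#'
#' @param series One station's rows of the station-series tibble.
#' @param event_hours POSIXct vector of event hours.
#' @param exposure Column name to extract (e.g. `"temp_c"`, `"rh_pct"`).
#' @param max_lag Maximum lag L in hours (default 24).
#' @return An object of class `lag_matrix`: list with `Q` (numeric
#'   matrix, `length(event_hours)` x `L + 1`, column `l + 1` = lag l),
#'   `event_hours`, `exposure`, `max_lag`.
#' @export
build_lag_matrix <- function(series, event_hours, exposure = "temp_c",
                             max_lag = 24) {
  if (max_lag < 0) abort("max_lag must be >= 0")
  if (!exposure %in% names(series)) {
    abort(paste0("series has no column '", exposure, "'"))
  }
  event_hours <- as_hour(event_hours)
  key <- as.numeric(series$timestamp)
  val <- series[[exposure]]
  n <- length(event_hours)
  Q <- matrix(NA_real_, n, max_lag + 1)
  ev <- as.numeric(event_hours)
  for (l in 0:max_lag) {
    Q[, l + 1] <- val[match(ev - l * 3600, key)]
  }
  colnames(Q) <- paste0("lag", 0:max_lag)
  structure(list(Q = Q, event_hours = event_hours, exposure = exposure,
                 max_lag = as.integer(max_lag)),
            class = "lag_matrix")
}

#' @export
print.lag_matrix <- function(x, ...) {
  cat("<lag_matrix> ", x$exposure, ": ", nrow(x$Q), " event hours x lags 0..",
      x$max_lag, " (", sum(is.na(x$Q)), " masked cells)\n", sep = "")
  invisible(x)
}

#' Two-stage percentile trimming of extreme exposure values
#'
#' Stage 1: percentile bounds (type-7, linear interpolation) are computed
#' on the pooled case-window values and every matrix cell strictly below
#' the lower or strictly above the upper bound is masked.  Stage 2: the
#' contrast ("extreme") and reference values are the contrast/reference
#' percentiles of the surviving pooled values.  With
#' `retain_extremes = TRUE` stage 1 is skipped (identity mask) and stage
#' 2 uses the raw pool.
#'
#' @param lagmat A [build_lag_matrix()] result whose rows include the
#'   pooling rows.
#' @param pool_rows Integer/logical index of rows whose values form the
#'   percentile pool (the case windows); default all rows.
#' @param trim_probs Stage-1 lower/upper percentile pair (default 1st and
#'   99th).
#' @param contrast_prob,ref_prob Stage-2 percentiles defining the extreme
#'   contrast value and the reference value (defaults 0.01 and 0.99).
#' @param retain_extremes If TRUE, skip stage-1 masking.
#' @return A list of class `trim_result`: `lagmat` (masked copy),
#'   `bounds` (stage-1 lower/upper, NA when retained), `x_ext`, `x_ref`,
#'   `n_masked` (cells newly masked), `retain_extremes`.
#' @export
trim_extremes <- function(lagmat, pool_rows = NULL,
                          trim_probs = c(0.01, 0.99),
                          contrast_prob = 0.01, ref_prob = 0.99,
                          retain_extremes = FALSE) {
  stopifnot(inherits(lagmat, "lag_matrix"))
  check_prob(c(trim_probs, contrast_prob, ref_prob), "percentiles")
  if (trim_probs[1] >= trim_probs[2]) abort("trim_probs must be increasing")
  if (contrast_prob >= ref_prob) {
    abort("contrast percentile must be below the reference percentile")
  }
  if (is.null(pool_rows)) pool_rows <- seq_len(nrow(lagmat$Q))
  pool <- as.numeric(lagmat$Q[pool_rows, , drop = FALSE])
  pool <- pool[!is.na(pool)]
  if (length(pool) < 100) {
    warn("fewer than 100 pooled values; percentile bounds are unstable")
  }
  Q <- lagmat$Q
  if (retain_extremes) {
    bounds <- c(NA_real_, NA_real_)
    n_masked <- 0L
    surviving <- pool
  } else {
    bounds <- pctl(pool, trim_probs)
    drop <- !is.na(Q) & (Q < bounds[1] | Q > bounds[2])
    n_masked <- sum(drop)
    Q[drop] <- NA_real_
    surviving <- pool[pool >= bounds[1] & pool <= bounds[2]]
  }
  x_ext <- pctl(surviving, contrast_prob)
  x_ref <- pctl(surviving, ref_prob)
  if (x_ext == x_ref) {
    abort("degenerate exposure distribution: contrast equals reference")
  }
  out <- lagmat
  out$Q <- Q
  structure(list(lagmat = out, bounds = bounds,
                 x_ext = x_ext, x_ref = x_ref,
                 n_masked = n_masked, retain_extremes = retain_extremes),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("<trim_result> ", x$lagmat$exposure,
      if (x$retain_extremes) " (extremes retained)" else
        sprintf(" bounds [%.3g, %.3g], %d cells masked",
                x$bounds[1], x$bounds[2], x$n_masked),
      sprintf("; x_ext = %.4g, x_ref = %.4g\n", x$x_ext, x$x_ref), sep = "")
  invisible(x)
}

#' Complete the lag windows of surviving event hours
#'
#' After trimming and event-level exclusion, rows retained by the drop
#' rule may still carry masked cells (at most the tolerated fraction of
#' the window, never at lag 0).  This declared completion rule fills
#' each masked cell by linear interpolation along the row's lag axis
#' (constant extension beyond the last observed lag) so the cross-basis
#' receives fully observed rows.
#'
#' @param lagmat A `lag_matrix` whose remaining rows satisfy the drop
#'   rule (lag-0 observed).
#' @return The `lag_matrix` with masked cells filled.
#' @export
complete_windows <- function(lagmat) {
  stopifnot(inherits(lagmat, "lag_matrix"))
  Q <- lagmat$Q
  bad <- which(rowSums(is.na(Q)) > 0)
  lags <- 0:lagmat$max_lag
  for (i in bad) {
    obs <- !is.na(Q[i, ])
    if (!any(obs)) abort("cannot complete a fully masked row")
    Q[i, ] <- stats::approx(lags[obs], Q[i, obs], xout = lags, rule = 2)$y
  }
  lagmat$Q <- Q
  lagmat
}

#' Backward-window pollutant means per event hour
#'
#' Arithmetic mean of each pollutant over the unmasked hours of the
#' backward window (lags 0..L).  Events with more than `max_frac_masked`
#' of their window missing are flagged and get `NA` means.
#'
#' @param series One station's rows of the station-series tibble.
#' @param event_hours POSIXct vector of event hours.
#' @param max_lag Window length L (default 24).
#' @param pollutants Pollutant column names.
#' @param max_frac_masked Missingness tolerance (default 0.25).
#' @return Tibble: `event_hour`, one mean column per pollutant, `flagged`.
#' @export
pollutant_means <- function(series, event_hours, max_lag = 24,
                            pollutants = c("pm25", "pm10", "so2", "no2", "o3", "co"),
                            max_frac_masked = 0.25) {
  out <- tibble::tibble(event_hour = as_hour(event_hours))
  flagged <- rep(FALSE, nrow(out))
  for (p in pollutants) {
    Q <- build_lag_matrix(series, event_hours, exposure = p,
                          max_lag = max_lag)$Q
    frac_na <- rowMeans(is.na(Q))
    m <- rowMeans(Q, na.rm = TRUE)
    bad <- frac_na > max_frac_masked
    m[bad | !is.finite(m)] <- NA_real_
    flagged <- flagged | bad | frac_na == 1
    out[[p]] <- m
  }
  out$flagged <- flagged
  out
}
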