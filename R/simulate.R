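#' Configuration for the hourly weather simulator
#'
#' Bundles the parameters of a synthetic humid-subtropical hourly climate:
#' an annual and a diurnal temperature sinusoid around a long-run mean,
#' AR(1) temperature noise, relative humidity anticorrelated with
#' temperature and clamped to \[0, 100\]%, and lognormal AR(1) pollutant
#' series.  Defaults emulate a mid-latitude monsoon-climate study region
#' with a long-run mean temperature of 16.8 degC.
#'
#' @param start_time,end_time Civil timestamps bounding the hourly grid
#'   (inclusive).  Defaults cover three full years.
#' @param mean_temp Long-run mean temperature (degC).
#' @param annual_amplitude,diurnal_amplitude Amplitudes (degC) of the
#'   annual and diurnal temperature sinusoids.
#' @param annual_peak_doy Day-of-year at which the annual cycle peaks
#'   (default 197, mid-July).
#' @param diurnal_peak_hour Hour-of-day at which the diurnal cycle peaks
#'   (default 15, i.e. 15:00 local).
#' @param ar1_coefficient AR(1) coefficient of the temperature noise,
#'   strictly inside (-1, 1).
#' @param noise_sd Innovation SD (degC) of the temperature AR(1) noise.
#' @param rh_mean Mean relative humidity (%).
#' @param rh_temp_slope Humidity change per degC of temperature anomaly
#'   (% per degC; typically negative).
#' @param rh_noise_sd Innovation SD (%) of the humidity AR(1) noise.
#' @param pollutant_logmean,pollutant_logsd Named numeric vectors (names
#'   pm25, pm10, so2, no2, o3, co) giving the log-scale mean and
#'   stationary SD of each lognormal pollutant series.
#' @param pollutant_ar1 AR(1) coefficient of the pollutant log series.
#' @param n_stations Number of stations to simulate (>= 1).
#' @param lat_range,lon_range Coordinate box (degrees) in which station
#'   locations are drawn.
#' @param seed Integer seed; identical configurations reproduce
#'   bit-identical output.
#'
#' @return An object of class `weather_config` (a named list).
#' @export
#' @examples
#' cfg <- weather_config(end_time = "2021-03-31 23:00", n_stations = 2)
#' head(simulate_weather(cfg))
weather_config <- function(start_time = "2019-01-01 00:00",
                           end_time = "2021-12-31 23:00",
                           mean_temp = 16.8,
                           annual_amplitude = 10.5,
                           diurnal_amplitude = 3.5,
                           annual_peak_doy = 197,
                           diurnal_peak_hour = 15,
                           ar1_coefficient = 0.85,
                           noise_sd = 1.2,
                           rh_mean = 72,
                           rh_temp_slope = -1.6,
                           rh_noise_sd = 4,
                           pollutant_logmean = c(pm25 = log(17.8), pm10 = log(33.8),
                                                 so2 = log(7.5), no2 = log(8.0),
                                                 o3 = log(79.1), co = log(0.6)),
                           pollutant_logsd = c(pm25 = 0.70, pm10 = 0.70,
                                               so2 = 0.35, no2 = 0.50,
                                               o3 = 0.31, co = 0.30),
                           pollutant_ar1 = 0.9,
                           n_stations = 1,
                           lat_range = c(32, 33),
                           lon_range = c(110, 111),
                           seed = 1L) {
  start_time <- as_hour(start_time)
  end_time <- as_hour(end_time)
  if (end_time <= start_time) abort("end_time must be after start_time")
  if (!on_hour_grid(c(start_time, end_time))) {
    abort("start_time and end_time must sit on the hourly grid")
  }
  if (abs(ar1_coefficient) >= 1) abort("|ar1_coefficient| must be < 1")
  if (n_stations < 1) abort("n_stations must be >= 1")
  pn <- c("pm25", "pm10", "so2", "no2", "o3", "co")
  if (!all(pn %in% names(pollutant_logmean)) ||
      !all(pn %in% names(pollutant_logsd))) {
    abort("pollutant_logmean/logsd must name pm25, pm10, so2, no2, o3, co")
  }
  structure(list(
    start_time = start_time, end_time = end_time,
    mean_temp = mean_temp,
    annual_amplitude = annual_amplitude,
    diurnal_amplitude = diurnal_amplitude,
    annual_peak_doy = annual_peak_doy,
    diurnal_peak_hour = diurnal_peak_hour,
    ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
    rh_mean = rh_mean, rh_temp_slope = rh_temp_slope,
    rh_noise_sd = rh_noise_sd,
    pollutant_logmean = pollutant_logmean[pn],
    pollutant_logsd = pollutant_logsd[pn],
    pollutant_ar1 = pollutant_ar1,
    n_stations = as.integer(n_stations),
    lat_range = lat_range, lon_range = lon_range,
    seed = as.integer(seed)
  ), class = "weather_config")
}

ar1_series <- function(n, phi, innov_sd) {
  as.numeric(filter(rnorm(n, 0, innov_sd), phi, method = "recursive"))
}

#' Simulate hourly station weather and pollutant series
#'
#' Generates one contiguous hourly series per station: temperature as
#' mean + annual sinusoid + diurnal sinusoid + AR(1) noise; relative
#' humidity as a linear response to the temperature anomaly plus AR(1)
#' noise, clamped to \[0, 100\]; pollutants as lognormal with AR(1)
#' dependence on the log scale (hence strictly positive).
#'
#' @param cfg A [weather_config()].
#' @return A tibble with one row per station-hour and columns
#'   `station_id`, `lat`, `lon`, `timestamp`, `temp_c`, `rh_pct`,
#'   `pm25`, `pm10`, `so2`, `no2`, `o3`, `co`.
#' @export
simulate_weather <- function(cfg) {
  if (!inherits(cfg, "weather_config")) abort("cfg must be a weather_config")
  set.seed(cfg$seed)
  tt <- hour_seq(cfg$start_time, cfg$end_time)
  n <- length(tt)
  day_frac <- as.numeric(tt) / 86400          # days since epoch, hourly steps
  doy_angle <- 2 * pi * (day_frac - (cfg$annual_peak_doy - 1)) / 365.25
  hod <- (as.numeric(tt) / 3600) %% 24
  hod_angle <- 2 * pi * (hod - cfg$diurnal_peak_hour) / 24

  lat <- runif(cfg$n_stations, cfg$lat_range[1], cfg$lat_range[2])
  lon <- runif(cfg$n_stations, cfg$lon_range[1], cfg$lon_range[2])
  ids <- sprintf("ST%02d", seq_len(cfg$n_stations))

  purrr::map_dfr(seq_len(cfg$n_stations), function(s) {
    temp <- cfg$mean_temp +
      cfg$annual_amplitude * cos(doy_angle) +
      cfg$diurnal_amplitude * cos(hod_angle) +
      ar1_series(n, cfg$ar1_coefficient, cfg$noise_sd)
    rh <- cfg$rh_mean + cfg$rh_temp_slope * (temp - cfg$mean_temp) +
      ar1_series(n, cfg$ar1_coefficient, cfg$rh_noise_sd)
    rh <- pmin(pmax(rh, 0), 100)
    poll <- purrr::imap(cfg$pollutant_logmean, function(mu, nm) {
      sigma <- cfg$pollutant_logsd[[nm]]
      innov <- sigma * sqrt(1 - cfg$pollutant_ar1^2)
      exp(mu + ar1_series(n, cfg$pollutant_ar1, innov))
    })
    tibble::tibble(
      station_id = ids[s], lat = lat[s], lon = lon[s], timestamp = tt,
      temp_c = temp, rh_pct = rh,
      pm25 = poll$pm25, pm10 = poll$pm10, so2 = poll$so2,
      no2 = poll$no2, o3 = poll$o3, co = poll$co
    )
  })
}

#' Declare the ground-truth hazard for onset simulation
#'
#' The onset process is an inhomogeneous point process with rate
#' `lambda(t) = lambda0(t) * exp(sum_{l=0..L} f(x_{t-l}, l))` where `x`
#' is the driving exposure at the patient's station and `f` the
#' exposure-lag-response surface.  `f` must be centred so that
#' `f(x_ref, l) = 0` at the declared reference exposure for every lag.
#'
#' @param surface Function `f(x, l)`, vectorised over both arguments,
#'   returning the log-rate contribution of exposure value `x` at lag
#'   `l`.  Use [truth_null()] or [surface_from_basis()] to construct one.
#' @param x_ref Reference exposure value at which the surface is centred.
#' @param exposure Name of the driving exposure column in the station
#'   series (default `"temp_c"`).
#' @param baseline_rate Baseline rate `lambda0(t)`: a single positive
#'   number (events/hour) or a function of POSIXct time.
#' @param max_lag Maximum lag L in hours (default 24).
#' @param covariates Named list of marginal covariate distributions used
#'   purely for cosmetic realism of the generated records: `p_male`,
#'   `p_smoking`, `p_alcohol`, `p_location` (named probabilities for
#'   deep/infratentorial/lobar), `age_mean`, `age_sd`, `gcs_probs`
#'   (length-13 weights for scores 3..15).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(surface,
                             x_ref,
                             exposure = "temp_c",
                             baseline_rate = 0.05,
                             max_lag = 24,
                             covariates = list()) {
  if (!is.function(surface)) abort("surface must be a function f(x, l)")
  if (is.numeric(baseline_rate)) {
    if (baseline_rate <= 0) abort("baseline_rate must be positive")
    lam0 <- baseline_rate
    baseline_rate <- function(t) rep(lam0, length(t))
  }
  cen <- surface(rep(x_ref, max_lag + 1), 0:max_lag)
  if (max(abs(cen)) > 1e-8) {
    abort("surface must satisfy f(x_ref, l) = 0 at every lag")
  }
  gcs_default <- c(rep(0.392 / 6, 6),     # 3..8
                   rep(0.133 / 3, 3),     # 9..11
                   rep(0.248 / 3, 3),     # 12..14
                   0.227)                 # 15
  cov <- utils::modifyList(list(
    p_male = 0.603, p_smoking = 0.343, p_alcohol = 0.443,
    p_location = c(deep = 0.732, infratentorial = 0.149, lobar = 0.119),
    age_mean = 60.1, age_sd = 11.5,
    gcs_probs = gcs_default
  ), covariates)
  structure(list(surface = surface, x_ref = x_ref, exposure = exposure,
                 baseline_rate = baseline_rate, max_lag = as.integer(max_lag),
                 covariates = cov),
            class = "simulation_truth")
}

#' Null ground truth (no exposure effect)
#' @param x_ref Reference exposure (irrelevant to the zero surface).
#' @param ... Passed on to [simulation_truth()].
#' @return A `simulation_truth` whose surface is identically zero.
#' @export
truth_null <- function(x_ref = 0, ...) {
  simulation_truth(function(x, l) rep(0, length(x)), x_ref = x_ref, ...)
}

#' Build a centred surface from basis coefficients
#'
#' Constructs `f(x, l) = sum_jk theta[j, k] * (B_j(x) - B_j(x_ref)) *
#' C_k(l)` from an exposure basis, a lag basis, and a coefficient matrix,
#' so the truth lies in the span estimated by the cross-basis model (up
#' to the centring, which contrasts difference away).
#'
#' @param theta Numeric matrix, `df_exposure` x `df_lag`.
#' @param exposure_spec,lag_spec Resolved [basis_spec()]s (knots set).
#' @param x_ref Reference exposure at which the surface is centred.
#' @return A vectorised function `f(x, l)`.
#' @export
surface_from_basis <- function(theta, exposure_spec, lag_spec, x_ref) {
  theta <- as.matrix(theta)
  bref <- natural_cubic_basis(x_ref, exposure_spec)
  function(x, l) {
    B <- sweep(natural_cubic_basis(x, exposure_spec), 2, as.numeric(bref))
    C <- natural_cubic_basis(l, lag_spec)
    rowSums((B %*% theta) * C)
  }
}

draw_covariates <- function(n, cov) {
  age <- round(rnorm(n, cov$age_mean, cov$age_sd))
  age[age < 18] <- 18
  tibble::tibble(
    age = age,
    sex = ifelse(runif(n) < cov$p_male, "male", "female"),
    smoking = ifelse(runif(n) < cov$p_smoking, "yes", "no"),
    alcohol = ifelse(runif(n) < cov$p_alcohol, "yes", "no"),
    gcs = sample(3:15, n, replace = TRUE, prob = cov$gcs_probs),
    ich_location = sample(names(cov$p_location), n, replace = TRUE,
                          prob = cov$p_location)
  )
}

#' Simulate onset records by thinning a known hazard
#'
#' Candidate onset hours are all station-hours whose full backward lag
#' window lies inside the station series.  Hours are proposed uniformly
#' and accepted with probability `lambda(t) / max lambda` (thinning), so
#' accepted hours follow the declared hazard exactly; draws continue
#' until `n_cases` records are produced.  Each record receives
#' coordinates within `radius_km` of its generating station and
#' covariates from the truth's marginal distributions.
#'
#' @param stations Station series tibble from [simulate_weather()].
#' @param truth A [simulation_truth()].
#' @param n_cases Number of onset records to generate.
#' @param seed Integer seed.
#' @param radius_km Radius (km) around the generating station within
#'   which patient coordinates are drawn (default 10; set larger than
#'   the station-matching cutoff to exercise distance exclusions).
#' @return A tibble of onset records: `patient_id`, `onset_time`, `lat`,
#'   `lon`, `age`, `sex`, `smoking`, `alcohol`, `gcs`, `ich_location`.
#' @export
simulate_onsets <- function(stations, truth, n_cases, seed = 1L,
                            radius_km = 10) {
  if (!inherits(truth, "simulation_truth")) abort("truth must be a simulation_truth")
  if (n_cases < 1) abort("n_cases must be >= 1")
  set.seed(as.integer(seed))
  L <- truth$max_lag

  # per station: linear predictor sum_l f(x_{t-l}, l) on candidate hours
  cand <- stations |>
    dplyr::group_by(.data$station_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      if (n <= L) {
        abort("station series shorter than the lag window; cannot simulate onsets")
      }
      x <- df[[truth$exposure]]
      fx <- matrix(0, n, L + 1)            # fx[, l+1] = f(x_t, l)
      for (l in 0:L) fx[, l + 1] <- truth$surface(x, rep(l, n))
      idx <- (L + 1):n
      s <- numeric(length(idx))
      for (l in 0:L) s <- s + fx[idx - l, l + 1]
      tibble::tibble(station_id = key$station_id,
                     lat = df$lat[1], lon = df$lon[1],
                     timestamp = df$timestamp[idx],
                     linpred = s)
    }) |>
    purrr::list_rbind()

  lam <- truth$baseline_rate(cand$timestamp) * exp(cand$linpred)
  if (any(lam <= 0)) abort("baseline_rate must be positive at every hour")
  lam_max <- max(lam)
  acc_prob <- lam / lam_max

  picked <- integer(0)
  while (length(picked) < n_cases) {
    m <- max(2L * n_cases, 100L)
    prop <- sample.int(nrow(cand), m, replace = TRUE)
    keep <- runif(m) < acc_prob[prop]
    picked <- c(picked, prop[keep])
  }
  picked <- picked[seq_len(n_cases)]

  # coordinates: uniform within radius_km of the generating station
  r <- radius_km * sqrt(runif(n_cases))
  theta <- runif(n_cases, 0, 2 * pi)
  lat0 <- cand$lat[picked]
  dlat <- (r * cos(theta)) / 111.195
  dlon <- (r * sin(theta)) / (111.195 * cos(lat0 * pi / 180))

  dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n_cases)),
      onset_time = cand$timestamp[picked],
      lat = lat0 + dlat,
      lon = cand$lon[picked] + dlon
    ),
    draw_covariates(n_cases, truth$covariates)
  )
}
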