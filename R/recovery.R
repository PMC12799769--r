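#' Canonical ground truth for parameter-recovery experiments
#'
#' A fixed cold-effect exposure-lag-response surface used by the
#' shipped recovery experiment: a linear exposure-response
#' `g(x) = -0.035 (x + 6)` (risk rising as temperature falls, pinned at
#' the lower boundary knot) times a lag profile `h(l)` lying in the span
#' of the default lag spline (intercept, three log-spaced knots),
#' scaled so the lag profile sums to `cum_target` over lags 0..24.
#' Both factors lie in the span of the fitted cross-basis, so the
#' cumulative contrast is estimable without approximation bias.
#'
#' @param cum_target Sum of the lag profile over lags 0..24 (default
#'   0.85, giving a true cumulative log odds ratio of about 0.91 for
#'   the 0.5 vs 31 degC contrast).
#' @return List: `truth` (a [simulation_truth()]), `exposure_spec`,
#'   `lag_spec`, `theta` (coefficient matrix of the surface on the
#'   basis pair), `x_ext`, `x_ref`, `true_cum_log_or` (full window).
#' @export
recovery_truth <- function(cum_target = 0.85) {
  exposure_spec <- basis_spec("natural_cubic", knots = c(10, 23),
                              boundary = c(-6, 40))
  lag_spec <- lag_basis_spec(24, 3)
  b0 <- c(0.15, 0.25, 0.2, 0.1, 0.05)
  h0 <- as.numeric(natural_cubic_basis(0:24, lag_spec) %*% b0)
  b <- b0 * cum_target / sum(h0)
  x_ref <- 31
  x_ext <- 0.5
  g <- function(x) -0.035 * (x + 6)
  surface <- function(x, l) {
    (g(x) - g(x_ref)) * as.numeric(natural_cubic_basis(l, lag_spec) %*% b)
  }
  # theta on the basis pair: g is linear and vanishes at the left
  # boundary, so it has exact coordinates a in the exposure basis
  B <- natural_cubic_basis(seq(-6, 40, length.out = 50), exposure_spec)
  a <- qr.solve(B, g(seq(-6, 40, length.out = 50)) - g(-6))
  list(truth = simulation_truth(surface, x_ref = x_ref,
                                baseline_rate = 0.05, max_lag = 24),
       exposure_spec = exposure_spec, lag_spec = lag_spec,
       theta = outer(a, b),
       x_ext = x_ext, x_ref = x_ref,
       true_cum_log_or = (g(x_ext) - g(x_ref)) *
         sum(as.numeric(natural_cubic_basis(0:24, lag_spec) %*% b)))
}

#' End-to-end parameter-recovery experiment
#'
#' Repeatedly simulates a year of hourly station weather and onset
#' events from the canonical known surface ([recovery_truth()]), runs
#' the full case-crossover DLNM pipeline (time-stratified strata,
#' cross-basis with the truth's knots, conditional-logistic fit), and
#' records the full-window cumulative log odds ratio for the fixed
#' 0.5 vs 31 degC contrast together with its delta-method 95% CI.
#'
#' @param n_replicates Number of simulation replicates.
#' @param n_cases Onset records per replicate (default 3000).
#' @param seed Integer seed for the whole experiment.
#' @return Tibble with one row per replicate: `estimate`, `se`,
#'   `ci_low`, `ci_high` (log scale), `true_value`, `covered`,
#'   `converged`.
#' @export
parameter_recovery <- function(n_replicates, n_cases = 3000, seed = 1L) {
  rt <- recovery_truth()
  cfg <- run_config(
    exposures = "temp_c",
    retain_extremes = TRUE,
    adjust_pollutants = FALSE,
    exposure_knots = list(temp_c = rt$exposure_spec$knots),
    exposure_boundary = list(temp_c = rt$exposure_spec$boundary),
    contrast_values = list(temp_c = c(rt$x_ext, rt$x_ref)),
    cumulative_windows = list(temp_c = list(c(0, 24)))
  )
  set.seed(seed)
  seeds <- matrix(sample.int(2^30, 2 * n_replicates), ncol = 2)
  purrr::map(seq_len(n_replicates), function(r) {
    w <- simulate_weather(weather_config(
      start_time = "2021-01-01 00:00", end_time = "2021-12-31 23:00",
      n_stations = 1, seed = seeds[r, 1]))
    pats <- simulate_onsets(w, rt$truth, n_cases, seed = seeds[r, 2])
    res <- cc_dlnm(pats, w, cfg)
    est <- res$effects$cumulative[1, ]
    tibble::tibble(
      replicate = r,
      estimate = est$log_or, se = est$se,
      ci_low = est$log_or - 1.96 * est$se,
      ci_high = est$log_or + 1.96 * est$se,
      true_value = rt$true_cum_log_or,
      covered = est$log_or - 1.96 * est$se <= rt$true_cum_log_or &
        rt$true_cum_log_or <= est$log_or + 1.96 * est$se,
      converged = res$fit$converged
    )
  }) |> purrr::list_rbind()
}
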