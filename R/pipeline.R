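#' Analysis configuration
#'
#' Bundles every tunable of the case-crossover DLNM pipeline.
#'
#' @param exposures Character vector of exposure columns to model with a
#'   cross-basis (default temperature and relative humidity; the first
#'   is the one the optional interaction block multiplies).
#' @param max_lag Maximum lag L in hours (default 24; values other than
#'   24/36/48 trigger a warning but are allowed).
#' @param exposure_df Natural-spline degrees of freedom in the exposure
#'   dimension (default 3, no intercept).
#' @param lag_knots Number of log-spaced internal knots in the lag
#'   dimension (default 3; the lag spline carries an intercept).
#' @param trim_probs Stage-1 trimming percentile pair (default 1st/99th).
#' @param contrast_prob,ref_prob Stage-2 percentiles defining the
#'   extreme contrast and the reference (defaults 0.01 and 0.99).
#' @param retain_extremes Skip stage-1 trimming?
#' @param max_station_km Nearest-station admissibility radius (default 50).
#' @param adjust_pollutants Include linear 24-h-mean pollutant
#'   covariates?
#' @param pollutants Pollutant columns used when adjusting.
#' @param interaction Also fit the temperature-by-humidity interaction
#'   block and report its likelihood-ratio test?
#' @param cumulative_windows Named list (by exposure column) of lag
#'   windows `c(l0, l1)` for cumulative odds ratios.  The default
#'   reports lag 0-12 h and 0-16 h for temperature, 0-6 h and 0-3 h for
#'   humidity, and the full window for both.
#' @param exposure_knots,exposure_boundary Optional named lists fixing
#'   the exposure-spline internal/boundary knots per exposure; when
#'   NULL, knots sit at equally spaced quantiles of the trimmed
#'   case-window distribution and the boundary at its range.
#' @param contrast_values Optional named list of `c(x_ext, x_ref)`
#'   per exposure, overriding the percentile-derived contrast.
#' @param max_frac_masked Window missingness tolerance for dropping an
#'   event hour (default 0.25).
#' @param seed Seed recorded for provenance.
#' @return Object of class `run_config`.
#' @export
run_config <- function(exposures = c("temp_c", "rh_pct"),
                       max_lag = 24,
                       exposure_df = 3,
                       lag_knots = 3,
                       trim_probs = c(0.01, 0.99),
                       contrast_prob = 0.01,
                       ref_prob = 0.99,
                       retain_extremes = FALSE,
                       max_station_km = 50,
                       adjust_pollutants = TRUE,
                       pollutants = c("pm25", "pm10", "so2", "no2", "o3", "co"),
                       interaction = FALSE,
                       cumulative_windows = NULL,
                       exposure_knots = NULL,
                       exposure_boundary = NULL,
                       contrast_values = NULL,
                       max_frac_masked = 0.25,
                       seed = 1L) {
  if (contrast_prob >= ref_prob) {
    abort("contrast percentile must be below the reference percentile")
  }
  if (!max_lag %in% c(24, 36, 48)) {
    warn("max_lag outside {24, 36, 48}; proceeding")
  }
  if (is.null(cumulative_windows)) {
    cumulative_windows <- list(
      temp_c = list(c(0, 12), c(0, 16), c(0, max_lag)),
      rh_pct = list(c(0, 6), c(0, 3), c(0, max_lag))
    )
  }
  structure(list(
    exposures = exposures, max_lag = as.integer(max_lag),
    exposure_df = as.integer(exposure_df), lag_knots = as.integer(lag_knots),
    trim_probs = trim_probs, contrast_prob = contrast_prob,
    ref_prob = ref_prob, retain_extremes = retain_extremes,
    max_station_km = max_station_km,
    adjust_pollutants = adjust_pollutants, pollutants = pollutants,
    interaction = interaction, cumulative_windows = cumulative_windows,
    exposure_knots = exposure_knots, exposure_boundary = exposure_boundary,
    contrast_values = contrast_values,
    max_frac_masked = max_frac_masked, seed = as.integer(seed)
  ), class = "run_config")
}

# lag matrix across mixed station assignments, rows aligned to events
lag_matrix_for_events <- function(stations, event_hours, station_id,
                                  exposure, max_lag) {
  n <- length(event_hours)
  Q <- matrix(NA_real_, n, max_lag + 1)
  for (sid in unique(station_id)) {
    idx <- which(station_id == sid)
    ser <- stations[stations$station_id == sid, , drop = FALSE]
    Q[idx, ] <- build_lag_matrix(ser, event_hours[idx], exposure, max_lag)$Q
  }
  colnames(Q) <- paste0("lag", 0:max_lag)
  structure(list(Q = Q, event_hours = event_hours, exposure = exposure,
                 max_lag = as.integer(max_lag)),
            class = "lag_matrix")
}

pollutants_for_events <- function(stations, event_hours, station_id,
                                  pollutants, max_lag, max_frac_masked) {
  out <- matrix(NA_real_, length(event_hours), length(pollutants),
                dimnames = list(NULL, pollutants))
  flagged <- rep(FALSE, length(event_hours))
  for (sid in unique(station_id)) {
    idx <- which(station_id == sid)
    ser <- stations[stations$station_id == sid, , drop = FALSE]
    pm <- pollutant_means(ser, event_hours[idx], max_lag = max_lag,
                          pollutants = pollutants,
                          max_frac_masked = max_frac_masked)
    out[idx, ] <- as.matrix(pm[, pollutants])
    flagged[idx] <- pm$flagged
  }
  list(means = out, flagged = flagged)
}

#' Fit the full case-crossover DLNM analysis
#'
#' Runs the entire pipeline: nearest-station assignment with the
#' distance cutoff, time-stratified stratum expansion, backward lag
#' matrices, two-stage extreme-value trimming, event/stratum exclusion,
#' cross-basis construction, pollutant covariates, conditional-logistic
#' fitting, and the standard effect summaries (lag-specific and
#' cumulative odds ratios at the extreme-vs-reference contrast).
#'
#' @param patients Onset records tibble (`patient_id`, `onset_time`,
#'   `lat`, `lon`, covariates).
#' @param stations Station series tibble as from [simulate_weather()] or
#'   [read_station_csv()].
#' @param config A [run_config()].
#' @return Object of class `cc_dlnm` with components `fit`,
#'   `interaction_test` (when requested), `effects` (list of `lag` and
#'   `cumulative` tibbles), `contrasts`, `trims`, `cross_bases`,
#'   `events`, `exclusions`, `config`.
#' @export
cc_dlnm <- function(patients, stations, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  L <- config$max_lag

  assign <- match_station(patients, stations, config$max_station_km)
  excl_distance <- assign[assign$excluded, c("patient_id", "distance_km")]
  kept <- dplyr::inner_join(patients,
                            assign[!assign$excluded, c("patient_id", "station_id")],
                            by = "patient_id")
  if (nrow(kept) == 0) abort("no patients within the station radius")

  events <- expand_strata(kept)
  # exposure lag matrices + two-stage trimming (pool = case windows)
  case_rows <- which(events$is_case)
  trims <- list()
  for (ex in config$exposures) {
    lm_ex <- lag_matrix_for_events(stations, events$event_time,
                                   events$station_id, ex, L)
    trims[[ex]] <- trim_extremes(
      lm_ex, pool_rows = case_rows,
      trim_probs = config$trim_probs,
      contrast_prob = config$contrast_prob, ref_prob = config$ref_prob,
      retain_extremes = config$retain_extremes
    )
  }

  surv <- do.call(build_strata,
                  c(list(events), unname(trims),
                    list(max_frac_masked = config$max_frac_masked)))
  excl_strata <- attr(surv, "exclusions")
  keep_idx <- attr(surv, "kept_rows")

  # pollutant covariates (may drop further events)
  poll <- NULL
  if (config$adjust_pollutants) {
    pf <- pollutants_for_events(stations, surv$event_time, surv$station_id,
                                config$pollutants, L, config$max_frac_masked)
    ok <- stats::complete.cases(pf$means)
    if (!all(ok)) {
      surv <- surv[ok, , drop = FALSE]
      keep_idx <- keep_idx[ok]
      pf$means <- pf$means[ok, , drop = FALSE]
      # re-check stratum survival after pollutant-driven drops
      n_ctrl <- tapply(!surv$is_case, surv$stratum_id, sum)
      has_case <- tapply(surv$is_case, surv$stratum_id, any)
      good <- as.integer(names(n_ctrl))[n_ctrl >= 1 & has_case]
      sel <- surv$stratum_id %in% good
      surv <- surv[sel, , drop = FALSE]
      keep_idx <- keep_idx[sel]
      pf$means <- pf$means[sel, , drop = FALSE]
    }
    poll <- scale(pf$means, center = TRUE, scale = FALSE)
  }

  # cross-bases on surviving rows
  cbs <- list()
  contrasts <- list()
  for (ex in config$exposures) {
    tr <- trims[[ex]]
    sub <- tr$lagmat
    sub$Q <- sub$Q[keep_idx, , drop = FALSE]
    sub$event_hours <- sub$event_hours[keep_idx]
    sub <- complete_windows(sub)
    pool_vals <- tr$lagmat$Q[case_rows, , drop = FALSE]
    spec <- basis_spec("natural_cubic", df = config$exposure_df,
                       knots = config$exposure_knots[[ex]],
                       boundary = config$exposure_boundary[[ex]],
                       intercept = FALSE)
    if (!is_resolved(spec)) spec <- resolve_spec(spec, as.numeric(pool_vals))
    lspec <- lag_basis_spec(L, config$lag_knots)
    cbs[[ex]] <- cross_basis(sub, spec, lspec)
    cv <- config$contrast_values[[ex]]
    contrasts[[ex]] <- if (!is.null(cv)) {
      c(x_ext = cv[1], x_ref = cv[2])
    } else {
      c(x_ext = tr$x_ext, x_ref = tr$x_ref)
    }
  }

  rh_mean24 <- NULL
  if (config$interaction) {
    if (length(config$exposures) < 2) {
      abort("interaction requires two exposures")
    }
    rh_tr <- trims[[config$exposures[2]]]
    rh_mean24 <- rowMeans(rh_tr$lagmat$Q[keep_idx, , drop = FALSE], na.rm = TRUE)
  }

  des <- assemble_design(cbs[[1]],
                         rh_cb = if (length(cbs) > 1) cbs[[2]],
                         pollutants = poll,
                         interaction = config$interaction,
                         rh_mean24 = rh_mean24)
  fit <- fit_clogit(des$X, surv$is_case, surv$stratum_id)
  interaction_test <- NULL
  if (config$interaction) {
    reduced_cols <- setdiff(seq_len(ncol(des$X)), des$blocks$interaction)
    fit_reduced <- fit_clogit(des$X[, reduced_cols, drop = FALSE],
                              surv$is_case, surv$stratum_id)
    interaction_test <- likelihood_ratio_test(fit, fit_reduced)
    fit_full <- fit
    fit <- fit_reduced               # effects come from the main model
  } else {
    fit_full <- NULL
  }

  eff_lag <- purrr::map(config$exposures, function(ex) {
    ctr <- contrasts[[ex]]
    lag_specific_or(fit, cbs[[ex]], ctr[["x_ext"]], ctr[["x_ref"]])
  }) |> purrr::list_rbind()
  eff_cum <- purrr::map(config$exposures, function(ex) {
    ctr <- contrasts[[ex]]
    windows <- config$cumulative_windows[[ex]] %||% list(c(0, L))
    purrr::map(windows, function(w) {
      cumulative_or(fit, cbs[[ex]], ctr[["x_ext"]], ctr[["x_ref"]],
                    window = pmin(w, L))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(
    fit = fit, fit_interaction = fit_full,
    interaction_test = interaction_test,
    effects = list(lag = eff_lag, cumulative = eff_cum),
    contrasts = contrasts, trims = trims, cross_bases = cbs,
    events = surv,
    exclusions = list(distance = excl_distance, strata = excl_strata,
                      n_input = nrow(patients),
                      n_after_distance = nrow(kept),
                      n_strata_fit = fit$n_strata),
    config = config
  ), class = "cc_dlnm")
}

#' @export
print.cc_dlnm <- function(x, ...) {
  cat("<cc_dlnm> case-crossover DLNM fit\n")
  cat("  patients in: ", x$exclusions$n_input,
      "; within station radius: ", x$exclusions$n_after_distance,
      "; strata fitted: ", x$exclusions$n_strata_fit, "\n", sep = "")
  for (ex in names(x$contrasts)) {
    ctr <- x$contrasts[[ex]]
    cat(sprintf("  %s: contrast %.3g vs reference %.3g\n",
                ex, ctr[["x_ext"]], ctr[["x_ref"]]))
  }
  cum <- x$effects$cumulative
  cat("  cumulative odds ratios:\n")
  for (i in seq_len(nrow(cum))) {
    cat(sprintf("    %s %s: OR %.2f (95%% CI %.2f-%.2f)\n",
                cum$exposure[i], cum$label[i], cum$or[i],
                cum$ci_low[i], cum$ci_high[i]))
  }
  if (!is.null(x$interaction_test)) {
    cat(sprintf("  interaction LRT: chi2 = %.3f, df = %d, p = %.3f\n",
                x$interaction_test$statistic, x$interaction_test$df,
                x$interaction_test$p.value))
  }
  invisible(x)
}

#' @export
tidy.cc_dlnm <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$effects$lag, type = "lag"),
    dplyr::mutate(x$effects$cumulative, type = "cumulative")
  )
}

#' @export
glance.cc_dlnm <- function(x, ...) {
  tibble::tibble(
    n.patients = x$exclusions$n_input,
    n.strata = x$exclusions$n_strata_fit,
    logLik = x$fit$loglik,
    converged = x$fit$converged,
    interaction.p = if (is.null(x$interaction_test)) NA_real_ else
      x$interaction_test$p.value
  )
}

#' The nine-variant sensitivity grid
#'
#' Enumerates the sensitivity analyses of the shipped design: pollutant
#' removal, exposure-spline df 4, maximum lag 36 h and 48 h, retention
#' of extreme values, and extreme-contrast percentiles 2.5/5/10/15 (each
#' against the 99th-percentile reference).
#'
#' @return Tibble with `variant`, `description`, and a list-column
#'   `modify` of functions that transform a [run_config()].
#' @export
sensitivity_variants <- function() {
  tweak <- function(...) {
    deltas <- list(...)
    function(cfg) {
      for (nm in names(deltas)) cfg[[nm]] <- deltas[[nm]]
      if ("max_lag" %in% names(deltas)) {
        cfg$cumulative_windows <- lapply(cfg$cumulative_windows,
                                         function(ws) lapply(ws, pmin, cfg$max_lag))
      }
      cfg
    }
  }
  tibble::tibble(
    variant = c("no_pollutants", "spline_df_4", "max_lag_36", "max_lag_48",
                "retain_extremes", "contrast_p2.5", "contrast_p5",
                "contrast_p10", "contrast_p15"),
    description = c("remove air pollutant covariates",
                    "natural cubic spline df 4 in the exposure dimension",
                    "maximum lag period 36 h",
                    "maximum lag period 48 h",
                    "retain extreme exposure values (no stage-1 trimming)",
                    "2.5th-percentile extreme contrast",
                    "5th-percentile extreme contrast",
                    "10th-percentile extreme contrast",
                    "15th-percentile extreme contrast"),
    modify = list(
      tweak(adjust_pollutants = FALSE),
      tweak(exposure_df = 4L),
      tweak(max_lag = 36L),
      tweak(max_lag = 48L),
      tweak(retain_extremes = TRUE),
      tweak(contrast_prob = 0.025),
      tweak(contrast_prob = 0.05),
      tweak(contrast_prob = 0.10),
      tweak(contrast_prob = 0.15)
    )
  )
}

#' Run the main analysis plus the nine sensitivity variants
#'
#' Refits the pipeline once per variant and tabulates the primary
#' cumulative odds ratio per exposure (the first window listed in the
#' configuration for that exposure).  A variant that fails to converge
#' is reported with `converged = FALSE`, not an error.
#'
#' @inheritParams cc_dlnm
#' @return Tibble: `variant`, `description`, `exposure`, `x`, `x_ref`,
#'   `window`, `or`, `ci_low`, `ci_high`, `converged`.
#' @export
run_sensitivity_suite <- function(patients, stations, config = run_config()) {
  variants <- sensitivity_variants()
  extract <- function(res, variant, description) {
    cum <- res$effects$cumulative
    purrr::map(names(res$contrasts), function(ex) {
      rows <- cum[cum$exposure == ex, ]
      rows[1, ] |>
        dplyr::transmute(variant = variant, description = description,
                         exposure = .data$exposure, x = .data$x,
                         x_ref = .data$x_ref, window = .data$label,
                         or = .data$or, ci_low = .data$ci_low,
                         ci_high = .data$ci_high,
                         converged = res$fit$converged)
    }) |> purrr::list_rbind()
  }
  main <- cc_dlnm(patients, stations, config)
  out <- list(extract(main, "main", "main analysis"))
  for (i in seq_len(nrow(variants))) {
    cfg_i <- variants$modify[[i]](config)
    row <- tryCatch(
      extract(cc_dlnm(patients, stations, cfg_i),
              variants$variant[i], variants$description[i]),
      error = function(e) tibble::tibble(
        variant = variants$variant[i], description = variants$description[i],
        exposure = config$exposures, x = NA_real_, x_ref = NA_real_,
        window = NA_character_, or = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, converged = FALSE)
    )
    out <- c(out, list(row))
  }
  purrr::list_rbind(out)
}

#' Subgroup analyses with z-tests against a reference level
#'
#' Refits the full pipeline on each level of a patient covariate
#' (case-crossover strata are patient-specific, so subsetting patients
#' subsets strata exactly) and compares each level's primary cumulative
#' log odds ratio to the first level's by a two-sample z-test.
#'
#' @inheritParams cc_dlnm
#' @param by Name of the patient covariate to stratify on.
#' @param exposure Exposure whose primary cumulative OR is compared
#'   (default the first configured exposure).
#' @return Tibble: `level`, `n`, `or`, `ci_low`, `ci_high`, `z`,
#'   `p.value` (z/p are NA for the reference level).
#' @export
subgroup_effects <- function(patients, stations, config = run_config(),
                             by, exposure = config$exposures[1]) {
  if (!by %in% names(patients)) abort(paste0("no column '", by, "' in patients"))
  levels <- unique(patients[[by]])
  ests <- purrr::map(levels, function(lv) {
    sub <- patients[patients[[by]] == lv, , drop = FALSE]
    res <- cc_dlnm(sub, stations, config)
    cum <- res$effects$cumulative
    cum[cum$exposure == exposure, ][1, ]
  })
  ref <- ests[[1]]
  purrr::map2(levels, ests, function(lv, est) {
    zt <- if (identical(lv, levels[1])) {
      tibble::tibble(z = NA_real_, p.value = NA_real_)
    } else {
      subgroup_ztest(est, ref)
    }
    tibble::tibble(level = as.character(lv),
                   n = sum(patients[[by]] == lv),
                   or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
                   z = zt$z, p.value = zt$p.value)
  }) |> purrr::list_rbind()
}
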