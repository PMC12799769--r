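# internal: delta-method effect rows from full-length contrast vectors
effect_from_contrast <- function(fit, Cmat, block_idx, labels, exposure,
                                 x, x_ref, conf_q = 1.96) {
  beta <- fit$coefficients[block_idx]
  Sig <- fit$vcov[block_idx, block_idx, drop = FALSE]
  log_or <- as.numeric(Cmat %*% beta)
  se <- sqrt(pmax(0, rowSums((Cmat %*% Sig) * Cmat)))
  tibble::tibble(
    exposure = exposure, label = labels,
    x = x, x_ref = x_ref,
    log_or = log_or, se = se,
    or = exp(log_or),
    ci_low = exp(log_or - conf_q * se),
    ci_high = exp(log_or + conf_q * se)
  )
}

check_fit_cb <- function(fit, cb, block) {
  stopifnot(inherits(fit, "cc_fit"), inherits(cb, "cross_basis"))
  if (fit$separation || !fit$converged) abort("fit did not converge")
  if (is.null(block)) {
    block <- which(names(fit$coefficients) %in% colnames(cb$W))
  }
  if (length(block) != ncol(cb$W)) {
    abort("could not align cross-basis columns with fit coefficients")
  }
  block
}

#' Lag-specific odds ratios for an exposure contrast
#'
#' `log OR(x, l) = sum_jk beta_jk [B_j(x) - B_j(x_ref)] C_k(l)`; the
#' standard error comes from the delta method, `sqrt(c' Sigma c)` with
#' `c` the contrast vector.  Values of `x` beyond the exposure boundary
#' knots are evaluated with the natural-spline linear extrapolation and
#' flagged.
#'
#' @param fit A converged [fit_clogit()] result.
#' @param cb The [cross_basis()] whose columns sit in `fit` (matched by
#'   column name unless `block` is given).
#' @param x Exposure value to contrast against the reference.
#' @param x_ref Reference exposure value.
#' @param lags Integer vector of lags (default all `0..max_lag`).
#' @param block Optional integer indices of the cross-basis columns
#'   within the fit's coefficient vector.
#' @return Tibble of effect estimates (class `cc_effect`): one row per
#'   lag with `log_or`, `se`, `or`, `ci_low`, `ci_high`, `extrapolated`.
#' @export
lag_specific_or <- function(fit, cb, x, x_ref, lags = 0:cb$max_lag,
                            block = NULL) {
  block <- check_fit_cb(fit, cb, block)
  if (any(lags < 0 | lags > cb$max_lag)) abort("lags must lie in [0, max_lag]")
  Cm <- cb_contrast(cb, x, x_ref, lags)
  out <- effect_from_contrast(fit, Cm, block,
                              labels = paste0("lag ", lags),
                              exposure = cb$exposure, x = x, x_ref = x_ref)
  out$lag <- lags
  bk <- cb$exposure_spec$boundary
  out$extrapolated <- !is.null(bk) && (x < bk[1] || x > bk[2])
  class(out) <- c("cc_effect", class(out))
  out
}

#' Cumulative odds ratio over a lag window
#'
#' The cumulative log odds ratio over `window = c(l0, l1)` is the sum of
#' the lag-specific log odds ratios over those lags; its standard error
#' is the delta method applied to the summed contrast vector.
#'
#' @inheritParams lag_specific_or
#' @param window Length-2 integer vector `c(l0, l1)`, `0 <= l0 <= l1 <= L`.
#' @return One-row tibble of class `cc_effect`.
#' @export
cumulative_or <- function(fit, cb, x, x_ref, window = c(0, cb$max_lag),
                          block = NULL) {
  block <- check_fit_cb(fit, cb, block)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 0 || window[2] > cb$max_lag) {
    abort("window must be c(l0, l1) with 0 <= l0 <= l1 <= max_lag")
  }
  lags <- seq(window[1], window[2])
  Cm <- matrix(colSums(cb_contrast(cb, x, x_ref, lags)), nrow = 1)
  out <- effect_from_contrast(fit, Cm, block,
                              labels = sprintf("lag %d-%d", window[1], window[2]),
                              exposure = cb$exposure, x = x, x_ref = x_ref)
  out$lag_from <- window[1]
  out$lag_to <- window[2]
  bk <- cb$exposure_spec$boundary
  out$extrapolated <- !is.null(bk) && (x < bk[1] || x > bk[2])
  class(out) <- c("cc_effect", class(out))
  out
}

#' Exposure-lag-response surface of odds ratios
#'
#' Evaluates `OR(x, l)` against the reference on a grid, for export or
#' 3-D plotting.
#'
#' @inheritParams lag_specific_or
#' @param x_grid Numeric vector of exposure values.
#' @param lag_grid Integer vector of lags (default `0..max_lag`).
#' @return Long tibble (class `cc_surface`): `exposure`, `x`, `lag`,
#'   `log_or`, `se`, `or`, `ci_low`, `ci_high`, `extrapolated`.
#' @export
effect_surface <- function(fit, cb, x_grid, x_ref, lag_grid = 0:cb$max_lag,
                           block = NULL) {
  block <- check_fit_cb(fit, cb, block)
  bk <- cb$exposure_spec$boundary
  rows <- purrr::map(x_grid, function(x) {
    Cm <- cb_contrast(cb, x, x_ref, lag_grid)
    out <- effect_from_contrast(fit, Cm, block,
                                labels = paste0("lag ", lag_grid),
                                exposure = cb$exposure, x = x, x_ref = x_ref)
    out$lag <- lag_grid
    out$extrapolated <- !is.null(bk) && (x < bk[1] || x > bk[2])
    out
  }) |> purrr::list_rbind()
  class(rows) <- c("cc_surface", class(rows))
  rows
}

#' Two-sample z-test comparing two effect estimates
#'
#' `z = (log_or1 - log_or2) / sqrt(se1^2 + se2^2)` with a two-sided
#' normal p-value; used to compare stratum-specific (subgroup)
#' estimates.
#'
#' @param est1,est2 One-row effect tibbles (from [cumulative_or()] or
#'   [lag_specific_or()]), or lists with `log_or` and `se`.
#' @return Tibble: `z`, `p.value`.
#' @export
subgroup_ztest <- function(est1, est2) {
  if (est1$se[1] <= 0 || est2$se[1] <= 0) {
    abort("standard errors must be positive")
  }
  z <- (est1$log_or[1] - est2$log_or[1]) / sqrt(est1$se[1]^2 + est2$se[1]^2)
  tibble::tibble(z = z, p.value = 2 * pnorm(-abs(z)))
}
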