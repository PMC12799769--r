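#' Plot lag-specific odds ratios
#'
#' Line-and-ribbon lag pattern: OR with its 95% CI across lags, one
#' panel per exposure, with the null line at OR = 1.
#'
#' @param effects A `cc_effect` tibble from [lag_specific_or()] (or the
#'   `lag` rows of [tidy.cc_dlnm()]).
#' @return A ggplot object.
#' @export
plot_lag_pattern <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$lag, y = .data$or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~exposure, scales = "free_y") +
    ggplot2::labs(x = "lag (hours)", y = "odds ratio",
                  title = "Lag-specific odds ratios, extreme vs reference")
}

#' Plot an exposure-lag-response surface
#'
#' Tile map of OR(x, lag) against the reference exposure.
#'
#' @param surface A `cc_surface` tibble from [effect_surface()].
#' @return A ggplot object.
#' @export
plot_surface <- function(surface) {
  ggplot2::ggplot(surface,
                  ggplot2::aes(x = .data$x, y = .data$lag, fill = .data$or)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "exposure", y = "lag (hours)", fill = "OR",
                  title = "Exposure-lag-response surface")
}

#' Plot a cumulative exposure-response curve
#'
#' Cumulative OR over a fixed lag window as a function of exposure.
#'
#' @param curve A `cc_effect` tibble of cumulative estimates evaluated
#'   over an exposure grid (see the examples in the vignette).
#' @return A ggplot object.
#' @export
plot_cumulative_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "exposure", y = "cumulative odds ratio")
}

#' @export
autoplot.cc_dlnm <- function(object, type = c("lag", "surface"), ...) {
  type <- match.arg(type)
  if (type == "lag") {
    return(plot_lag_pattern(object$effects$lag))
  }
  ex <- object$config$exposures[1]
  cb <- object$cross_bases[[ex]]
  ctr <- object$contrasts[[ex]]
  grid <- seq(cb$exposure_spec$boundary[1], cb$exposure_spec$boundary[2],
              length.out = 40)
  plot_surface(effect_surface(object$fit, cb, grid, ctr[["x_ref"]]))
}
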