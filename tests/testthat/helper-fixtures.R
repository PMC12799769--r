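# shared fixture builders: everything is generated in code at test time

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a deterministic single-station hourly series whose temperature equals the
# hour index, starting at a known origin; handy for lag-matrix arithmetic
index_station <- function(n_hours = 200, start = "2021-06-01 00:00",
                          station_id = "ST01", lat = 32.5, lon = 110.5) {
  tt <- seq(utc(start), by = 3600, length.out = n_hours)
  tibble::tibble(
    station_id = station_id, lat = lat, lon = lon, timestamp = tt,
    temp_c = seq_len(n_hours) - 1, rh_pct = 70,
    pm25 = 17.8, pm10 = 30, so2 = 7, no2 = 8, o3 = 80, co = 0.6
  )
}

# simulate matched case-control sets directly from the conditional model:
# covariates X, one case per stratum drawn with prob proportional to exp(X beta)
make_strata <- function(n_strata, size = 4, beta = 0, n_covariates = length(beta),
                        x_fun = function(n) matrix(rnorm(n * n_covariates), ncol = n_covariates)) {
  n <- n_strata * size
  X <- x_fun(n)
  si <- rep(seq_len(n_strata), each = size)
  eta <- as.numeric(X %*% beta)
  case <- logical(n)
  for (s in seq_len(n_strata)) {
    ix <- which(si == s)
    p <- exp(eta[ix] - max(eta[ix]))
    case[ix[sample.int(size, 1, prob = p / sum(p))]] <- TRUE
  }
  list(X = X, case = case, stratum = si)
}

# enumeration oracle for the matched-set log-likelihood: direct arithmetic,
# one stratum at a time, no shared code with the package implementation
enum_loglik <- function(beta, X, case, stratum) {
  ll <- 0
  for (s in unique(stratum)) {
    ix <- which(stratum == s)
    eta <- as.numeric(X[ix, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[ix]] - log(sum(exp(eta)))
  }
  ll
}

# a lag_matrix object straight from a value matrix (bypasses any series)
raw_lag_matrix <- function(Q, exposure = "temp_c", event_hours = NULL) {
  if (is.null(event_hours)) {
    event_hours <- utc("2021-01-02 00:00") + 3600 * seq_len(nrow(Q))
  }
  structure(list(Q = Q, event_hours = event_hours,
                 exposure = exposure, max_lag = ncol(Q) - 1L),
            class = "lag_matrix")
}

# a fixed, non-separated tiny instance (5 strata of 3, one covariate):
# the case does not always carry the extreme covariate value, so the
# conditional MLE is finite and a grid search can bracket it
tiny_instance <- function() {
  X <- matrix(c(0.5, 1.2, -0.3,
                -0.2, 0.4, 0.1,
                1.0, 0.8, 1.5,
                0.0, -0.5, 0.3,
                0.7, 0.9, -1.0), ncol = 1, byrow = TRUE)
  list(X = X,
       case = rep(c(TRUE, FALSE, FALSE), 5),
       stratum = rep(1:5, each = 3))
}

# draw one case uniformly within each stratum (global null)
uniform_cases <- function(stratum) {
  case <- logical(length(stratum))
  for (s in unique(stratum)) {
    ix <- which(stratum == s)
    case[ix[sample.int(length(ix), 1)]] <- TRUE
  }
  case
}

# one replicate of the interaction-LRT null experiment: no exposure effect,
# no interaction; returns the LRT p-value for the interaction block
lrt_null_once <- function(n_strata = 200, size = 4) {
  repeat {
    n <- n_strata * size
    Q <- matrix(15 + 8 * as.numeric(stats::filter(rnorm(n * 25), 0.9,
                                                  method = "recursive")), n, 25)
    es <- basis_spec("natural_cubic", knots = 15, boundary = range(Q))
    lsp <- basis_spec("natural_cubic", knots = 5, boundary = c(0, 24),
                      intercept = TRUE)
    cb <- cross_basis(raw_lag_matrix(Q), es, lsp)
    des <- assemble_design(cb, interaction = TRUE, rh_mean24 = rnorm(n, 70, 10))
    si <- rep(seq_len(n_strata), each = size)
    case <- uniform_cases(si)
    f1 <- fit_clogit(des$X, case, si)
    f0 <- fit_clogit(des$X[, des$blocks$temp, drop = FALSE], case, si)
    # a handful of replicates per thousand are quasi-separated and carry
    # no usable likelihood ratio; redraw those
    if (f1$converged && f0$converged) {
      return(likelihood_ratio_test(f1, f0)$p.value)
    }
  }
}

# one replicate of the subgroup z-test null: two independent groups with the
# same (zero) effect, compared on a single-lag linear-basis log odds ratio
ztest_null_once <- function(n_strata = 150, size = 4) {
  one_group <- function() {
    d <- make_strata(n_strata, size, beta = 0, n_covariates = 1)
    cb <- cross_basis(raw_lag_matrix(d$X, exposure = "x"),
                      basis_spec("linear"), basis_spec("constant"))
    fit <- fit_clogit(cb$W, d$case, d$stratum)
    lag_specific_or(fit, cb, x = 1, x_ref = 0, lags = 0)
  }
  subgroup_ztest(one_group(), one_group())$p.value
}
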