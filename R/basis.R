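#' Specify a one-dimensional basis
#'
#' Describes a basis over exposure values or lags: a natural cubic
#' spline (piecewise cubic, continuous second derivatives, linear beyond
#' the boundary knots), a plain linear term, or a constant.  For a
#' natural cubic spline `df = (#internal knots) + 1 + (1 if intercept)`.
#' A spec created with `df` but no knots is *unresolved*: call
#' [resolve_spec()] with data to place internal knots at equally spaced
#' quantiles and boundary knots at the data range.
#'
#' @param kind `"natural_cubic"`, `"linear"`, or `"constant"`.
#' @param df Requested degrees of freedom (natural_cubic only).
#' @param knots Internal knot values (natural_cubic only).
#' @param boundary Length-2 boundary knots bracketing the internal knots.
#' @param intercept Include the constant in the basis span?
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("natural_cubic", "linear", "constant"),
                       df = NULL, knots = NULL, boundary = NULL,
                       intercept = FALSE) {
  kind <- match.arg(kind)
  if (kind == "natural_cubic") {
    if (!is.null(knots)) {
      knots <- sort(as.numeric(knots))
      df <- length(knots) + 1L + as.integer(intercept)
      if (!is.null(boundary)) {
        boundary <- sort(as.numeric(boundary))
        if (length(knots) && (min(knots) <= boundary[1] ||
                              max(knots) >= boundary[2])) {
          abort("boundary knots must strictly bracket the internal knots")
        }
      }
    } else if (is.null(df)) {
      abort("natural_cubic spec needs df or knots")
    }
    df <- as.integer(df)
    if (df < 1 + as.integer(intercept)) abort("df too small for a natural spline")
  } else {
    df <- if (kind == "linear") 1L else 1L
    intercept <- kind == "constant"
  }
  structure(list(kind = kind, df = df, knots = knots, boundary = boundary,
                 intercept = intercept),
            class = "basis_spec")
}

is_resolved <- function(spec) {
  spec$kind != "natural_cubic" ||
    (!is.null(spec$boundary) &&
       (!is.null(spec$knots) || spec$df == 1L + as.integer(spec$intercept)))
}

#' Resolve a df-only spline spec against data
#'
#' Places the internal knots at equally spaced quantiles of `values`
#' (probabilities `1/(m+1), ..., m/(m+1)` for m internal knots) and the
#' boundary knots at the data range — the conventional default for
#' exposure dimensions of distributed-lag models.
#'
#' @param spec A [basis_spec()].
#' @param values Numeric values (NA ignored) supplying the quantiles.
#' @return A resolved `basis_spec` with knots and boundary set.
#' @export
resolve_spec <- function(spec, values) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$kind != "natural_cubic" || is_resolved(spec)) return(spec)
  values <- values[!is.na(values)]
  m <- spec$df - 1L - as.integer(spec$intercept)
  if (m > 0) {
    spec$knots <- pctl(values, seq_len(m) / (m + 1))
  } else {
    spec$knots <- numeric(0)
  }
  spec$boundary <- range(values)
  spec
}

#' Evaluate a basis at given values
#'
#' Natural cubic splines are evaluated with [splines::ns()] (with the
#' spec's internal and boundary knots), which extrapolates linearly
#' beyond the boundary knots.  Rows with `NA` input propagate `NA`.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A resolved [basis_spec()].
#' @return Numeric matrix, `length(x)` rows and `spec$df` columns.
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- as.numeric(x)
  if (spec$kind == "constant") {
    return(matrix(1, length(x), 1))
  }
  if (spec$kind == "linear") {
    return(matrix(x, length(x), 1))
  }
  if (!is_resolved(spec)) abort("spec is unresolved; call resolve_spec() first")
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok, ] <- splines::ns(x[ok],
                             knots = if (length(spec$knots)) spec$knots,
                             Boundary.knots = spec$boundary,
                             intercept = spec$intercept)
  }
  out
}

#' Log-spaced internal knots for the lag dimension
#'
#' Internal knots at `exp(i * log(L) / (n_knots + 1))` for
#' `i = 1..n_knots`: strictly increasing, inside `(0, L)`, denser at
#' short lags where delayed effects change fastest.
#'
#' @param max_lag Maximum lag L in hours (>= 1).
#' @param n_knots Number of internal knots (>= 1, < L).
#' @return Numeric vector of internal knot positions.
#' @export
#' @examples
#' log_lag_knots(24, 3)   # 24^(1/4), sqrt(24), 24^(3/4)
log_lag_knots <- function(max_lag, n_knots = 3) {
  if (max_lag < 1) abort("max_lag must be >= 1")
  if (n_knots < 1) abort("n_knots must be >= 1")
  if (n_knots >= max_lag) abort("n_knots must be smaller than max_lag")
  exp(seq_len(n_knots) * log(max_lag) / (n_knots + 1))
}

#' Default lag-dimension spline spec
#'
#' Natural cubic spline over `0..max_lag` with intercept and log-spaced
#' internal knots.
#'
#' @param max_lag Maximum lag L.
#' @param n_knots Number of internal log-spaced knots (default 3).
#' @return A resolved [basis_spec()].
#' @export
lag_basis_spec <- function(max_lag, n_knots = 3) {
  basis_spec("natural_cubic", knots = log_lag_knots(max_lag, n_knots),
             boundary = c(0, max_lag), intercept = TRUE)
}

#' Cross-basis of exposure and lag bases
#'
#' Builds the tensor-product design block of a distributed lag non-linear
#' model: `W[i, (j,k)] = sum_{l=0..L} B_j(Q[i, l]) * C_k(l)` where `B`
#' are the exposure-basis functions and `C` the lag-basis functions.
#' Columns are ordered exposure-major: column `(j, k)` sits at index
#' `(j-1) * v_l + k`.
#'
#' @param lagmat A [build_lag_matrix()] result (or trimmed copy) with no
#'   masked cells in the rows supplied; masked rows must be excluded
#'   upstream.
#' @param exposure_spec Resolved [basis_spec()] for the exposure axis.
#' @param lag_spec Resolved [basis_spec()] for the lag axis.
#' @return Object of class `cross_basis`: list with `W` (matrix),
#'   `exposure_spec`, `lag_spec`, `max_lag`, `exposure`.
#' @export
cross_basis <- function(lagmat, exposure_spec, lag_spec) {
  stopifnot(inherits(lagmat, "lag_matrix"))
  if (anyNA(lagmat$Q)) {
    abort("cross_basis requires fully observed rows; exclude masked rows upstream")
  }
  if (!is_resolved(exposure_spec)) {
    abort("exposure_spec is unresolved; call resolve_spec() first")
  }
  L <- lagmat$max_lag
  C <- natural_cubic_basis(0:L, lag_spec)
  vx <- exposure_spec$df
  vl <- lag_spec$df
  n <- nrow(lagmat$Q)
  W <- matrix(0, n, vx * vl)
  for (l in 0:L) {
    B <- natural_cubic_basis(lagmat$Q[, l + 1], exposure_spec)
    W <- W + B[, rep(seq_len(vx), each = vl), drop = FALSE] *
      rep(C[l + 1, ], vx)[col(W)]
  }
  colnames(W) <- paste0(lagmat$exposure, ".b",
                        rep(seq_len(vx), each = vl), ".l",
                        rep(seq_len(vl), vx))
  structure(list(W = W, exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = L, exposure = lagmat$exposure),
            class = "cross_basis")
}

#' @export
print.cross_basis <- function(x, ...) {
  cat("<cross_basis> ", x$exposure, ": ", nrow(x$W), " rows, ",
      x$exposure_spec$df, " x ", x$lag_spec$df, " = ", ncol(x$W),
      " columns, lags 0..", x$max_lag, "\n", sep = "")
  invisible(x)
}

# contrast rows for effects: for each lag in `lags`, the coefficient
# weights of log OR(x vs x_ref) at that lag
cb_contrast <- function(cb, x, x_ref, lags) {
  B <- natural_cubic_basis(c(x, x_ref), cb$exposure_spec)
  db <- B[1, ] - B[2, ]
  C <- natural_cubic_basis(lags, cb$lag_spec)
  vx <- cb$exposure_spec$df
  vl <- cb$lag_spec$df
  out <- matrix(0, length(lags), vx * vl)
  for (j in seq_len(vx)) {
    out[, (j - 1) * vl + seq_len(vl)] <- db[j] * C
  }
  out
}

#' Assemble the conditional-logistic design matrix
#'
#' Column blocks: temperature cross-basis, optional humidity
#' cross-basis, optional linear pollutant covariates, and an optional
#' temperature-by-humidity interaction block formed as the elementwise
#' product of the temperature cross-basis columns with each event's
#' centred 24-h mean relative humidity (a rank-reduced interaction:
#' humidity enters the product as a scalar).
#'
#' @param temp_cb [cross_basis()] for temperature.
#' @param rh_cb Optional [cross_basis()] for relative humidity.
#' @param pollutants Optional numeric matrix/data frame of per-event
#'   covariates entered linearly.
#' @param interaction Add the interaction block?
#' @param rh_mean24 Per-event 24-h mean relative humidity (required when
#'   `interaction = TRUE`); centred internally.
#' @return List: `X` (design matrix), `blocks` (named list of column
#'   index vectors).
#' @export
assemble_design <- function(temp_cb, rh_cb = NULL, pollutants = NULL,
                            interaction = FALSE, rh_mean24 = NULL) {
  n <- nrow(temp_cb$W)
  parts <- list(temp = temp_cb$W)
  if (!is.null(rh_cb)) {
    if (nrow(rh_cb$W) != n) abort("block 'rh' is misaligned with block 'temp'")
    parts$rh <- rh_cb$W
  }
  if (!is.null(pollutants)) {
    P <- as.matrix(pollutants)
    if (nrow(P) != n) abort("block 'pollutants' is misaligned with block 'temp'")
    parts$pollutants <- P
  }
  if (interaction) {
    if (is.null(rh_mean24)) abort("interaction block needs rh_mean24")
    if (length(rh_mean24) != n) {
      abort("block 'interaction' is misaligned with block 'temp'")
    }
    z <- rh_mean24 - mean(rh_mean24)
    Xi <- temp_cb$W * z
    colnames(Xi) <- paste0("ix.", colnames(temp_cb$W))
    parts$interaction <- Xi
  }
  X <- do.call(cbind, parts)
  sizes <- vapply(parts, ncol, integer(1))
  ends <- cumsum(sizes)
  blocks <- purrr::map2(ends - sizes + 1L, ends, seq)
  names(blocks) <- names(parts)
  list(X = X, blocks = blocks)
}
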