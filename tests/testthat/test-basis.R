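test_that("natural spline basis has the declared dimension and span", {
  spec <- basis_spec("natural_cubic", df = 3)
  spec <- resolve_spec(spec, seq(0, 10, by = 0.1))
  x <- seq(0.2, 9.8, length.out = 50)
  B <- natural_cubic_basis(x, spec)
  expect_equal(ncol(B), 3L)
  # linear functions lie in the span of basis + intercept
  fit <- lm.fit(cbind(1, B), 2 * x + 1)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("the natural spline is linear beyond its boundary knots", {
  spec <- basis_spec("natural_cubic", knots = c(3, 6), boundary = c(0, 10))
  xout <- seq(11, 15, by = 0.25)
  B <- natural_cubic_basis(xout, spec)
  d2 <- diff(B, differences = 2)
  expect_lt(max(abs(d2)) / max(abs(B)), 1e-8)
  xlow <- seq(-5, -1, by = 0.25)
  d2l <- diff(natural_cubic_basis(xlow, spec), differences = 2)
  expect_lt(max(abs(d2l)), 1e-8)
})

test_that("NA inputs propagate as masked basis rows", {
  spec <- basis_spec("natural_cubic", knots = 5, boundary = c(0, 10))
  B <- natural_cubic_basis(c(1, NA, 9), spec)
  expect_true(all(is.na(B[2, ])))
  expect_false(anyNA(B[c(1, 3), ]))
})

test_that("log-spaced lag knots follow the closed form", {
  k <- log_lag_knots(24, 3)
  expect_equal(k, exp((1:3) * log(24) / 4), tolerance = 1e-12)
  expect_equal(k, c(24^0.25, 24^0.5, 24^0.75), tolerance = 1e-12)
  expect_equal(k, c(2.213364, 4.898979, 10.843224), tolerance = 1e-6)
  expect_equal(log_lag_knots(24, 1), sqrt(24))
  for (L in c(12, 24, 36, 48)) {
    for (m in c(1, 3, 5)) {
      kk <- log_lag_knots(L, m)
      expect_true(all(diff(kk) > 0))
      expect_true(all(kk > 0 & kk < L))
    }
  }
  expect_error(log_lag_knots(24, 24), "smaller than max_lag")
})

test_that("basis_spec enforces the df bookkeeping invariant", {
  s <- basis_spec("natural_cubic", knots = c(2, 5), boundary = c(0, 10))
  expect_equal(s$df, 3L)                    # 2 internal + 1, no intercept
  si <- basis_spec("natural_cubic", knots = c(2, 5), boundary = c(0, 10),
                   intercept = TRUE)
  expect_equal(si$df, 4L)
  expect_error(basis_spec("natural_cubic", knots = c(2, 11), boundary = c(0, 10)),
               "bracket")
})

test_that("a collapsed cross-basis recovers the window sum", {
  set.seed(4)
  Q <- matrix(runif(8 * 25, 0, 30), 8, 25)
  cb <- cross_basis(raw_lag_matrix(Q), basis_spec("linear"),
                    basis_spec("constant"))
  expect_equal(ncol(cb$W), 1L)
  expect_equal(unname(cb$W[, 1]), rowSums(Q))
})

test_that("cross-basis dimension is the product of the marginal dfs", {
  Q <- matrix(runif(5 * 25, 0, 30), 5, 25)
  es <- basis_spec("natural_cubic", knots = c(10, 20), boundary = c(0, 30))
  ls4 <- basis_spec("natural_cubic", knots = log_lag_knots(24, 2),
                    boundary = c(0, 24), intercept = TRUE)
  expect_equal(es$df, 3L)
  expect_equal(ls4$df, 4L)
  cb <- cross_basis(raw_lag_matrix(Q), es, ls4)
  expect_equal(ncol(cb$W), 12L)
})

test_that("the vectorised cross-basis equals the naive triple loop", {
  set.seed(5)
  Q <- matrix(runif(5 * 25, -2, 32), 5, 25)
  es <- basis_spec("natural_cubic", knots = c(8, 22), boundary = c(-2, 32))
  lsp <- lag_basis_spec(24, 3)
  cb <- cross_basis(raw_lag_matrix(Q), es, lsp)
  vx <- es$df; vl <- lsp$df
  W2 <- matrix(0, 5, vx * vl)
  for (i in 1:5) for (j in 1:vx) for (k in 1:vl) {
    acc <- 0
    for (l in 0:24) {
      acc <- acc + natural_cubic_basis(Q[i, l + 1], es)[1, j] *
        natural_cubic_basis(l, lsp)[1, k]
    }
    W2[i, (j - 1) * vl + k] <- acc
  }
  expect_lt(max(abs(unname(cb$W) - W2)), 1e-12)
})

test_that("cross-basis is additive in Q for a linear exposure basis", {
  set.seed(6)
  Q1 <- matrix(runif(6 * 13), 6, 13)
  Q2 <- matrix(runif(6 * 13), 6, 13)
  lsp <- lag_basis_spec(12, 2)
  lin <- basis_spec("linear")
  w <- function(Q) cross_basis(raw_lag_matrix(Q), lin, lsp)$W
  expect_equal(w(Q1 + Q2), w(Q1) + w(Q2), tolerance = 1e-12)
})

test_that("design assembly stacks blocks with declared widths", {
  Q <- matrix(runif(10 * 25, 0, 30), 10, 25)
  es <- basis_spec("natural_cubic", knots = c(10, 20), boundary = c(0, 30))
  ls4 <- basis_spec("natural_cubic", knots = log_lag_knots(24, 2),
                    boundary = c(0, 24), intercept = TRUE)
  tcb <- cross_basis(raw_lag_matrix(Q), es, ls4)
  rcb <- cross_basis(raw_lag_matrix(Q + 40, exposure = "rh_pct"), es, ls4)
  d0 <- assemble_design(tcb, rcb)
  expect_equal(ncol(d0$X), 24L)
  d1 <- assemble_design(tcb, rcb, interaction = TRUE,
                        rh_mean24 = rowMeans(Q + 40))
  expect_equal(ncol(d1$X), 36L)
  expect_equal(length(d1$blocks$interaction), 12L)
  short <- cross_basis(raw_lag_matrix(Q[1:5, ], exposure = "rh_pct"), es, ls4)
  expect_error(assemble_design(tcb, short), "misaligned")
})

test_that("permuting stratum order leaves the fit invariant", {
  set.seed(7)
  d <- make_strata(60, 4, beta = c(0.5, -0.3))
  f1 <- fit_clogit(d$X, d$case, d$stratum)
  perm <- sample(length(d$case))
  f2 <- fit_clogit(d$X[perm, ], d$case[perm], d$stratum[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("shifting all exposures leaves fixed-pair odds ratios unchanged", {
  set.seed(8)
  d <- make_strata(150, 4, beta = numeric(0), n_covariates = 0,
                   x_fun = function(n) matrix(nrow = n, ncol = 0))
  Q <- matrix(15 + 6 * as.numeric(stats::filter(rnorm(600 * 13), 0.8,
                                                method = "recursive")), 600, 13)
  lsp <- lag_basis_spec(12, 2)
  fit_or <- function(shift) {
    Qs <- Q + shift
    spec <- resolve_spec(basis_spec("natural_cubic", df = 3), as.numeric(Qs))
    cb <- cross_basis(raw_lag_matrix(Qs), spec, lsp)
    case <- d$case
    fit <- fit_clogit(cb$W, case, d$stratum)
    lag_specific_or(fit, cb, x = 10 + shift, x_ref = 25 + shift, lags = 0:12)
  }
  set.seed(9); a <- fit_or(0)
  set.seed(9); b <- fit_or(100)
  expect_equal(a$log_or, b$log_or, tolerance = 1e-6)
  expect_equal(a$se, b$se, tolerance = 1e-6)
})
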