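test_that("null log-likelihood equals -sum log stratum sizes", {
  X <- matrix(rnorm(40), 40, 1)
  si <- rep(1:10, each = 4)
  case <- rep(c(TRUE, FALSE, FALSE, FALSE), 10)
  expect_equal(conditional_loglik(0, X, case, si), -10 * log(4))
})

test_that("stratum-constant covariates drop out of the likelihood", {
  set.seed(12)
  si <- rep(1:20, each = 3)
  X <- cbind(rnorm(60), rep(rnorm(20), each = 3))   # column 2 stratum-constant
  case <- uniform_cases(si)
  for (b2 in c(-3, 0, 7)) {
    expect_equal(conditional_loglik(c(0.5, b2), X, case, si),
                 conditional_loglik(c(0.5, 0), X, case, si), tolerance = 1e-12)
  }
})

test_that("likelihood matches hand enumeration on tiny instances", {
  X <- matrix(c(0.2, -1.1, 0.7, 1.5, -0.4, 0.9, 0.0, 2.2), ncol = 1)
  si <- c(1, 1, 1, 1, 2, 2, 2, 2)
  case <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  beta <- 0.8
  by_hand <- (0.2 * beta - log(sum(exp(c(0.2, -1.1, 0.7, 1.5) * beta)))) +
    (0.9 * beta - log(sum(exp(c(-0.4, 0.9, 0.0, 2.2) * beta))))
  expect_equal(conditional_loglik(beta, X, case, si), by_hand,
               tolerance = 1e-12)
})

test_that("likelihood equals the enumeration oracle on many small instances", {
  set.seed(13)
  for (rep in 1:20) {
    n_str <- sample(1:3, 1)
    size <- sample(2:4, 1)
    p <- sample(1:2, 1)
    d <- make_strata(n_str, size, beta = rep(0, p), n_covariates = p)
    beta <- rnorm(p)
    expect_equal(conditional_loglik(beta, d$X, d$case, d$stratum),
                 enum_loglik(beta, d$X, d$case, d$stratum),
                 tolerance = 1e-12)
  }
})

test_that("malformed strata are rejected", {
  X <- matrix(rnorm(8), ncol = 1)
  expect_error(conditional_loglik(0, X, rep(FALSE, 8), rep(1:2, each = 4)),
               "exactly one case")
  expect_error(conditional_loglik(0, X, rep(TRUE, 8), rep(1:2, each = 4)),
               "exactly one case")
  expect_error(fit_clogit(X, c(TRUE, TRUE, rep(FALSE, 6)), rep(1, 8)),
               "exactly one case")
  expect_error(fit_clogit(X[1:2, , drop = FALSE], c(TRUE, TRUE), 1:2),
               "at least one control")
})

test_that("Newton-Raphson recovers simulated coefficients", {
  set.seed(14)
  d <- make_strata(3000, 4, beta = c(0.8, -0.4))
  fit <- fit_clogit(d$X, d$case, d$stratum)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients[1] - 0.8), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] + 0.4), 3 * se[2])
  expect_gte(fit$loglik, fit$loglik_null)
  # covariance is symmetric positive definite at the optimum
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("the Newton optimum matches a brute-force grid search", {
  d <- tiny_instance()
  fit <- fit_clogit(d$X, d$case, d$stratum)
  expect_false(fit$separation)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) enum_loglik(b, d$X, d$case, d$stratum),
               numeric(1))
  expect_lt(abs(fit$coefficients[1] - grid[which.max(ll)]), 1e-4 + 1e-9)
})

test_that("monotone likelihoods are flagged as separation", {
  # the case always has the strictly largest covariate value
  si <- rep(1:10, each = 3)
  X <- matrix(rep(c(2, 0, -1), 10) + rnorm(30, 0, 0.01), ncol = 1)
  case <- rep(c(TRUE, FALSE, FALSE), 10)
  fit <- fit_clogit(X, case, si)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$coefficients)))
})

test_that("matched-set estimates agree with survival::clogit", {
  skip_if_not_installed("survival")
  set.seed(16)
  d <- make_strata(400, 4, beta = c(0.7, -0.2, 0.1))
  fit <- fit_clogit(d$X, d$case, d$stratum)
  df <- data.frame(y = d$case, d$X, s = d$stratum)
  sf <- survival::coxph(survival::Surv(rep(1, nrow(df)), y) ~
                          X1 + X2 + X3 + survival::strata(s),
                        data = df, method = "exact")
  expect_equal(unname(fit$coefficients), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(vcov(sf)), tolerance = 1e-6)
  expect_equal(fit$loglik, sf$loglik[2], tolerance = 1e-8)
})

test_that("stratum-wise row shifts leave the estimates unchanged", {
  set.seed(17)
  d <- make_strata(100, 4, beta = c(0.5, -0.5))
  f1 <- fit_clogit(d$X, d$case, d$stratum)
  shifts <- matrix(rnorm(100 * 2, sd = 3), 100, 2)
  X2 <- d$X + shifts[d$stratum, ]
  f2 <- fit_clogit(X2, d$case, d$stratum)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("likelihood-ratio tests follow the nested-model contract", {
  set.seed(18)
  d <- make_strata(200, 4, beta = c(0.4, 0))
  colnames(d$X) <- c("a", "b")
  full <- fit_clogit(d$X, d$case, d$stratum)
  reduced <- fit_clogit(d$X[, 1, drop = FALSE], d$case, d$stratum)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  expect_error(likelihood_ratio_test(reduced, full), "not nested")
})

test_that("the declared interaction block tests on 12 degrees of freedom", {
  set.seed(19)
  n_strata <- 150
  n <- n_strata * 4
  Q <- matrix(15 + 8 * rnorm(n * 25), n, 25)
  es <- basis_spec("natural_cubic", knots = c(10, 20), boundary = range(Q))
  ls4 <- basis_spec("natural_cubic", knots = log_lag_knots(24, 2),
                    boundary = c(0, 24), intercept = TRUE)
  cb <- cross_basis(raw_lag_matrix(Q), es, ls4)       # 3 x 4 = 12 columns
  des <- assemble_design(cb, interaction = TRUE, rh_mean24 = rnorm(n, 70, 8))
  si <- rep(seq_len(n_strata), each = 4)
  case <- uniform_cases(si)
  full <- fit_clogit(des$X, case, si)
  reduced <- fit_clogit(des$X[, des$blocks$temp, drop = FALSE], case, si)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 12L)
  expect_true(lrt$p.value >= 0 && lrt$p.value <= 1)
})

test_that("tidy and glance summarise a fit in broom style", {
  set.seed(20)
  d <- make_strata(200, 4, beta = 0.5, n_covariates = 1)
  colnames(d$X) <- "exposure"
  fit <- fit_clogit(d$X, d$case, d$stratum)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$term, "exposure")
  tde <- tidy(fit, exponentiate = TRUE)
  expect_equal(tde$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n.strata, 200L)
  expect_true(gl$converged)
})
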