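# shared internals: one case per stratum, log-likelihood / score / information

cc_prepare <- function(X, case, stratum) {
  X <- as.matrix(X)
  case <- as.logical(case)
  if (anyNA(X) || anyNA(case)) abort("design and case indicator must be complete")
  si <- as.integer(factor(stratum))
  S <- max(si)
  ncase <- rowsum(as.numeric(case), si, reorder = TRUE)
  if (any(ncase != 1)) {
    abort("every stratum must contain exactly one case")
  }
  size <- as.numeric(rowsum(rep(1, length(si)), si, reorder = TRUE))
  if (any(size < 2)) abort("every stratum needs at least one control")
  list(X = X, case = case, si = si, S = S)
}

cc_eval <- function(beta, d, what = c("ll", "grad", "hess")) {
  eta <- as.numeric(d$X %*% beta)
  mx <- vapply(split(eta, d$si), max, numeric(1))
  e <- exp(eta - mx[d$si])
  Z <- as.numeric(rowsum(e, d$si, reorder = TRUE))
  ll <- sum(eta[d$case]) - sum(log(Z) + mx)
  out <- list(ll = ll)
  if (any(c("grad", "hess") %in% what)) {
    w <- e / Z[d$si]
    wX <- d$X * w
    M <- rowsum(wX, d$si, reorder = TRUE)       # S x p stratum means
    out$grad <- colSums(d$X[d$case, , drop = FALSE]) - colSums(M)
    if ("hess" %in% what) {
      out$hess <- -(crossprod(d$X, wX) - crossprod(M))
    }
  }
  out
}

#' Conditional (matched-set) log-likelihood
#'
#' Exact 1:M matched-set likelihood
#' `l(beta) = sum_s [x_case . beta - log sum_{j in s} exp(x_j . beta)]`,
#' the likelihood of a time-stratified case-crossover analysis with one
#' case hour and M control hours per stratum.
#'
#' @param beta Coefficient vector (length = design columns).
#' @param X Design matrix, one row per event hour.
#' @param case Logical case indicator, one TRUE per stratum.
#' @param stratum Stratum identifier vector.
#' @return The log-likelihood (scalar, <= 0 at beta = 0 relative scale).
#' @export
conditional_loglik <- function(beta, X, case, stratum) {
  d <- cc_prepare(X, case, stratum)
  cc_eval(as.numeric(beta), d, "ll")$ll
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximises the exact matched-set likelihood starting at `beta = 0`
#' (always feasible; the likelihood is concave) with step-halving.
#' Convergence requires both the relative log-likelihood change and the
#' maximum absolute score to fall below `tol`.  Monotone likelihoods
#' (separation: `||beta||` beyond `beta_bound` while still improving)
#' are flagged and estimates withheld.
#'
#' @param X Design matrix (columns must not all be constant within
#'   every stratum).
#' @param case Logical case indicator, exactly one TRUE per stratum.
#' @param stratum Stratum identifier.
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param beta_bound Separation bound on `max |beta|` (default 15).
#' @return Object of class `cc_fit`: `coefficients`, `vcov` (inverse
#'   observed information), `loglik`, `loglik_null` (at beta = 0),
#'   `n_strata`, `n_events`, `iterations`, `converged`, `separation`.
#' @export
fit_clogit <- function(X, case, stratum, tol = 1e-8, max_iter = 50,
                       beta_bound = 15) {
  d <- cc_prepare(X, case, stratum)
  p <- ncol(d$X)
  cn <- colnames(d$X) %||% paste0("x", seq_len(p))
  beta <- rep(0, p)
  ev <- cc_eval(beta, d, c("ll", "grad", "hess"))
  ll0 <- ev$ll
  converged <- FALSE
  separation <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    H <- ev$hess
    step <- tryCatch(solve(-H, ev$grad), error = function(e) NULL)
    if (is.null(step)) {
      sv <- svd(-H)
      bad <- which.min(sv$d)
      abort(paste0("singular information matrix; offending direction loads on column '",
                   cn[which.max(abs(sv$v[, bad]))], "'"))
    }
    new_beta <- beta + step
    new_ev <- cc_eval(new_beta, d, c("ll", "grad", "hess"))
    halvings <- 0
    while ((!is.finite(new_ev$ll) || new_ev$ll < ev$ll) && halvings < 30) {
      halvings <- halvings + 1
      new_beta <- beta + step / 2^halvings
      new_ev <- cc_eval(new_beta, d, c("ll", "grad", "hess"))
    }
    rel_change <- abs(new_ev$ll - ev$ll) / (abs(ev$ll) + 1e-10)
    beta <- new_beta
    ev <- new_ev
    if (max(abs(beta)) > beta_bound) {
      separation <- TRUE
      break
    }
    if (rel_change < tol && max(abs(ev$grad)) < max(tol, 1e-6)) {
      converged <- TRUE
      break
    }
  }
  vcov <- matrix(NA_real_, p, p)
  coefs <- setNames(rep(NA_real_, p), cn)
  if (!separation) {
    vcov <- solve(-ev$hess)
    vcov <- (vcov + t(vcov)) / 2
    coefs <- setNames(beta, cn)
  }
  dimnames(vcov) <- list(cn, cn)
  structure(list(coefficients = coefs, vcov = vcov,
                 loglik = ev$ll, loglik_null = ll0,
                 n_strata = d$S, n_events = nrow(d$X),
                 iterations = iter, converged = converged && !separation,
                 separation = separation),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("<cc_fit> conditional logistic regression: ", x$n_strata, " strata, ",
      length(x$coefficients), " coefficients\n", sep = "")
  cat("  loglik ", format(x$loglik), " (null ", format(x$loglik_null), "), ",
      x$iterations, " iterations, ",
      if (x$separation) "SEPARATION detected" else
        if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (!x$separation) print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test of nested conditional-logistic fits
#'
#' @param full,reduced Converged [fit_clogit()] results; the reduced
#'   model's columns must be a subset of the full model's.
#' @return A tibble: `statistic`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "cc_fit"), inherits(reduced, "cc_fit"))
  if (!full$converged || !reduced$converged) {
    abort("both fits must have converged")
  }
  if (!all(names(reduced$coefficients) %in% names(full$coefficients))) {
    abort("models are not nested: reduced columns are not a subset of full's")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) abort("models are not nested")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  tibble::tibble(statistic = stat, df = df,
                 p.value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' @export
tidy.cc_fit <- function(x, conf.int = TRUE, conf.level = 0.95,
                        exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  z <- est / se
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
  if (conf.int) {
    q <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' @export
glance.cc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik.null = x$loglik_null,
                 n.strata = x$n_strata, n.events = x$n_events,
                 iterations = x$iterations, converged = x$converged,
                 separation = x$separation)
}
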