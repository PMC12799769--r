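# internal helpers shared across modules

as_hour <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- x
  } else if (inherits(x, "Date")) {
    out <- as.POSIXct(as.character(x), tz = CC_TZ)
  } else {
    out <- as.POSIXct(x, tz = CC_TZ)
  }
  if (anyNA(out)) abort("unparseable timestamp(s)")
  attr(out, "tzone") <- CC_TZ
  out
}

# TRUE when every timestamp sits exactly on the hour
on_hour_grid <- function(t) all(as.numeric(t) %% 3600 == 0)

floor_hour <- function(t) {
  t <- as_hour(t)
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
             origin = "1970-01-01", tz = CC_TZ)
}

hour_seq <- function(from, to) {
  seq(as_hour(from), as_hour(to), by = 3600)
}

# type-7 (linear interpolation) percentiles; stated convention for trimming
pctl <- function(x, probs) {
  quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || any(p < 0) || any(p > 1)) {
    abort(paste0(what, " must lie in [0, 1]"))
  }
  invisible(p)
}

logsumexp_by <- function(eta, group, n_groups) {
  mx <- rep(-Inf, n_groups)
  # group-wise max via ordered assignment (groups are small; vectorised)
  mx <- vapply(split(eta, group), max, numeric(1))
  mx_full <- mx[group]
  z <- rowsum(exp(eta - mx_full), group, reorder = TRUE)
  list(lse = as.numeric(log(z)) + mx, max = mx_full, z = as.numeric(z))
}
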