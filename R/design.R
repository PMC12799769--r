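#' Time-stratified referent hours for a case hour
#'
#' Returns every other occurrence, within the same calendar month and
#' year, of the case hour's weekday at the same hour-of-day — the
#' time-stratified referent rule that matches controls on year, month,
#' day of the week and hour of the day.  Pure calendar arithmetic; a
#' month always yields 3 or 4 referents.
#'
#' @param case_hour A single civil timestamp at hour precision.
#' @return POSIXct vector of control hours, sorted ascending.
#' @export
#' @examples
#' select_referents(as.POSIXct("2021-10-08 10:00", tz = "UTC"))
#' # Fridays of October 2021 other than the 8th: Oct 1, 15, 29 at 10:00
select_referents <- function(case_hour) {
  case_hour <- as_hour(case_hour)
  if (length(case_hour) != 1) abort("case_hour must be a single timestamp")
  if (!on_hour_grid(case_hour)) abort("case_hour must sit on the hour")
  as.POSIXct(referents_list(as.numeric(case_hour))[[1]],
             origin = "1970-01-01", tz = CC_TZ)
}

# vectorised core: numeric epoch-second hours in, list of numeric
# referent vectors out (same weekday/hour, same month, case excluded)
referents_list <- function(hours_n) {
  lt <- as.POSIXlt(as.POSIXct(hours_n, origin = "1970-01-01", tz = CC_TZ))
  dom <- lt$mday
  ndays <- days_in_month(lt$year + 1900L, lt$mon + 1L)
  lapply(seq_along(hours_n), function(i) {
    doms <- seq.int(((dom[i] - 1L) %% 7L) + 1L, ndays[i], by = 7L)
    doms <- doms[doms != dom[i]]
    hours_n[i] + (doms - dom[i]) * 86400
  })
}

days_in_month <- function(year, month) {
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- dim[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n[month == 2 & leap] <- 29L
  n
}

#' Expand onset records into case/control event rows
#'
#' One stratum per case: the case hour plus its time-stratified
#' referents from [select_referents()].
#'
#' @param records Tibble of onset records (`patient_id`, `onset_time`,
#'   plus any covariate columns, which are carried along).
#' @return Tibble with one row per event hour: `stratum_id`,
#'   `patient_id`, `event_time`, `is_case`, and the input covariates.
#' @export
expand_strata <- function(records) {
  if (nrow(records) == 0) {
    warn("no onset records; empty strata")
    return(tibble::tibble(stratum_id = integer(), patient_id = character(),
                          event_time = as_hour(character()), is_case = logical()))
  }
  onset <- floor_hour(records$onset_time)
  onset_n <- as.numeric(onset)
  uniq <- unique(onset_n)
  refs <- referents_list(uniq)
  u_idx <- match(onset_n, uniq)
  k <- lengths(refs)[u_idx]
  n <- nrow(records)
  row_record <- rep.int(seq_len(n), k + 1L)
  event_n <- unlist(lapply(seq_len(n), function(i) {
    c(onset_n[i], refs[[u_idx[i]]])
  }), use.names = FALSE)
  is_case <- sequence(k + 1L) == 1L
  covars <- dplyr::select(records, -dplyr::any_of(c("onset_time", "lat", "lon")))
  dplyr::bind_cols(
    tibble::tibble(
      stratum_id = row_record,
      event_time = as.POSIXct(event_n, origin = "1970-01-01", tz = CC_TZ),
      is_case = is_case
    ),
    covars[row_record, , drop = FALSE]
  )
}

#' Apply exposure-driven exclusions to expanded strata
#'
#' An event hour (case or control) is dropped when, for any of the
#' supplied trimmed exposures, its lag-0 value is masked or more than
#' `max_frac_masked` of its lag window is masked.  A stratum is dropped
#' when its case is dropped or no control survives (a case with zero
#' controls contributes no likelihood information).
#'
#' @param events Tibble from [expand_strata()]; rows must align
#'   one-to-one with the rows of each trimmed lag matrix.
#' @param ... One or more [trim_extremes()] results (or `lag_matrix`
#'   objects) built on `events$event_time`.
#' @param max_frac_masked Window missingness tolerance (default 0.25).
#' @return The surviving event rows, with attribute `"exclusions"`: a
#'   tibble (`stratum_id`, `patient_id`, `reason`) describing dropped
#'   strata, and attribute `"dropped_events"` counting dropped rows.
#' @export
build_strata <- function(events, ..., max_frac_masked = 0.25) {
  mats <- lapply(list(...), function(m) if (inherits(m, "trim_result")) m$lagmat else m)
  drop_event <- rep(FALSE, nrow(events))
  for (m in mats) {
    stopifnot(inherits(m, "lag_matrix"))
    if (nrow(m$Q) != nrow(events)) {
      abort("lag matrix rows do not align with event rows")
    }
    drop_event <- drop_event | is.na(m$Q[, 1]) |
      rowMeans(is.na(m$Q)) > max_frac_masked
  }
  keep <- !drop_event
  case_dropped <- events$stratum_id[drop_event & events$is_case]
  surv <- events[keep, , drop = FALSE]
  n_ctrl <- tapply(!surv$is_case, surv$stratum_id, sum)
  has_case <- tapply(surv$is_case, surv$stratum_id, any)
  no_ctrl <- as.integer(names(n_ctrl))[n_ctrl == 0 & has_case]
  bad <- unique(c(case_dropped, no_ctrl))
  excl <- tibble::tibble(
    stratum_id = bad,
    patient_id = events$patient_id[match(bad, events$stratum_id)],
    reason = ifelse(bad %in% case_dropped, "case hour masked",
                    "no surviving control")
  )
  out <- surv[!surv$stratum_id %in% bad, , drop = FALSE]
  attr(out, "exclusions") <- excl
  attr(out, "dropped_events") <- sum(drop_event)
  attr(out, "kept_rows") <- which(keep)[!surv$stratum_id %in% bad]
  out
}
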