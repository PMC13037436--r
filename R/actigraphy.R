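# Nonparametric rest-activity metrics from epoch-level actimetry:
# interdaily stability (IS), intradaily variability (IV), relative
# amplitude (RA), and the Circadian Function Index
#   CFI = (IS + (2 - IV)/2 + RA) / 3,  each component in [0, 1]
# after clamping IV to [0, 2]. The IS/IV formulas are the standard
# nonparametric circadian definitions on hourly bins (p = 24).

#' Aggregate an epoch-level activity series to hourly bins
#'
#' Hourly mean over wear epochs; an hour is valid when at least 50% of its
#' epochs are wear. Invalid hours are imputed by the mean of the same clock
#' hour over the other (valid) days. Leading/trailing partial hours are
#' dropped, then trailing hours so the series spans whole 24-h days.
#' Fewer than 72 such hours (3 days) is a refusal.
#'
#' @param timestamps regular increasing epoch-start datetimes.
#' @param activity nonnegative activity counts per epoch.
#' @param wear logical wear mask (default all TRUE).
#' @return list(value = hourly activity, clock_hour, day, valid, imputed,
#'   n_days).
#' @export
bin_hourly <- function(timestamps, activity, wear = NULL) {
  n <- length(timestamps)
  stopifnot(length(activity) == n)
  if (is.null(wear)) wear <- rep(TRUE, n)
  if (n < 2) stopf("activity series too short")
  step <- as.numeric(difftime(timestamps[2], timestamps[1], units = "secs"))
  steps <- as.numeric(difftime(timestamps[-1], timestamps[-n], units = "secs"))
  if (any(abs(steps - step) > 1e-6))
    stopf("activity series must be on a regular grid")
  if ((3600 %% step) != 0) stopf("epoch length must divide 60 min")
  eph <- as.integer(3600 / step)           # epochs per hour
  # trim to the first whole-hour boundary
  lt <- as.POSIXlt(timestamps, tz = GR_TZ)
  start <- which(lt$min == 0 & lt$sec == 0)[1]
  if (is.na(start)) stopf("no whole-hour boundary in series")
  idx <- start:n
  nh <- length(idx) %/% eph
  nh <- 24L * (nh %/% 24L)                 # whole days only
  if (nh < 72)
    stopf("only %d whole-day hours; at least three continuous days (72 h) are required",
          nh)
  idx <- idx[seq_len(nh * eph)]
  hour_of <- factor(rep(seq_len(nh), each = eph), levels = seq_len(nh))
  act <- activity[idx]; wr <- wear[idx]
  wear_frac <- tapply(wr, hour_of, mean)
  wear_sum <- tapply(act * wr, hour_of, sum)
  wear_n <- tapply(wr, hour_of, sum)
  value <- ifelse(wear_n > 0, wear_sum / wear_n, NA_real_)
  valid <- wear_frac >= 0.5 & wear_n > 0
  clock <- as.POSIXlt(timestamps[idx[seq(1, length(idx), by = eph)]],
                      tz = GR_TZ)$hour
  day <- rep(seq_len(nh / 24L), each = 24L)
  imputed <- !valid
  if (any(!valid)) {
    for (i in which(!valid)) {
      same <- which(clock == clock[i] & valid)
      value[i] <- if (length(same)) mean(value[same]) else
        mean(value[valid], na.rm = TRUE)
    }
    if (anyNA(value))
      stopf("cannot impute hourly bins: a clock hour has no valid data")
  }
  list(value = unname(as.numeric(value)), clock_hour = clock, day = day,
       valid = unname(as.logical(valid)), imputed = unname(imputed),
       n_days = nh / 24L)
}

#' Interdaily stability
#'
#' IS = (n * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2) with
#' p = 24 clock-hour bins, n = 24 d total hours and xbar_h the clock-hour
#' means across days. 1 for a perfectly repeating daily profile; ~1/d for
#' iid noise. NA (flagged) for a constant series.
#'
#' @param hourly list from [bin_hourly()], or a numeric vector spanning
#'   whole days (clock hours assumed aligned).
#' @return IS in [0, 1], or NA for zero-variance input.
#' @export
interdaily_stability <- function(hourly) {
  h <- as_hourly(hourly)
  x <- h$value; n <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom <= 0) return(NA_real_)
  hb <- tapply(x, h$clock_hour, mean)
  p <- length(hb)
  unname(n * sum((hb - xbar)^2) / (p * denom))
}

#' Intradaily variability
#'
#' IV_raw = (n * sum first-difference^2) / ((n - 1) * sum (x - xbar)^2);
#' the clamped IV = min(max(IV_raw, 0), 2) enters the CFI so that
#' (2 - IV)/2 stays in [0, 1].
#'
#' @inheritParams interdaily_stability
#' @return list(iv_raw, iv).
#' @export
intradaily_variability <- function(hourly) {
  h <- as_hourly(hourly)
  x <- h$value; n <- length(x)
  denom <- sum((x - mean(x))^2)
  if (denom <= 0) return(list(iv_raw = NA_real_, iv = NA_real_))
  iv_raw <- n * sum(diff(x)^2) / ((n - 1) * denom)
  list(iv_raw = unname(iv_raw), iv = min(max(iv_raw, 0), 2))
}

#' Relative amplitude of the average 24-h profile
#'
#' M10 / L5 are the most / least active 10 / 5 consecutive clock hours of
#' the per-clock-hour mean profile, scanned circularly;
#' RA = (M10 - L5) / (M10 + L5), 0 when M10 + L5 = 0.
#'
#' @inheritParams interdaily_stability
#' @return list(ra, m10, l5).
#' @export
relative_amplitude <- function(hourly) {
  h <- as_hourly(hourly)
  prof <- tapply(h$value, h$clock_hour, mean)
  prof <- as.numeric(prof[order(as.numeric(names(prof)))])
  p <- length(prof)
  win_mean <- function(width) {
    vapply(seq_len(p), function(s)
      mean(prof[((s - 1 + 0:(width - 1)) %% p) + 1]), 0)
  }
  m10 <- max(win_mean(10))
  l5 <- min(win_mean(5))
  ra <- if ((m10 + l5) == 0) 0 else (m10 - l5) / (m10 + l5)
  list(ra = unname(ra), m10 = unname(m10), l5 = unname(l5))
}

#' Compose IS, IV and RA into the Circadian Function Index
#'
#' CFI = (IS + (2 - IV)/2 + RA) / 3 with IV clamped to [0, 2], so
#' CFI(1, 0, 1) = 1 and CFI(0, 2, 0) = 0.
#' @param is,iv,ra component values.
#' @export
cfi_from_components <- function(is, iv, ra) {
  iv <- pmin(pmax(iv, 0), 2)
  (is + (2 - iv) / 2 + ra) / 3
}

as_hourly <- function(hourly) {
  if (is.list(hourly) && !is.null(hourly$value)) return(hourly)
  x <- as.numeric(hourly)
  if (length(x) %% 24 != 0) stopf("hourly series must span whole days")
  list(value = x, clock_hour = rep(0:23, length(x) / 24),
       day = rep(seq_len(length(x) / 24), each = 24),
       n_days = length(x) / 24)
}

#' Circadian Function Index from an epoch-level series
#'
#' Composes [bin_hourly()], [interdaily_stability()],
#' [intradaily_variability()] and [relative_amplitude()] into
#' CFI = (IS + (2 - IV)/2 + RA) / 3. Requires >= 3 continuous whole days;
#' any missing component leaves CFI missing with a reason.
#'
#' @inheritParams bin_hourly
#' @return one-row data.frame(n_days, is, iv_raw, iv, m10, l5, ra, cfi,
#'   reason).
#' @export
circadian_function_index <- function(timestamps, activity, wear = NULL) {
  h <- bin_hourly(timestamps, activity, wear)
  is_v <- interdaily_stability(h)
  ivl <- intradaily_variability(h)
  ral <- relative_amplitude(h)
  reason <- NA_character_
  cfi <- NA_real_
  if (is.na(is_v) || is.na(ivl$iv)) {
    reason <- "zero-variance activity: IS/IV undefined"
  } else {
    cfi <- cfi_from_components(is_v, ivl$iv, ral$ra)
  }
  data.frame(n_days = h$n_days, is = is_v, iv_raw = ivl$iv_raw, iv = ivl$iv,
             m10 = ral$m10, l5 = ral$l5, ra = ral$ra, cfi = cfi,
             reason = reason, stringsAsFactors = FALSE)
}

#' CFI for every infant-age in a long actimetry table
#'
#' @param actimetry long data.frame from [read_actimetry()].
#' @return list(metrics = data.frame(infant_id, age_group, n_days, is,
#'   iv_raw, iv, m10, l5, ra, cfi), exclusions).
#' @export
actigraphy_per_infant_age <- function(actimetry) {
  keys <- unique(actimetry[, c("infant_id", "age_group")])
  rows <- list(); excl <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- actimetry[actimetry$infant_id == keys$infant_id[k] &
                       actimetry$age_group == keys$age_group[k], ]
    sub <- sub[order(sub$timestamp), ]
    res <- tryCatch(
      circadian_function_index(sub$timestamp, sub$activity, sub$wear),
      error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        infant_id = keys$infant_id[k], age_group = keys$age_group[k],
        reason = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(infant_id = keys$infant_id[k],
                 age_group = keys$age_group[k]), res)
  }
  empty_m <- data.frame(infant_id = character(), age_group = integer(),
                        n_days = integer(), is = double(), iv_raw = double(),
                        iv = double(), m10 = double(), l5 = double(),
                        ra = double(), cfi = double(), reason = character())
  empty_e <- data.frame(infant_id = character(), age_group = integer(),
                        reason = character())
  list(metrics = if (length(rows)) do.call(rbind, rows) else empty_m,
       exclusions = if (length(excl)) do.call(rbind, excl) else empty_e)
}
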