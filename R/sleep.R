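# Infant sleep-quality composite (BabySQUID) and diary-derived covariates:
# sleep history, feeding history, feeding rhythmicity, time since last
# bowel movement.

BISQ_VARS <- c("bisq_night_sleep_h", "bisq_latency_h",
               "bisq_bedtime_clock_h", "bisq_n_awakenings")
BISQ_REVERSED <- c("bisq_latency_h", "bisq_bedtime_clock_h",
                   "bisq_n_awakenings")

#' BabySQUID composite sleep-quality score
#'
#' Per infant-age: records with at most 2 missing BISQ variables are kept
#' (missing values replaced by the cohort median of that variable over
#' non-missing included values); records with 3+ missing are excluded.
#' Each variable is min-max scaled over all included records (pooled
#' across ages), latency, bedtime and awakenings are reverse-coded as
#' 1 - scaled, and the composite is the equal-weight mean of the four. A
#' constant variable scales to the uninformative midpoint 0.5.
#'
#' @param records questionnaire data frame ([read_questionnaires()]).
#' @return list(scores = data.frame(infant_id, age_group, duration,
#'   latency_rev, bedtime_rev, awakenings_rev, babysquid, n_imputed),
#'   exclusions).
#' @export
compute_babysquid <- function(records) {
  if (nrow(records) < 2) stopf("BabySQUID needs a cohort of >= 2 records")
  raw <- as.matrix(records[, BISQ_VARS])
  n_missing <- rowSums(is.na(raw))
  keep <- n_missing <= 2
  exclusions <- data.frame(
    infant_id = records$infant_id[!keep],
    age_group = records$age_group[!keep],
    reason = sprintf("%d missing BISQ variables (> 2)", n_missing[!keep]))
  inc <- raw[keep, , drop = FALSE]
  if (nrow(inc) < 2) stopf("fewer than 2 BabySQUID-eligible records")
  for (j in seq_len(ncol(inc))) {
    med <- stats::median(inc[, j], na.rm = TRUE)
    if (is.na(med)) stopf("BISQ variable %s entirely missing", BISQ_VARS[j])
    inc[is.na(inc[, j]), j] <- med
  }
  scaled <- inc
  for (j in seq_len(ncol(inc))) {
    rng <- range(inc[, j])
    scaled[, j] <- if (diff(rng) == 0) 0.5 else
      (inc[, j] - rng[1]) / diff(rng)
  }
  for (v in BISQ_REVERSED) scaled[, v] <- 1 - scaled[, v]
  scores <- data.frame(
    infant_id = records$infant_id[keep],
    age_group = records$age_group[keep],
    duration = scaled[, "bisq_night_sleep_h"],
    latency_rev = scaled[, "bisq_latency_h"],
    bedtime_rev = scaled[, "bisq_bedtime_clock_h"],
    awakenings_rev = scaled[, "bisq_n_awakenings"],
    babysquid = rowMeans(scaled),
    n_imputed = n_missing[keep],
    stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, exclusions = exclusions)
}

# Merge consecutive same-state 15-min diary intervals into bouts.
diary_bouts <- function(diary_sub, interval_min = 15) {
  d <- diary_sub[order(diary_sub$interval_start), ]
  if (nrow(d) == 0) return(d[, 0])
  run <- cumsum(c(TRUE, d$state[-1] != d$state[-nrow(d)] |
                    as.numeric(diff(d$interval_start), units = "mins") >
                      interval_min + 1e-9))
  run <- factor(run, levels = unique(run))
  starts <- tapply(as.numeric(d$interval_start), run, min)
  ends <- tapply(as.numeric(d$interval_start), run, max) + interval_min * 60
  data.frame(state = d$state[!duplicated(run)],
             start = as.POSIXct(as.numeric(starts), origin = "1970-01-01",
                                tz = GR_TZ),
             end = as.POSIXct(as.numeric(ends), origin = "1970-01-01",
                              tz = GR_TZ))
}

#' Sleep/feeding history and bowel-movement interval per stool sample
#'
#' For a sample collected at time t: in a wake bout, prior_awake_h is the
#' time since the end of the most recent sleep bout and
#' last_sleep_duration_h that bout's length; inside a sleep bout,
#' prior_awake_h = 0 and last_sleep_duration_h is the elapsed time of the
#' ongoing bout. time_since_feeding_h uses the most recent feeding at or
#' before t. time_since_last_bowel_movement_h is the gap to the infant's
#' previous sample within the same age assessment (first sample missing).
#' Diary intervals are half-open; a sample on a boundary belongs to the
#' later interval. Fields the diary cannot cover are missing.
#'
#' @param metadata sample metadata.
#' @param diary diary table ([read_diary()]).
#' @param feedings feeding events ([read_feedings()]).
#' @return data.frame(sample_id, prior_awake_h, last_sleep_duration_h,
#'   time_since_feeding_h, time_since_last_bowel_movement_h).
#' @export
derive_sample_history <- function(metadata, diary, feedings) {
  out <- data.frame(sample_id = metadata$sample_id,
                    prior_awake_h = NA_real_,
                    last_sleep_duration_h = NA_real_,
                    time_since_feeding_h = NA_real_,
                    time_since_last_bowel_movement_h = NA_real_,
                    stringsAsFactors = FALSE)
  hours <- function(a, b) as.numeric(difftime(a, b, units = "hours"))
  for (i in seq_len(nrow(metadata))) {
    t <- metadata$collection_datetime[i]
    inf <- metadata$infant_id[i]; ag <- metadata$age_group[i]
    dsub <- diary[diary$infant_id == inf & diary$age_group == ag, ]
    if (nrow(dsub)) {
      bouts <- diary_bouts(dsub)
      cur <- which(bouts$start <= t & t < bouts$end)
      if (length(cur) == 1) {
        if (bouts$state[cur] == "sleep") {
          out$prior_awake_h[i] <- 0
          out$last_sleep_duration_h[i] <- hours(t, bouts$start[cur])
        } else {
          prev_sleep <- which(bouts$state == "sleep" & bouts$end <= t)
          if (length(prev_sleep)) {
            ps <- prev_sleep[length(prev_sleep)]
            out$prior_awake_h[i] <- hours(t, bouts$end[ps])
            out$last_sleep_duration_h[i] <- hours(bouts$end[ps], bouts$start[ps])
          }
        }
      }
    }
    fsub <- feedings[feedings$infant_id == inf & feedings$age_group == ag, ]
    prev_feed <- fsub$feed_time[fsub$feed_time <= t]
    if (length(prev_feed))
      out$time_since_feeding_h[i] <- hours(t, max(prev_feed))
    prev_samp <- metadata$collection_datetime[
      metadata$infant_id == inf & metadata$age_group == ag &
        metadata$collection_datetime < t]
    if (length(prev_samp))
      out$time_since_last_bowel_movement_h[i] <- hours(t, max(prev_samp))
  }
  out
}

#' Feeding rhythmicity per infant-age
#'
#' Per midnight-to-midnight calendar day: the sample standard deviation
#' (n - 1 denominator) of consecutive inter-feeding intervals in hours;
#' days with fewer than 2 intervals (3 feedings) are skipped and counted.
#' The infant-age value aggregates day-level SDs by `aggregate` (mean by
#' default, median available).
#'
#' @param feedings feeding events table.
#' @param aggregate "mean" or "median".
#' @return data.frame(infant_id, age_group, feeding_rhythmicity, n_days,
#'   n_days_skipped); infant-ages with no eligible day are absent.
#' @export
feeding_rhythmicity <- function(feedings, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  keys <- unique(feedings[, c("infant_id", "age_group")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- feedings[feedings$infant_id == keys$infant_id[k] &
                      feedings$age_group == keys$age_group[k], ]
    times <- sort(sub$feed_time)
    day <- format(times, "%Y-%m-%d", tz = GR_TZ)
    sds <- c(); skipped <- 0L
    for (d in unique(day)) {
      ft <- times[day == d]
      if (length(ft) < 3) { skipped <- skipped + 1L; next }
      iv <- as.numeric(diff(ft), units = "hours")
      sds <- c(sds, stats::sd(iv))
    }
    if (!length(sds)) next
    rows[[length(rows) + 1L]] <- data.frame(
      infant_id = keys$infant_id[k], age_group = keys$age_group[k],
      feeding_rhythmicity = if (aggregate == "mean") mean(sds) else
        stats::median(sds),
      n_days = length(sds), n_days_skipped = skipped,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(infant_id = character(), age_group = integer(),
                      feeding_rhythmicity = double(), n_days = integer(),
                      n_days_skipped = integer()))
  do.call(rbind, rows)
}
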