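# Fixed-period (24 h) cosinor fits of per-infant-age series.
#
# The model y(t) = C + A cos(2 pi t / 24 + phi) is linear in
# (C, a, b) with a = A cos(phi), b = -A sin(phi), so ordinary least
# squares on cbind(1, cos(wt), sin(wt)) gives the exact solution.

#' Fit a 24-hour cosinor by ordinary least squares
#'
#' @param times_h observation times in hours on a common origin.
#' @param values series values (alpha diversity or genus relative
#'   abundance).
#' @param period_h fixed period (24 h).
#' @param min_samples minimum observations (default 4).
#' @return list with amplitude, acrophase (radians in (-pi, pi]),
#'   peak_hour (clock hour of fitted maximum), mesor, r_squared
#'   (NA iff the series has zero variance), n_samples, degenerate flag.
#' @export
fit_cosinor <- function(times_h, values, period_h = 24, min_samples = 4) {
  stopifnot(length(times_h) == length(values))
  ok <- is.finite(times_h) & is.finite(values)
  t <- times_h[ok]; y <- values[ok]
  n <- length(y)
  if (n < min_samples)
    stopf("insufficient samples: %d < minimum requirement of %d samples",
          n, min_samples)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  sv <- svd(X)$d
  rank <- sum(sv > max(sv) * 1e-10)
  if (rank < 3)
    stopf("rank-deficient cosinor design (rank %d < 3); times must span >= 3 independent phases",
          rank)
  beta <- qr.coef(qr(X), y)
  fitted <- drop(X %*% beta)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  a <- beta[2]; b <- beta[3]
  amplitude <- sqrt(a^2 + b^2)
  acrophase <- atan2(-b, a)
  if (acrophase <= -pi) acrophase <- acrophase + 2 * pi
  r2 <- if (ss_tot <= 0) NA_real_ else max(0, min(1, 1 - ss_res / ss_tot))
  peak <- (-acrophase / w) %% period_h
  if (peak >= period_h - 1e-9) peak <- 0
  list(amplitude = amplitude,
       acrophase = acrophase,
       peak_hour = peak,
       mesor = unname(beta[1]),
       r_squared = r2,
       n_samples = n,
       degenerate = ss_tot <= 0)
}

#' Cosinor rhythmicity for every infant-age group
#'
#' Fits one cosinor per alpha metric (4) and one per top genus for every
#' infant-age with at least `min_samples` samples. The time coordinate is
#' hours elapsed since midnight of the group's first sampling day (with the
#' period fixed at 24 h, R-squared is origin-invariant; the origin only
#' standardizes the reported acrophase).
#'
#' @param alpha long data.frame(sample_id, metric, value) from
#'   [bootstrapped_alpha()].
#' @param genus_rel samples x genera relative-abundance matrix.
#' @param top_genera genera to fit (default: all columns of `genus_rel`).
#' @param metadata sample metadata (sample_id, infant_id, age_group,
#'   collection_datetime).
#' @param min_samples minimum samples per fit (default 4).
#' @return list(fits = data.frame(infant_id, age_group, target, n_samples,
#'   amplitude, acrophase_rad, peak_hour, mesor, r_squared),
#'   exclusions = data.frame(infant_id, age_group, target, reason)).
#' @export
rhythmicity_per_infant_age <- function(alpha, genus_rel, metadata,
                                       top_genera = colnames(genus_rel),
                                       min_samples = 4) {
  meta <- metadata[metadata$sample_id %in% unique(alpha$sample_id) |
                     metadata$sample_id %in% rownames(genus_rel), ]
  keys <- unique(meta[, c("infant_id", "age_group")])
  fits <- list(); excl <- list()
  targets <- c(ALPHA_METRICS, top_genera)
  for (k in seq_len(nrow(keys))) {
    sub <- meta[meta$infant_id == keys$infant_id[k] &
                  meta$age_group == keys$age_group[k], ]
    if (nrow(sub) < min_samples) {
      excl[[length(excl) + 1L]] <- data.frame(
        infant_id = keys$infant_id[k], age_group = keys$age_group[k],
        target = "all",
        reason = sprintf("minimum requirement of %d samples not met (%d)",
                         min_samples, nrow(sub)))
      next
    }
    origin <- midnight_of(sub$collection_datetime)
    times <- as.numeric(difftime(sub$collection_datetime, origin,
                                 units = "hours"))
    for (target in targets) {
      vals <- if (target %in% ALPHA_METRICS) {
        a <- alpha[alpha$metric == target, ]
        a$value[match(sub$sample_id, a$sample_id)]
      } else {
        genus_rel[match(sub$sample_id, rownames(genus_rel)), target]
      }
      res <- tryCatch(fit_cosinor(times, vals, min_samples = min_samples),
                      error = function(e) e)
      if (inherits(res, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          infant_id = keys$infant_id[k], age_group = keys$age_group[k],
          target = target, reason = conditionMessage(res))
        next
      }
      fits[[length(fits) + 1L]] <- data.frame(
        infant_id = keys$infant_id[k], age_group = keys$age_group[k],
        target = target, n_samples = res$n_samples,
        amplitude = res$amplitude, acrophase_rad = res$acrophase,
        peak_hour = res$peak_hour, mesor = res$mesor,
        r_squared = res$r_squared, stringsAsFactors = FALSE)
    }
  }
  empty_fit <- data.frame(infant_id = character(), age_group = integer(),
                          target = character(), n_samples = integer(),
                          amplitude = double(), acrophase_rad = double(),
                          peak_hour = double(), mesor = double(),
                          r_squared = double())
  empty_excl <- data.frame(infant_id = character(), age_group = integer(),
                           target = character(), reason = character())
  list(fits = if (length(fits)) do.call(rbind, fits) else empty_fit,
       exclusions = if (length(excl)) do.call(rbind, excl) else empty_excl)
}
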