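# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: 20 infants
# assessed at 2/4/6 months (age-days centered on 76/128/190), clusters of
# 1-11 stool samples (median 4) across a 48-h window with clock times that
# concentrate toward the morning with age, diurnal cosine modulation of
# selected genera on the log-abundance scale before multinomial count
# sampling, age-increasing richness and stool melatonin, rest-activity
# series with tunable relative amplitude and fragmentation, 15-min diaries
# with feeding times, and questionnaire variables with age trends.
# Everything is deterministic under the master seed; sub-stage seeds are
# derived by hashing.

#' Default synthetic-cohort configuration
#'
#' Values mirror the cohort the pipeline targets where those are stated
#' (sample-count distribution, age-days centers, actimetry durations,
#' melatonin age slope 0.638 pg/g/day, richness age slope ~0.1
#' features/day); remaining scales (oscillation amplitudes, noise) are
#' fixed realistic choices documented in the methods vignette.
#'
#' @return nested list of generator parameters.
#' @export
default_cohort_config <- function() {
  list(
    n_infants = 20,
    age_groups = AGE_GROUPS,
    age_days_mean = c(`2` = 76, `4` = 128, `6` = 190),
    age_days_sd = 5,
    # realized assessment pattern: P(1, 2, 3 ages per infant)
    ages_per_infant_probs = c(0.2, 0.55, 0.25),
    sex_ratio_female = 0.5,
    samples_per_infant_age = list(meanlog = log(4), sdlog = 0.55,
                                  min = 1, max = 11),
    window_h = 48,
    # morning-weighted clock-time mixture weight by age group
    morning_weight = c(`2` = 0, `4` = 0.3, `6` = 0.6),
    morning_peak_h = 12, morning_sd_h = 2.5,
    genera = data.frame(
      genus = c("Bifidobacterium", "Veillonella", "Escherichia-Shigella",
                "Bacteroides", "Clostridium sensu stricto 1",
                "Streptococcus", "Enterococcus", "Lactobacillus",
                "Klebsiella", "Blautia"),
      family = c("Bifidobacteriaceae", "Veillonellaceae",
                 "Enterobacteriaceae", "Bacteroidaceae", "Clostridiaceae",
                 "Streptococcaceae", "Enterococcaceae", "Lactobacillaceae",
                 "Enterobacteriaceae", "Lachnospiraceae"),
      phylum = c("Actinobacteriota", "Firmicutes", "Proteobacteria",
                 "Bacteroidota", "Firmicutes", "Firmicutes", "Firmicutes",
                 "Firmicutes", "Proteobacteria", "Firmicutes"),
      baseline = c(3.0, 2.5, 2.6, 2.4, 2.2, 1.0, 0.8, 0.5, 0.6, 0.3),
      amplitude = c(0.5, 0.4, 0.6, 0.5, 0.3, 0, 0, 0, 0, 0),
      acrophase_h = c(8, 14, 20, 2, 11, 0, 0, 0, 0, 0),
      n_asvs = c(15, 12, 10, 12, 10, 10, 8, 8, 8, 7),
      stringsAsFactors = FALSE),
    n_rare_features = 10,        # planted below the frequency-10 filter
    rare_log_baseline = -14,
    asv_weight_dispersion = 4, # spread of within-genus ASV weights (log)
    phylum_unassigned_frac = 0.05,
    n_emerging_features = 40,    # late-onset ASVs driving the age trend
    richness_slope = 0.1,        # detectable features per day of age
    infant_sd = 0.5,             # infant random effect on log abundance
    noise_sd = 0.4,              # per sample x genus log-abundance noise
    volatility_age_slope = -0.002, # scales noise_sd with (age_days - 76)
    diversity_propensity_features = 3, # extra onsets per SD of propensity
    library_size = list(meanlog = log(8000), sdlog = 0.25, min = 4000),
    melatonin = list(intercept = 5, slope = 0.638,
                     noise_meanlog = log(10), noise_sdlog = 0.5,
                     missing_frac = 0.1),
    activity = list(mesor = 50, epoch_min = 1,
                    days_mean = 8, days_sd = 2.71, days_min = 3,
                    days_max = 11,
                    ra_base = 0.6, ra_age_slope = 0.0015, # per day of age
                    ra_propensity = 0.05,  # diversity -> rhythm coupling
                    frag_per_h = 0.4, frag_age_slope = -0.0004,
                    frag_exit_per_h = 2, # ~30-min fragmentation episodes
                    peak_hour = 14, duty = 16 / 24, noise_sd = 3,
                    nonwear_blocks_mean = 1, nonwear_min = 30,
                    nonwear_max = 90),
    diary = list(interval_min = 15, wake_frac = 10 / 24,
                 report_jitter = 0.1),
    feeding = list(mean_interval_h = 3, jitter_h = 0.5),
    bisq = list(night_base = 9.5, night_age_slope = 0.005, night_sd = 0.6,
                latency_base = 0.5, latency_age_slope = -0.001,
                latency_sd = 0.15,
                bedtime_base = 20.5, bedtime_age_slope = -0.003,
                bedtime_sd = 0.6,
                awakenings_lambda = 2, missing_frac = 0.05),
    bcq = list(mean = 3.5, sd = 0.25),
    asq = list(mean = 275, sd = 15)
  )
}

# Cohort skeleton: infants (sex, diversity propensity), observed ages,
# assessment start dates, per infant-age sample counts.
design_cohort <- function(config, seed) {
  with_seed(derive_seed(seed, "design"), {
    n <- config$n_infants
    infants <- data.frame(
      infant_id = sprintf("I%02d", seq_len(n)),
      sex = ifelse(stats::runif(n) < config$sex_ratio_female,
                   "female", "male"),
      propensity = stats::rnorm(n),
      stringsAsFactors = FALSE)
    n_ages <- sample(seq_along(config$ages_per_infant_probs), n,
                     replace = TRUE, prob = config$ages_per_infant_probs)
    keys <- list()
    for (i in seq_len(n)) {
      ages <- sort(sample(config$age_groups, n_ages[i]))
      for (a in ages) {
        nd <- round(stats::rlnorm(1, config$samples_per_infant_age$meanlog,
                                  config$samples_per_infant_age$sdlog))
        nd <- min(max(nd, config$samples_per_infant_age$min),
                  config$samples_per_infant_age$max)
        age_days <- max(1, round(stats::rnorm(
          1, config$age_days_mean[[as.character(a)]], config$age_days_sd)))
        keys[[length(keys) + 1L]] <- data.frame(
          infant_id = infants$infant_id[i], age_group = a,
          age_days = age_days, n_samples = nd,
          start = as.POSIXct("2023-06-01 00:00:00", tz = GR_TZ) +
            86400 * (7 * i + 60 * match(a, config$age_groups)),
          stringsAsFactors = FALSE)
      }
    }
    list(infants = infants, keys = do.call(rbind, keys))
  })
}

# ASV registry: feature ids, taxonomy, per-ASV within-genus weight,
# age-onset day, planted rare/unassigned flags.
build_asv_registry <- function(config, seed) {
  with_seed(derive_seed(seed, "asvs"), {
    g <- config$genera
    reg <- list()
    for (j in seq_len(nrow(g))) {
      ids <- sprintf("ASV_%s_%02d", gsub("[^A-Za-z]", "", g$genus[j]),
                     seq_len(g$n_asvs[j]))
      reg[[j]] <- data.frame(
        feature_id = ids, genus = g$genus[j], family = g$family[j],
        phylum = g$phylum[j],
        log_weight = config$asv_weight_dispersion *
          log(stats::rexp(g$n_asvs[j])),
        onset_day = 0, rare = FALSE, stringsAsFactors = FALSE)
    }
    reg <- do.call(rbind, reg)
    # late-onset ASVs: onsets spaced so ~richness_slope features/day emerge
    ne <- config$n_emerging_features
    pick <- sample(nrow(reg), ne, replace = TRUE)
    onset_span <- ne / config$richness_slope
    emerging <- reg[pick, ]
    emerging$feature_id <- sprintf("ASV_late_%02d", seq_len(ne))
    emerging$onset_day <- stats::runif(ne, 40, 40 + onset_span)
    emerging$log_weight <- config$asv_weight_dispersion *
      log(stats::rexp(ne)) - 1
    reg <- rbind(reg, emerging)
    # planted low-frequency features (exercise the frequency-10 filter)
    nr <- config$n_rare_features
    if (nr > 0) {
      rare <- reg[sample(which(!reg$onset_day > 0), nr, replace = TRUE), ]
      rare$feature_id <- sprintf("ASV_rare_%02d", seq_len(nr))
      rare$log_weight <- config$rare_log_baseline
      rare$rare <- TRUE
      reg <- rbind(reg, rare)
    }
    # phylum-unassigned fraction
    un <- stats::runif(nrow(reg)) < config$phylum_unassigned_frac
    reg$phylum[un] <- ""
    reg$genus[un] <- ""
    reg$family[un] <- ""
    rownames(reg) <- NULL
    reg
  })
}

#' Simulate the feature table, taxonomy, tree and sample metadata
#'
#' Per sample at clock time t, genus log-abundance = baseline +
#' A_g cos(2 pi (t - phi_g)/24) + infant random effect + noise, split over
#' the genus ASVs by fixed weights, with late-onset ASVs switched off
#' below their age threshold; counts are drawn multinomially at the
#' sample's library size (log-normal, floored above the rarefaction
#' depth). The tree is a random coalescent over all ASVs.
#'
#' @param config [default_cohort_config()]-shaped list.
#' @param seed master seed.
#' @param design optional precomputed cohort skeleton (internal).
#' @return list(table, taxonomy, tree, metadata, ground_truth).
#' @export
simulate_feature_table <- function(config = default_cohort_config(),
                                   seed = 1L, design = NULL) {
  if (config$library_size$meanlog <= 0 || config$library_size$min <= 0)
    stopf("config error: library size must be positive")
  if (is.null(design)) design <- design_cohort(config, seed)
  reg <- build_asv_registry(config, seed)
  keys <- design$keys; infants <- design$infants
  g <- config$genera

  # sample clock times and metadata
  meta <- with_seed(derive_seed(seed, "times"), {
    rows <- list()
    for (k in seq_len(nrow(keys))) {
      nd <- keys$n_samples[k]
      mw <- config$morning_weight[[as.character(keys$age_group[k])]]
      offs <- numeric(nd)
      for (s in seq_len(nd)) {
        if (stats::runif(1) < mw) {
          ct <- stats::rnorm(1, config$morning_peak_h,
                             config$morning_sd_h) %% 24
          offs[s] <- 24 * sample(0:(config$window_h / 24 - 1), 1) + ct
        } else offs[s] <- stats::runif(1, 0, config$window_h)
      }
      rows[[k]] <- data.frame(
        sample_id = sprintf("%s_A%d_S%02d", keys$infant_id[k],
                            keys$age_group[k], seq_len(nd)),
        infant_id = keys$infant_id[k], age_group = keys$age_group[k],
        age_days = keys$age_days[k],
        collection_datetime = keys$start[k] + round(offs * 3600),
        sex = infants$sex[match(keys$infant_id[k], infants$infant_id)],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  counts <- with_seed(derive_seed(seed, "counts"), {
    nfeat <- nrow(reg)
    cm <- matrix(0, nrow(meta), nfeat,
                 dimnames = list(meta$sample_id, reg$feature_id))
    # infant x genus random effects
    u <- matrix(stats::rnorm(nrow(infants) * nrow(g), 0, config$infant_sd),
                nrow(infants), nrow(g),
                dimnames = list(infants$infant_id, g$genus))
    for (s in seq_len(nrow(meta))) {
      t_clock <- clock_hour(meta$collection_datetime[s])
      age <- meta$age_days[s]
      prop <- infants$propensity[match(meta$infant_id[s],
                                       infants$infant_id)]
      sdn <- config$noise_sd *
        max(0.2, 1 + config$volatility_age_slope * (age - 76))
      gl <- g$baseline +
        g$amplitude * cos(2 * pi * (t_clock - g$acrophase_h) / 24) +
        u[meta$infant_id[s], ] + stats::rnorm(nrow(g), 0, sdn)
      la <- gl[match(reg$genus, g$genus)]
      la[is.na(la)] <- mean(g$baseline) - 2   # phylum-unassigned ASVs
      la <- la + reg$log_weight
      # propensity shifts the onset clock: +1 SD of propensity makes
      # `diversity_propensity_features` extra ASVs detectable (their onset
      # density is richness_slope per day)
      onset_cut <- age + prop * config$diversity_propensity_features /
        config$richness_slope
      la[reg$onset_day > max(0, onset_cut)] <- -Inf
      w <- exp(la - max(la[is.finite(la)]))
      w[!is.finite(w)] <- 0
      lib <- round(stats::rlnorm(1, config$library_size$meanlog,
                                 config$library_size$sdlog))
      lib <- max(lib, config$library_size$min)
      cm[s, ] <- stats::rmultinom(1, lib, w)
    }
    cm
  })

  tree <- with_seed(derive_seed(seed, "tree"),
                    ape::rcoal(nrow(reg), tip.label = reg$feature_id))
  taxonomy <- data.frame(
    feature_id = reg$feature_id,
    domain = "Bacteria", phylum = reg$phylum,
    class = ifelse(nzchar(reg$phylum), paste0(reg$phylum, "_c"), ""),
    order = ifelse(nzchar(reg$phylum), paste0(reg$family, "_o"), ""),
    family = reg$family, genus = reg$genus, stringsAsFactors = FALSE)

  truth <- list(
    genera = g[, c("genus", "baseline", "amplitude", "acrophase_h")],
    top_genera = g$genus[order(g$baseline, decreasing = TRUE)][1:5],
    rare_features = reg$feature_id[reg$rare],
    phylum_unassigned_features = reg$feature_id[!nzchar(reg$phylum)],
    richness_slope = config$richness_slope,
    infants = design$infants)
  list(table = feature_table(counts), taxonomy = taxonomy,
       tree = validate_tree(tree), metadata = meta, ground_truth = truth,
       design = design)
}

# Clean (noise- and fragmentation-free) rest-activity profile in [0, 1]
# scale units: (1 - r) + r * max(0, cos(theta) - tau) / (1 - tau), with
# tau = cos(pi * duty) so the profile is exactly 0 for (1 - duty) of the
# day when r = 1.
activity_profile <- function(clock_h, r, peak_hour, duty) {
  tau <- cos(pi * duty)
  theta <- 2 * pi * (clock_h - peak_hour) / 24
  (1 - r) + r * pmax(0, cos(theta) - tau) / (1 - tau)
}

#' Simulate per-minute actimetry for every infant-age
#'
#' Rectified-sinusoid profile with configured relative amplitude and peak
#' hour, white noise, a fragmentation process (Poisson-rate state flips
#' that mirror activity within its clean range, monotonically raising IV),
#' and optional non-wear gaps recorded in the wear mask.
#'
#' @inheritParams simulate_feature_table
#' @return list(actimetry = long data.frame(infant_id, age_group,
#'   timestamp, activity, wear), truth = per-key data.frame(days, ra_true,
#'   frag_per_h)).
#' @export
simulate_actigraphy <- function(config = default_cohort_config(), seed = 1L,
                                design = NULL) {
  if (is.null(design)) design <- design_cohort(config, seed)
  ac <- config$activity
  if (ac$days_min < 1) stopf("config error: days must be >= 1")
  if ((60 %% ac$epoch_min) != 0)
    stopf("config error: epoch length must divide 60 min")
  keys <- design$keys
  out <- list(); truth <- list()
  for (k in seq_len(nrow(keys))) {
    sub_seed <- derive_seed(seed, "actigraphy", keys$infant_id[k],
                            keys$age_group[k])
    res <- with_seed(sub_seed, {
      days <- round(stats::rnorm(1, ac$days_mean, ac$days_sd))
      days <- min(max(days, ac$days_min), ac$days_max)
      prop <- design$infants$propensity[
        match(keys$infant_id[k], design$infants$infant_id)]
      r <- ac$ra_base + ac$ra_age_slope * (keys$age_days[k] - 76) +
        ac$ra_propensity * prop
      r <- min(max(r, 0.1), 1)
      frag <- max(0, ac$frag_per_h +
                    ac$frag_age_slope * (keys$age_days[k] - 76))
      epm <- ac$epoch_min
      nmin <- days * 24 * 60 / epm
      ts <- keys$start[k] + (seq_len(nmin) - 1) * 60 * epm
      clk <- clock_hour(ts)
      clean <- ac$mesor * activity_profile(clk, r, ac$peak_hour, ac$duty)
      act <- clean
      if (frag > 0) {
        # two-state sojourn process: quiet spells end at rate `frag`/h,
        # fragmentation episodes end at rate `frag_exit_per_h`, so the
        # flipped fraction (and the realized IV) grows with `frag`
        p_enter <- frag * epm / 60
        p_exit <- ac$frag_exit_per_h * epm / 60
        toggle <- logical(nmin)
        t_pos <- 1L
        frag_state <- FALSE
        while (t_pos <= nmin) {
          len <- stats::rgeom(1, if (frag_state) p_exit else p_enter) + 1L
          end <- min(nmin, t_pos + len - 1L)
          if (frag_state) toggle[t_pos:end] <- TRUE
          t_pos <- end + 1L
          frag_state <- !frag_state
        }
        act[toggle] <- max(clean) + min(clean) - act[toggle]
      }
      if (ac$noise_sd > 0)
        act <- pmax(0, act + stats::rnorm(nmin, 0, ac$noise_sd))
      wear <- rep(TRUE, nmin)
      nb <- stats::rpois(1, ac$nonwear_blocks_mean)
      if (nb > 0) for (b in seq_len(nb)) {
        len <- round(stats::runif(1, ac$nonwear_min, ac$nonwear_max) / epm)
        st <- sample.int(nmin - len, 1)
        wear[st:(st + len - 1)] <- FALSE
      }
      list(df = data.frame(infant_id = keys$infant_id[k],
                           age_group = keys$age_group[k], timestamp = ts,
                           activity = act, wear = wear,
                           stringsAsFactors = FALSE),
           tr = data.frame(infant_id = keys$infant_id[k],
                           age_group = keys$age_group[k], days = days,
                           ra_true = r, frag_per_h = frag,
                           stringsAsFactors = FALSE))
    })
    out[[k]] <- res$df; truth[[k]] <- res$tr
  }
  list(actimetry = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Simulate diaries, feeding events, questionnaires and melatonin
#'
#' Diary sleep/wake states discretize the clean activity ground truth to
#' 15-min intervals with reporting jitter; feeding events recur at the
#' configured mean interval with uniform jitter during wake hours; BISQ
#' variables follow configured age trends; BCQ/ASQ are draws from
#' configured normals; stool melatonin = intercept + slope * age_days +
#' log-normal noise, attached to the sample metadata.
#'
#' @inheritParams simulate_feature_table
#' @param activity_truth per-key truth from [simulate_actigraphy()].
#' @param metadata sample metadata from [simulate_feature_table()]
#'   (melatonin column is filled in).
#' @return list(diary, feedings, questionnaires, metadata).
#' @export
simulate_diary_and_questionnaires <- function(config = default_cohort_config(),
                                              seed = 1L, design = NULL,
                                              activity_truth = NULL,
                                              metadata = NULL) {
  if (is.null(design)) design <- design_cohort(config, seed)
  if (is.null(activity_truth))
    activity_truth <- simulate_actigraphy(config, seed, design)$truth
  keys <- design$keys
  dy <- config$diary; fe <- config$feeding; ac <- config$activity
  diary <- list(); feeds <- list(); quest <- list()
  for (k in seq_len(nrow(keys))) {
    sub_seed <- derive_seed(seed, "diary", keys$infant_id[k],
                            keys$age_group[k])
    res <- with_seed(sub_seed, {
      tr <- activity_truth[
        activity_truth$infant_id == keys$infant_id[k] &
          activity_truth$age_group == keys$age_group[k], ]
      days <- if (nrow(tr)) tr$days[1] else
        round(ac$days_mean)
      r <- if (nrow(tr)) tr$ra_true[1] else ac$ra_base
      n_int <- days * 24 * 60 / dy$interval_min
      starts <- keys$start[k] + (seq_len(n_int) - 1) * 60 * dy$interval_min
      clk <- clock_hour(starts)
      # sleep whenever the clean profile is in its trough region; wake
      # spans `wake_frac` of the day around the activity peak
      tau_wake <- cos(pi * dy$wake_frac)
      awake <- cos(2 * pi * (clk - ac$peak_hour) / 24) > tau_wake
      if (dy$report_jitter > 0) {
        flips <- which(diff(awake) != 0)
        for (f in flips) if (stats::runif(1) < dy$report_jitter)
          awake[f] <- !awake[f]
      }
      ddf <- data.frame(infant_id = keys$infant_id[k],
                        age_group = keys$age_group[k],
                        interval_start = starts,
                        state = ifelse(awake, "wake", "sleep"),
                        stringsAsFactors = FALSE)
      ftimes <- c()
      for (d in seq_len(days)) {
        day0 <- keys$start[k] + (d - 1) * 86400
        wake_start <- (ac$peak_hour - 12 * dy$wake_frac) %% 24
        t <- wake_start + 0.5
        end_t <- wake_start + 24 * dy$wake_frac
        while (t < end_t) {
          ftimes <- c(ftimes, day0 + round(t * 3600))
          t <- t + fe$mean_interval_h +
            stats::runif(1, -fe$jitter_h, fe$jitter_h)
        }
      }
      fdf <- data.frame(infant_id = keys$infant_id[k],
                        age_group = keys$age_group[k],
                        feed_time = .POSIXct(as.numeric(ftimes),
                                             tz = GR_TZ),
                        stringsAsFactors = FALSE)
      bq <- config$bisq; age <- keys$age_days[k]
      qvals <- c(
        bisq_night_sleep_h = max(6, bq$night_base +
                                   bq$night_age_slope * (age - 76) +
                                   stats::rnorm(1, 0, bq$night_sd)),
        bisq_latency_h = max(0.05, bq$latency_base +
                               bq$latency_age_slope * (age - 76) +
                               stats::rnorm(1, 0, bq$latency_sd)),
        bisq_bedtime_clock_h = (bq$bedtime_base +
                                  bq$bedtime_age_slope * (age - 76) +
                                  stats::rnorm(1, 0, bq$bedtime_sd)) %% 24,
        bisq_n_awakenings = stats::rpois(1, bq$awakenings_lambda))
      qvals[stats::runif(4) < bq$missing_frac] <- NA
      qdf <- data.frame(infant_id = keys$infant_id[k],
                        age_group = keys$age_group[k],
                        t(qvals),
                        bcq_attunement = stats::rnorm(1, config$bcq$mean,
                                                      config$bcq$sd),
                        asq_composite = stats::rnorm(1, config$asq$mean,
                                                     config$asq$sd),
                        stringsAsFactors = FALSE)
      list(d = ddf, f = fdf, q = qdf)
    })
    diary[[k]] <- res$d; feeds[[k]] <- res$f; quest[[k]] <- res$q
  }
  out <- list(diary = do.call(rbind, diary),
              feedings = do.call(rbind, feeds),
              questionnaires = do.call(rbind, quest))
  if (!is.null(metadata)) {
    ml <- config$melatonin
    metadata$melatonin_pg_per_g <- with_seed(derive_seed(seed, "melatonin"), {
      v <- ml$intercept + ml$slope * metadata$age_days +
        stats::rlnorm(nrow(metadata), ml$noise_meanlog, ml$noise_sdlog)
      v[stats::runif(nrow(metadata)) < ml$missing_frac] <- NA
      v
    })
    out$metadata <- metadata
  }
  out
}

#' Generate a complete synthetic cohort bundle
#'
#' Calls the three simulators with derived sub-seeds and (optionally)
#' writes every input file in the standard layout plus
#' `ground_truth.json`.
#'
#' @inheritParams simulate_feature_table
#' @param dir optional output directory; when given the bundle is written
#'   with [write_cohort_bundle()].
#' @return the cohort bundle (list).
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            dir = NULL) {
  design <- design_cohort(config, seed)
  ft <- simulate_feature_table(config, seed, design)
  acts <- simulate_actigraphy(config, seed, design)
  dq <- simulate_diary_and_questionnaires(config, seed, design,
                                          activity_truth = acts$truth,
                                          metadata = ft$metadata)
  truth <- ft$ground_truth
  truth$activity <- acts$truth
  truth$coefficients <- list(
    melatonin_slope = config$melatonin$slope,
    richness_slope = config$richness_slope,
    ra_age_slope = config$activity$ra_age_slope,
    volatility_age_slope = config$volatility_age_slope)
  bundle <- list(table = ft$table, taxonomy = ft$taxonomy, tree = ft$tree,
                 metadata = dq$metadata, questionnaires = dq$questionnaires,
                 actimetry = acts$actimetry, diary = dq$diary,
                 feedings = dq$feedings, ground_truth = truth)
  if (!is.null(dir)) write_cohort_bundle(bundle, dir)
  bundle
}
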