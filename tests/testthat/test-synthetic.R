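# Generator properties: determinism, stated-world distributions, and the
# ground-truth couplings downstream recovery tests rely on.

test_that("generation is deterministic under the master seed", {
  cfg <- tiny_cohort_config()
  a <- simulate_feature_table(cfg, seed = 11)
  b <- simulate_feature_table(cfg, seed = 11)
  expect_identical(a$table, b$table)
  c <- simulate_feature_table(cfg, seed = 12)
  expect_false(identical(a$table, c$table))
})

test_that("cohort shape honors the configured distributions", {
  cfg <- tiny_cohort_config()
  b <- generate_cohort(cfg, seed = 3)
  counts <- table(paste(b$metadata$infant_id, b$metadata$age_group))
  expect_true(all(counts >= 1 & counts <= 11))
  expect_true(all(rowSums(b$table) >= 3035))
  tr <- b$ground_truth$activity
  expect_true(all(tr$days >= 3 & tr$days <= 11))
  # every feature is a tree tip
  expect_true(all(colnames(b$table) %in% b$tree$tip.label))
})

test_that("phylum-unassigned fraction matches its binomial expectation", {
  cfg <- tiny_cohort_config()
  # ~500 ASVs, 10% unassigned
  cfg$genera$n_asvs <- c(60, 55, 50, 50, 45, 45, 45, 40, 40, 40)
  cfg$n_emerging_features <- 30
  cfg$n_rare_features <- 0
  cfg$phylum_unassigned_frac <- 0.1
  ft <- simulate_feature_table(cfg, seed = 5)
  n <- nrow(ft$taxonomy)
  n_un <- sum(!nzchar(ft$taxonomy$phylum))
  expect_identical(length(ft$ground_truth$phylum_unassigned_features), n_un)
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(n_un - 0.1 * n), 3 * sigma)
})

test_that("noise-free integer-day actigraphy yields IS = 1 and RA = 1", {
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 2
  cfg$activity$noise_sd <- 0
  cfg$activity$frag_per_h <- 0
  cfg$activity$frag_age_slope <- 0
  cfg$activity$nonwear_blocks_mean <- 0
  cfg$activity$ra_base <- 1
  cfg$activity$ra_age_slope <- 0
  cfg$activity$ra_propensity <- 0
  sim <- simulate_actigraphy(cfg, seed = 2)
  key <- sim$truth[1, ]
  sub <- sim$actimetry[sim$actimetry$infant_id == key$infant_id &
                         sim$actimetry$age_group == key$age_group, ]
  h <- bin_hourly(sub$timestamp, sub$activity, sub$wear)
  expect_close(interdaily_stability(h), 1, 1e-9)
  # duty 16/24 leaves an 8-h zero trough -> L5 = 0 -> RA = 1
  expect_identical(relative_amplitude(h)$ra, 1)
})

test_that("realized IV increases with the fragmentation rate", {
  # spec states a 50-seed average; 10 seeds suffice for strict ordering
  # at these widely spaced rates and keep the suite fast
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 1
  cfg$ages_per_infant_probs <- c(1, 0, 0)
  cfg$activity$frag_age_slope <- 0
  mean_iv <- vapply(c(0, 0.2, 0.5), function(fr) {
    cfg$activity$frag_per_h <- fr
    ivs <- vapply(1:10, function(s) {
      sim <- simulate_actigraphy(cfg, seed = 100 + s)
      sub <- sim$actimetry
      h <- bin_hourly(sub$timestamp, sub$activity, sub$wear)
      intradaily_variability(h)$iv_raw
    }, 0)
    mean(ivs)
  }, 0)
  expect_true(all(diff(mean_iv) > 0))
})

test_that("CFI decreases with fragmentation (seed-averaged)", {
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 1
  cfg$ages_per_infant_probs <- c(1, 0, 0)
  cfg$activity$frag_age_slope <- 0
  mean_cfi <- vapply(c(0, 0.2, 0.5), function(fr) {
    cfg$activity$frag_per_h <- fr
    v <- vapply(1:10, function(s) {
      sim <- simulate_actigraphy(cfg, seed = 200 + s)
      actigraphy_per_infant_age(sim$actimetry)$metrics$cfi[1]
    }, 0)
    mean(v)
  }, 0)
  expect_true(all(diff(mean_cfi) < 0))
})

test_that("zero feed jitter gives zero feeding rhythmicity", {
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 3
  cfg$feeding$jitter_h <- 0
  dq <- simulate_diary_and_questionnaires(cfg, seed = 4)
  fr <- feeding_rhythmicity(dq$feedings)
  expect_true(nrow(fr) > 0)
  expect_close(fr$feeding_rhythmicity, 0, 1e-9)
})

test_that("flat diurnal amplitudes produce no systematic cosinor signal", {
  # permutation-null check, scaled down from the spec's 200 groups
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 10
  cfg$genera$amplitude <- rep(0, nrow(cfg$genera))
  cfg$samples_per_infant_age <- list(meanlog = log(6), sdlog = 0.2,
                                     min = 4, max = 11)
  ft <- simulate_feature_table(cfg, seed = 21)
  gen <- collapse_to_genus(ft$table, ft$taxonomy)$rel_abundance
  meta <- ft$metadata
  keys <- unique(meta[, c("infant_id", "age_group")])
  target <- "Bifidobacterium"
  r2_obs <- c(); r2_null <- c()
  set.seed(99)
  for (k in seq_len(nrow(keys))) {
    sub <- meta[meta$infant_id == keys$infant_id[k] &
                  meta$age_group == keys$age_group[k], ]
    if (nrow(sub) < 4) next
    t_h <- as.numeric(sub$collection_datetime) / 3600
    y <- gen[sub$sample_id, target]
    f <- tryCatch(fit_cosinor(t_h, y), error = function(e) NULL)
    if (is.null(f) || is.na(f$r_squared)) next
    r2_obs <- c(r2_obs, f$r_squared)
    for (p in 1:5) {
      fp <- tryCatch(fit_cosinor(sample(t_h), y), error = function(e) NULL)
      if (!is.null(fp) && !is.na(fp$r_squared))
        r2_null <- c(r2_null, fp$r_squared)
    }
  }
  expect_gt(length(r2_obs), 10)
  se <- sqrt(stats::var(r2_obs) / length(r2_obs) +
               stats::var(r2_null) / length(r2_null))
  expect_lt(abs(mean(r2_obs) - mean(r2_null)), 4 * se + 0.02)
})

test_that("melatonin age slope is recoverable by the mixed model", {
  # single-replicate CI check, scaled down from the spec's 100-replicate
  # recovery study over 200 infants
  cfg <- tiny_cohort_config()
  cfg$n_infants <- 40
  cfg$ages_per_infant_probs <- c(0, 0, 1)
  dsn <- gutrhythm:::design_cohort(cfg, seed = 31)
  md <- do.call(rbind, lapply(seq_len(nrow(dsn$keys)), function(k) {
    data.frame(sample_id = paste0("s", k), infant_id = dsn$keys$infant_id[k],
               age_group = dsn$keys$age_group[k],
               age_days = dsn$keys$age_days[k],
               collection_datetime = dsn$keys$start[k],
               sex = dsn$infants$sex[match(dsn$keys$infant_id[k],
                                           dsn$infants$infant_id)])
  }))
  cfg$melatonin$missing_frac <- 0
  dq <- simulate_diary_and_questionnaires(cfg, seed = 31, design = dsn,
                                          metadata = md)
  fit <- fit_lmm(dq$metadata, "melatonin_pg_per_g", "age_days")
  co <- fit$coefficients[fit$coefficients$term == "age_days", ]
  expect_lt(abs(co$estimate - 0.638), 1.96 * co$se + 1e-9)
})
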