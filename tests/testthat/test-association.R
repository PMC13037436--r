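# Analysis-table assembly rules and the mixed-model suite.

alpha_long <- function(meta, values) {
  do.call(rbind, lapply(ALPHA_METRICS, function(m)
    data.frame(sample_id = meta$sample_id, metric = m,
               value = if (m == "shannon") values else
                 seq_along(meta$sample_id))))
}

meta_min <- function() {
  data.frame(sample_id = paste0("s", 1:3), infant_id = "I1", age_group = 2L,
             age_days = c(75, 76, 77),
             collection_datetime = as.POSIXct("2023-06-01 10:00:00",
                                              tz = "UTC") + 3600 * (1:3),
             sex = "female", melatonin_pg_per_g = NA_real_)
}

test_that("per-infant-age alpha aggregation is the median", {
  meta <- meta_min()
  tabs <- build_analysis_tables(alpha = alpha_long(meta, c(2.0, 2.4, 3.0)),
                                metadata = meta)
  expect_close(tabs$infant_age$shannon, 2.4, 1e-12)
  expect_identical(tabs$infant_age$age_days, 76)
})

test_that("melatonin outliers beyond mean + 8 SD are excluded", {
  base <- c(rep(10, 40), rep(12, 40))
  # fixed point v* where v = mean + 8 SD of the augmented cohort
  f <- function(v) {
    x <- c(base, v); v - (mean(x) + 8 * stats::sd(x))
  }
  vstar <- stats::uniroot(f, c(13, 1e5), tol = 1e-12)$root
  mk <- function(v) {
    n <- length(base) + 1
    data.frame(sample_id = paste0("s", 1:n),
               infant_id = rep(paste0("I", 1:9), length.out = n),
               age_group = 2L, age_days = 76,
               collection_datetime = as.POSIXct("2023-06-01", tz = "UTC"),
               sex = "female", melatonin_pg_per_g = c(base, v))
  }
  m_keep <- mk(vstar - 1e-6)   # at/below the cut: retained
  m_drop <- mk(vstar * 1.05)   # strictly above: excluded
  t_keep <- build_analysis_tables(alpha = alpha_long(m_keep, 1),
                                  metadata = m_keep)
  t_drop <- build_analysis_tables(alpha = alpha_long(m_drop, 1),
                                  metadata = m_drop)
  expect_false(anyNA(t_keep$sample$melatonin_pg_per_g))
  expect_identical(sum(is.na(t_drop$sample$melatonin_pg_per_g)), 1L)
  expect_true(any(grepl("melatonin outliers",
                        t_drop$provenance$what)))
})

sim_lmm_data <- function(n_inf = 20, beta = 0.1, re_sd = 0.5, sd = 1,
                         seed = 1) {
  set.seed(seed)
  inf <- rep(sprintf("I%02d", 1:n_inf), each = 3)
  age <- rep(c(76, 128, 190), n_inf) + rnorm(3 * n_inf, 0, 3)
  u <- rnorm(n_inf, 0, re_sd)[rep(1:n_inf, each = 3)]
  y <- beta * age + u + rnorm(3 * n_inf, 0, sd)
  data.frame(infant_id = inf, age_days = age, y = y)
}

test_that("fixed-at-zero variance equals a hand-rolled OLS oracle", {
  d <- sim_lmm_data(seed = 41)
  fit <- fit_lmm(d, "y", "age_days", random_intercept = FALSE)
  X <- cbind(1, d$age_days)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_close(fit$coefficients$estimate, as.numeric(beta_hat), 1e-10)
  expect_true(fit$ols_fallback)
  # singular REML fits also fall back to the same numbers
  d0 <- sim_lmm_data(re_sd = 0, seed = 42)
  fit0 <- fit_lmm(d0, "y", "age_days")
  if (fit0$singular)
    expect_close(fit0$coefficients$estimate, as.numeric(
      solve(t(cbind(1, d0$age_days)) %*% cbind(1, d0$age_days),
            t(cbind(1, d0$age_days)) %*% d0$y)), 1e-6)
})

test_that("Wald CIs cover the true exposure effect (scaled-down check)", {
  # 30-replicate companion of the acceptance-run 100-replicate study
  hits <- 0
  for (r in 1:30) {
    d <- sim_lmm_data(seed = 500 + r)
    fit <- fit_lmm(d, "y", "age_days")
    co <- fit$coefficients[fit$coefficients$term == "age_days", ]
    if (abs(co$estimate - 0.1) <= 1.96 * co$se) hits <- hits + 1
  }
  expect_gte(hits, 24) # binomial(30, .95) lower tail
})

test_that("rank-deficient designs and imputation rules are enforced", {
  d <- sim_lmm_data(seed = 43)
  d$age_copy <- d$age_days
  expect_error(fit_lmm(d, "y", "age_days", covariates = "age_copy"),
               "collinear")
  # covariate gaps are median-imputed and counted; exposure gaps excluded
  d2 <- sim_lmm_data(seed = 44)
  d2$cov <- rnorm(nrow(d2)); d2$cov[1:4] <- NA
  d2$y[5] <- NA
  fit <- fit_lmm(d2, "y", "age_days", covariates = "cov")
  expect_identical(fit$n_imputed, 4L)
  expect_identical(fit$excluded, 1L)
  expect_identical(fit$n_obs, nrow(d2) - 1L)
})

test_that("the registry instantiates one model per equation x metric", {
  targets <- c(ALPHA_METRICS, paste0("G", 1:5))
  reg <- default_model_registry(rhythm_targets = targets)
  counts <- table(reg$equation)
  expect_identical(as.integer(counts[c("eq4", "eq5", "eq6", "eq7")]),
                   rep(4L, 4))
  expect_identical(as.integer(counts["eq3"]), 9L)
  expect_identical(as.integer(counts["eq8"]), 1L)
  expect_identical(as.integer(counts["eq9"]), 4L)
  expect_false(anyDuplicated(reg$model_id) > 0)
})

test_that("the suite records per-model failures and continues", {
  d <- sim_lmm_data(seed = 45)
  d$sex <- rep(c("female", "male"), length.out = nrow(d))
  reg <- data.frame(model_id = c("ok:1", "bad:1"), equation = "eqX",
                    metric = c("a", "b"), resolution = "infant_age",
                    outcome = c("y", "not_a_column"),
                    exposure = "age_days", covariates = "sex")
  suite <- run_model_suite(reg, list(infant_age = d))
  expect_identical(suite$n_models, 2L)
  expect_s3_class(suite$fits[["ok:1"]], "gr_lmm")
  expect_true(is.character(suite$fits[["bad:1"]]))
  expect_true(any(grepl("^ERROR:", suite$summary$term)))
})

test_that("aggregation-then-model equals model on a pre-aggregated table", {
  meta <- rbind(meta_min(), within(meta_min(), {
    sample_id <- paste0("t", 1:3); infant_id <- "I2"; sex <- "male"
    age_days <- c(120, 128, 130)
  }))
  alpha <- alpha_long(meta, c(2, 2.4, 3, 1, 1.5, 2))
  tabs <- build_analysis_tables(alpha = alpha, metadata = meta)
  manual <- data.frame(infant_id = c("I1", "I2"),
                       shannon = c(2.4, 1.5),
                       age_days = c(76, 128),
                       sex = c("female", "male"))
  got <- tabs$infant_age[order(tabs$infant_age$infant_id),
                         c("infant_id", "shannon", "age_days", "sex")]
  rownames(got) <- NULL
  expect_equal(got, manual)
})
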