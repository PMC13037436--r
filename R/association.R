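# Analysis-table assembly (aggregation, imputation, outlier rules) and the
# random-intercept linear mixed-model suite.
#
# Rules carried through from the analysis protocol: per-infant-age alpha
# diversity is the MEDIAN of the samples' values; rows missing outcome or
# exposure are excluded per model; missing covariates are median-imputed;
# melatonin values more than 8 SD above the cohort mean are excluded
# (exactly mean + 8 SD is retained); estimation is REML with Wald z
# inference; sex is coded with female as reference; age enters as
# continuous age_days; no multiplicity correction (the number of models is
# reported instead).

#' Assemble the infant-age- and sample-level analysis tables
#'
#' @param alpha long per-sample alpha table (sample_id, metric, value).
#' @param rhythm cosinor fits ([rhythmicity_per_infant_age()]`$fits`).
#' @param volatility named list (per beta metric) of volatility records.
#' @param circadian CFI table ([actigraphy_per_infant_age()]`$metrics`).
#' @param squid BabySQUID scores ([compute_babysquid()]`$scores`).
#' @param feeding feeding rhythmicity table.
#' @param questionnaires questionnaire records (BCQ/ASQ).
#' @param history per-sample history table ([derive_sample_history()]).
#' @param metadata sample metadata.
#' @return list(infant_age, sample, provenance).
#' @export
build_analysis_tables <- function(alpha, rhythm = NULL, volatility = NULL,
                                  circadian = NULL, squid = NULL,
                                  feeding = NULL, questionnaires = NULL,
                                  history = NULL, metadata) {
  prov <- list()
  note <- function(stage, what, n)
    prov[[length(prov) + 1L]] <<- data.frame(stage = stage, what = what,
                                             n = n)
  meta <- metadata
  # melatonin outlier rule: strictly greater than mean + 8 SD
  mel <- meta$melatonin_pg_per_g
  if (any(!is.na(mel))) {
    cut <- mean(mel, na.rm = TRUE) + 8 * stats::sd(mel, na.rm = TRUE)
    out <- which(!is.na(mel) & mel > cut)
    if (length(out)) {
      note("sample", "melatonin outliers excluded (> mean + 8 SD)",
           length(out))
      meta$melatonin_pg_per_g[out] <- NA
    }
  }

  # ---- sample-level table ----
  sample_tab <- meta[, c("sample_id", "infant_id", "age_group", "age_days",
                         "sex", "melatonin_pg_per_g")]
  aw <- stats::reshape(alpha, idvar = "sample_id", timevar = "metric",
                       direction = "wide")
  names(aw) <- sub("^value\\.", "", names(aw))
  sample_tab <- merge(sample_tab, aw, by = "sample_id", all.x = TRUE)
  if (!is.null(history))
    sample_tab <- merge(sample_tab, history, by = "sample_id", all.x = TRUE)
  note("sample", "rows", nrow(sample_tab))

  # ---- infant-age-level table ----
  keys <- unique(meta[, c("infant_id", "age_group")])
  ia <- keys
  ia$age_days <- NA_real_; ia$sex <- NA_character_
  for (m in ALPHA_METRICS) ia[[m]] <- NA_real_
  for (i in seq_len(nrow(ia))) {
    sub <- meta[meta$infant_id == ia$infant_id[i] &
                  meta$age_group == ia$age_group[i], ]
    ia$age_days[i] <- stats::median(sub$age_days)
    ia$sex[i] <- sub$sex[1]
    for (m in ALPHA_METRICS) {
      v <- alpha$value[alpha$metric == m &
                         alpha$sample_id %in% sub$sample_id]
      ia[[m]][i] <- if (length(v)) stats::median(v, na.rm = TRUE) else NA_real_
    }
  }
  join_ia <- function(tab, cols, prefix = NULL) {
    if (is.null(tab) || nrow(tab) == 0) return(invisible(NULL))
    for (cl in cols) {
      nm <- if (is.null(prefix)) cl else paste0(prefix, cl)
      ia[[nm]] <<- tab[[cl]][match(paste(ia$infant_id, ia$age_group),
                                   paste(tab$infant_id, tab$age_group))]
    }
  }
  if (!is.null(rhythm) && nrow(rhythm)) {
    for (target in unique(rhythm$target)) {
      sub <- rhythm[rhythm$target == target, ]
      ia[[paste0("rhythm_", gsub("[^A-Za-z0-9]+", "_", target))]] <-
        sub$r_squared[match(paste(ia$infant_id, ia$age_group),
                            paste(sub$infant_id, sub$age_group))]
    }
  }
  if (!is.null(volatility)) {
    for (bm in names(volatility)) {
      sub <- volatility[[bm]]
      ia[[paste0("vol_", bm)]] <-
        sub$volatility[match(paste(ia$infant_id, ia$age_group),
                             paste(sub$infant_id, sub$age_group))]
    }
  }
  join_ia(circadian, "cfi")
  join_ia(squid, "babysquid")
  join_ia(feeding, "feeding_rhythmicity")
  join_ia(questionnaires, c("bcq_attunement", "asq_composite"))
  note("infant_age", "rows", nrow(ia))
  prov <- do.call(rbind, prov)
  list(infant_age = ia, sample = sample_tab, provenance = prov)
}

#' Fit one random-intercept linear mixed model
#'
#' `outcome ~ exposure + covariates + (1 | group)` by REML with Wald z
#' tests. Rows with a missing outcome or exposure are excluded; missing
#' covariates are replaced by the median of that variable (the count is
#' reported). A singular random-effect fit (or `random_intercept = FALSE`,
#' the exact variance-fixed-at-zero model) falls back to ordinary least
#' squares with the same Wald inference and a flag.
#'
#' @param table analysis data frame.
#' @param outcome,exposure,covariates variable names; `exposure` may be a
#'   character vector (all treated under the exclusion rule).
#' @param group grouping factor column (default "infant_id").
#' @param random_intercept set FALSE to fix the random-intercept variance
#'   at zero (plain OLS).
#' @return list (class "gr_lmm") with coefficients data frame (term,
#'   estimate, se, z, p), n_obs, n_groups, re_var, resid_var, singular,
#'   converged, n_imputed, excluded.
#' @export
fit_lmm <- function(table, outcome, exposure, covariates = character(),
                    group = "infant_id", random_intercept = TRUE) {
  vars <- c(outcome, exposure, covariates, group)
  miss <- setdiff(vars, names(table))
  if (length(miss))
    stopf("variable(s) not in table: %s", paste(miss, collapse = ", "))
  df <- table[, vars, drop = FALSE]
  keep <- stats::complete.cases(df[, c(outcome, exposure), drop = FALSE])
  excluded <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n_imputed <- 0L
  for (cv in covariates) {
    na <- is.na(df[[cv]])
    if (any(na)) {
      if (is.numeric(df[[cv]])) {
        df[[cv]][na] <- stats::median(df[[cv]], na.rm = TRUE)
        n_imputed <- n_imputed + sum(na)
      } else {
        df <- df[!na, , drop = FALSE]
      }
    }
  }
  if (nrow(df) == 0) stopf("empty analysis table for outcome %s", outcome)
  if (length(unique(df[[group]])) < 2)
    stopf("need >= 2 groups to fit a mixed model")
  if ("sex" %in% names(df))
    df$sex <- factor(df$sex, levels = c("female", "male"))
  fixed <- paste(c(exposure, covariates), collapse = " + ")
  fixed_formula <- stats::as.formula(paste(outcome, "~", fixed))
  X <- stats::model.matrix(fixed_formula, df)
  if (qr(X)$rank < ncol(X)) {
    drop_candidates <- colnames(X)[-1]
    stopf("rank-deficient fixed-effects design; collinear term(s) among: %s",
          paste(drop_candidates, collapse = ", "))
  }
  n_fixed <- ncol(X)
  if (nrow(df) < n_fixed + 1)
    stopf("too few observations (%d) for %d fixed effects", nrow(df), n_fixed)

  ols_fit <- function() {
    fit <- stats::lm(fixed_formula, data = df)
    s <- summary(fit)
    co <- s$coefficients
    list(coefficients = data.frame(
      term = rownames(co), estimate = co[, 1], se = co[, 2],
      z = co[, 1] / co[, 2],
      p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
      row.names = NULL, stringsAsFactors = FALSE),
      re_var = 0, resid_var = s$sigma^2)
  }

  singular <- FALSE; converged <- TRUE; used_ols <- FALSE
  if (random_intercept) {
    form <- stats::as.formula(paste(outcome, "~", fixed,
                                    "+ (1 |", group, ")"))
    conv_msgs <- character(0)
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(form, data = df, REML = TRUE,
                   # covariates stay on raw scales by design; the scale
                   # check would warn on age_days vs unit-scale outcomes
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               check.scaleX = "ignore")),
        warning = function(w) {
          conv_msgs <<- c(conv_msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (length(conv_msgs)) converged <- FALSE
    if (inherits(fit, "error")) {
      converged <- FALSE; used_ols <- TRUE
      res <- ols_fit()
    } else if (lme4::isSingular(fit, tol = 1e-6)) {
      singular <- TRUE; used_ols <- TRUE
      res <- ols_fit()
    } else {
      co <- summary(fit)$coefficients
      vc <- as.data.frame(lme4::VarCorr(fit))
      res <- list(coefficients = data.frame(
        term = rownames(co), estimate = co[, 1], se = co[, 2],
        z = co[, 1] / co[, 2],
        p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
        row.names = NULL, stringsAsFactors = FALSE),
        re_var = vc$vcov[vc$grp == group],
        resid_var = vc$vcov[vc$grp == "Residual"])
    }
  } else {
    used_ols <- TRUE
    res <- ols_fit()
  }
  structure(list(coefficients = res$coefficients,
                 outcome = outcome, exposure = exposure,
                 covariates = covariates,
                 n_obs = nrow(df),
                 n_groups = length(unique(df[[group]])),
                 re_var = res$re_var, resid_var = res$resid_var,
                 singular = singular, converged = converged,
                 ols_fallback = used_ols,
                 n_imputed = n_imputed, excluded = excluded),
            class = "gr_lmm")
}

#' @export
print.gr_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: %s ~ %s (+%d covariates)\n",
              x$outcome, paste(x$exposure, collapse = " + "),
              length(x$covariates)))
  cat(sprintf("  n_obs = %d, n_groups = %d, re_var = %.4g, singular = %s\n",
              x$n_obs, x$n_groups, x$re_var, x$singular))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Default model registry
#'
#' One entry per (equation, metric): sleep rhythmicity (CFI) against
#' microbiota rhythmicity / diversity / volatility; sleep quality
#' (BabySQUID) against diversity / volatility; melatonin against sample
#' history; diversity against sample history.
#'
#' @param rhythm_targets rhythmicity target names present in the
#'   infant-age table (alpha metrics and top genera).
#' @return data.frame registry (model_id, equation, metric, resolution,
#'   outcome, exposure, covariates as ;-joined string).
#' @export
default_model_registry <- function(rhythm_targets =
                                     c(ALPHA_METRICS, character())) {
  safe <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  rows <- list()
  add <- function(eq, metric, resolution, outcome, exposure, covs)
    rows[[length(rows) + 1L]] <<- data.frame(
      model_id = paste0(eq, ":", metric), equation = eq, metric = metric,
      resolution = resolution, outcome = outcome, exposure = exposure,
      covariates = paste(covs, collapse = ";"), stringsAsFactors = FALSE)
  covs_eq3 <- c("feeding_rhythmicity", "bcq_attunement", "age_days", "sex")
  for (t in rhythm_targets)
    add("eq3", t, "infant_age", "cfi", paste0("rhythm_", safe(t)), covs_eq3)
  covs_dev <- c("bcq_attunement", "asq_composite", "age_days", "sex")
  for (m in ALPHA_METRICS) add("eq4", m, "infant_age", "cfi", m, covs_dev)
  for (b in BETA_METRICS)
    add("eq5", b, "infant_age", "cfi", paste0("vol_", b), covs_dev)
  for (m in ALPHA_METRICS)
    add("eq6", m, "infant_age", "babysquid", m, covs_dev)
  for (b in BETA_METRICS)
    add("eq7", b, "infant_age", "babysquid", paste0("vol_", b), covs_dev)
  add("eq8", "melatonin", "sample", "melatonin_pg_per_g",
      "time_since_last_bowel_movement_h",
      c("prior_awake_h", "time_since_feeding_h", "age_days", "sex"))
  for (m in ALPHA_METRICS)
    add("eq9", m, "sample", m, "prior_awake_h",
        c("last_sleep_duration_h", "time_since_feeding_h", "age_days",
          "sex"))
  do.call(rbind, rows)
}

#' Fit every model in a registry
#'
#' Per-model failures are recorded and the suite continues. No
#' multiple-testing correction is applied; the summary reports the model
#' count so users can adjust externally.
#'
#' @param registry data.frame from [default_model_registry()].
#' @param tables list(infant_age, sample) from [build_analysis_tables()].
#' @return list(fits = named list of "gr_lmm" (or error message strings),
#'   summary = long data.frame of coefficients, n_models).
#' @export
run_model_suite <- function(registry, tables) {
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    tab <- tables[[r$resolution]]
    covs <- strsplit(r$covariates, ";", fixed = TRUE)[[1]]
    fit <- tryCatch(
      fit_lmm(tab, r$outcome, r$exposure, covs),
      error = function(e) conditionMessage(e))
    fits[[r$model_id]] <- fit
    if (inherits(fit, "gr_lmm")) {
      co <- fit$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = r$model_id, equation = r$equation, metric = r$metric,
        term = co$term, estimate = co$estimate, se = co$se, p = co$p,
        n_obs = fit$n_obs, n_infants = fit$n_groups,
        singular = fit$singular, ols_fallback = fit$ols_fallback,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = r$model_id, equation = r$equation, metric = r$metric,
        term = paste("ERROR:", fit), estimate = NA_real_, se = NA_real_,
        p = NA_real_, n_obs = NA_integer_, n_infants = NA_integer_,
        singular = NA, ols_fallback = NA, stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, summary = do.call(rbind, rows),
       n_models = nrow(registry))
}
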