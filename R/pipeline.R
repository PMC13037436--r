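# Configuration and the end-to-end pipeline orchestrator.

#' Default pipeline configuration
#'
#' Every tolerance, depth, count and seed used by the stages, organized by
#' stage; overridable piecewise via a YAML file ([read_config()]).
#' @return nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    input = list(simulate = TRUE, dir = NULL),
    synthetic = default_cohort_config(),
    filter = list(min_feature_total = 10, min_depth = 3035),
    diversity = list(depth = 3035, n_boot = 100,
                     normalized_wunifrac = FALSE,
                     genus_top_k = 5,
                     # genus series use raw filtered counts, per-sample
                     # normalized (config flag per open convention)
                     genus_abundance_source = "filtered"),
    rhythmicity = list(min_samples = 4),
    volatility = list(n_axes = 3, embedding_scope = "cohort"),
    actigraphy = list(epoch_min = 1, min_days = 3),
    history = list(feeding_aggregate = "mean"),
    association = list()
  )
}

#' Read a YAML configuration, merged over the defaults
#' @param path YAML file; NULL returns the defaults.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: simulate/load -> filter -> diversity ->
#' rhythmicity + volatility -> actigraphy -> sleep behavior -> association.
#' Every stage's outputs are written as TSV before the next consumes them;
#' a resolved config snapshot and a run log are kept alongside. The run is
#' a pure function of (inputs, config, seed): repeated runs are
#' byte-identical (the log carries no timestamps for this reason).
#'
#' @param config nested configuration ([default_config()]).
#' @param out_dir output directory (created).
#' @param seed master seed; overrides `config$seed` when given.
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(logf), add = TRUE)
  cfg_out <- config
  cfg_out$synthetic$genera <- NULL # data frame; serialized separately
  jsonlite::write_json(cfg_out, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  stage <- function(name, expr) {
    log_line(logf, "stage: ", name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  bundle <- stage("input", {
    if (isTRUE(config$input$simulate))
      generate_cohort(config$synthetic, seed = derive_seed(seed, "cohort"))
    else load_cohort_bundle(config$input$dir)
  })
  keep <- bundle$metadata$sample_id %in% rownames(bundle$table)
  bundle$metadata <- bundle$metadata[keep, ]

  filt <- stage("filter", filter_table(
    bundle$table, bundle$taxonomy,
    min_feature_total = config$filter$min_feature_total,
    min_depth = config$filter$min_depth))
  write_long_table(filt$exclusions, file.path(out_dir, "filter_exclusions.tsv"))
  write_feature_table(filt$table, file.path(out_dir, "filtered_table.tsv"))
  meta <- bundle$metadata[bundle$metadata$sample_id %in%
                            rownames(filt$table), ]
  log_line(logf, sprintf("retained %d/%d samples, %d features",
                         nrow(filt$table), nrow(bundle$table),
                         ncol(filt$table)))

  alpha <- stage("diversity/alpha", bootstrapped_alpha(
    filt$table, bundle$tree, depth = config$diversity$depth,
    n_boot = config$diversity$n_boot,
    seed = derive_seed(seed, "alpha")))
  write_long_table(alpha, file.path(out_dir, "alpha_diversity.tsv"))

  beta <- stage("diversity/beta", bootstrapped_beta(
    filt$table, bundle$tree, depth = config$diversity$depth,
    n_boot = config$diversity$n_boot,
    seed = derive_seed(seed, "beta"),
    normalized = isTRUE(config$diversity$normalized_wunifrac)))
  for (bm in names(beta)) {
    df <- data.frame(sample_id = rownames(beta[[bm]]), beta[[bm]],
                     check.names = FALSE)
    write_long_table(df, file.path(out_dir, paste0("beta_", bm, ".tsv")))
  }

  genus <- stage("diversity/genus", collapse_to_genus(
    filt$table, bundle$taxonomy, top_k = config$diversity$genus_top_k))
  write_long_table(
    data.frame(sample_id = rownames(genus$rel_abundance),
               genus$rel_abundance, check.names = FALSE),
    file.path(out_dir, "genus_relative_abundance.tsv"))

  rhythm <- stage("rhythmicity", rhythmicity_per_infant_age(
    alpha, genus$rel_abundance, meta, top_genera = genus$top_genera,
    min_samples = config$rhythmicity$min_samples))
  write_long_table(rhythm$fits, file.path(out_dir, "rhythmicity.tsv"))
  write_long_table(rhythm$exclusions,
                   file.path(out_dir, "rhythmicity_exclusions.tsv"))

  vol <- stage("volatility", {
    out <- list()
    for (bm in names(beta)) {
      v <- compute_volatility(beta[[bm]], meta,
                              n_axes = config$volatility$n_axes,
                              scope = config$volatility$embedding_scope)
      rec <- v$records
      rec$beta_metric <- rep(bm, nrow(rec))
      rec <- rec[, c("infant_id", "age_group", "beta_metric", "n_samples",
                     "volatility", "n_axes_used")]
      out[[bm]] <- list(records = v$records, long = rec,
                        exclusions = v$exclusions)
    }
    out
  })
  vol_long <- do.call(rbind, lapply(vol, `[[`, "long"))
  write_long_table(vol_long, file.path(out_dir, "volatility.tsv"))

  circ <- stage("actigraphy", actigraphy_per_infant_age(bundle$actimetry))
  write_long_table(circ$metrics, file.path(out_dir, "circadian_metrics.tsv"))
  write_long_table(circ$exclusions,
                   file.path(out_dir, "circadian_exclusions.tsv"))

  squid <- stage("squid", compute_babysquid(bundle$questionnaires))
  write_long_table(squid$scores, file.path(out_dir, "babysquid.tsv"))
  hist <- stage("history", derive_sample_history(meta, bundle$diary,
                                                 bundle$feedings))
  write_long_table(hist, file.path(out_dir, "sample_history.tsv"))
  feedr <- stage("feeding_rhythmicity", feeding_rhythmicity(
    bundle$feedings, aggregate = config$history$feeding_aggregate))
  write_long_table(feedr, file.path(out_dir, "feeding_rhythmicity.tsv"))

  assoc <- stage("association", {
    tables <- build_analysis_tables(
      alpha = alpha, rhythm = rhythm$fits,
      volatility = lapply(vol, `[[`, "records"),
      circadian = circ$metrics, squid = squid$scores, feeding = feedr,
      questionnaires = bundle$questionnaires, history = hist,
      metadata = meta)
    targets <- c(ALPHA_METRICS, genus$top_genera)
    registry <- default_model_registry(rhythm_targets = targets)
    suite <- run_model_suite(registry, tables)
    list(tables = tables, registry = registry, suite = suite)
  })
  write_long_table(assoc$tables$infant_age,
                   file.path(out_dir, "table_infant_age.tsv"))
  write_long_table(assoc$tables$sample, file.path(out_dir, "table_sample.tsv"))
  write_long_table(assoc$tables$provenance,
                   file.path(out_dir, "provenance.tsv"))
  write_long_table(assoc$suite$summary, file.path(out_dir, "model_fits.tsv"))
  log_line(logf, sprintf("fitted %d models", assoc$suite$n_models))
  log_line(logf, "done")

  invisible(list(bundle = bundle, filtered = filt, alpha = alpha,
                 beta = beta, genus = genus, rhythm = rhythm,
                 volatility = vol, circadian = circ, squid = squid,
                 history = hist, feeding = feedr,
                 association = assoc, out_dir = out_dir))
}
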