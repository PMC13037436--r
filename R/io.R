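# Shared data contracts and file I/O.
#
# All tabular inputs/outputs are plain TSV with a header row; missing values
# are written as empty fields and both "" and "NA" are accepted on read.
# Datetimes are local wall-clock ISO-8601 (no timezone arithmetic).

TAXON_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
AGE_GROUPS <- c(2L, 4L, 6L)
ALPHA_METRICS <- c("observed_features", "shannon", "pielou", "faith_pd")
BETA_METRICS <- c("bray_curtis", "jaccard", "unweighted_unifrac",
                  "weighted_unifrac")

#' Validate a feature table
#'
#' A feature table is an integer matrix of counts with samples as rows and
#' features (ASVs) as columns; row and column names are the sample and
#' feature identifiers.
#'
#' @param counts numeric matrix, samples x features, dimnames set.
#' @return the validated matrix (in storage mode double, integral values).
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) stopf("feature table must be a matrix")
  sid <- rownames(counts); fid <- colnames(counts)
  if (is.null(sid) || is.null(fid))
    stopf("feature table requires sample rownames and feature colnames")
  if (anyDuplicated(sid))
    stopf("duplicate sample id(s): %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(fid))
    stopf("duplicate feature id(s): %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stopf("feature table counts must be nonnegative integers")
  storage.mode(counts) <- "double"
  counts
}

#' Read a feature table from TSV or BIOM
#'
#' TSV orientation is auto-detected: a leading `sample_id` column means
#' samples x features, a leading `feature_id` / `#OTU ID` column means
#' features x samples; otherwise `sample_ids` (if given) breaks the tie by
#' id overlap. `.biom` files are read through the biomformat package when
#' it is installed.
#'
#' @param path file path.
#' @param sample_ids optional character vector of known sample ids used for
#'   orientation auto-detection.
#' @return validated counts matrix (samples x features).
#' @export
read_feature_table <- function(path, sample_ids = NULL) {
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading %s requires the biomformat package", path)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # features x samples
    return(feature_table(t(m)))
  }
  df <- read_long_table(path, check.names = FALSE)
  if (!ncol(df)) stopf("parse error in %s: empty table", path)
  first <- names(df)[1]
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("parse error in %s: non-numeric counts", path)
  rownames(m) <- ids
  orient <- if (first %in% c("sample_id", "sample-id", "SampleID")) {
    "samples"
  } else if (first %in% c("feature_id", "#OTU ID", "Feature ID")) {
    "features"
  } else if (!is.null(sample_ids)) {
    if (mean(ids %in% sample_ids) >= mean(colnames(m) %in% sample_ids))
      "samples" else "features"
  } else "samples"
  if (orient == "features") m <- t(m)
  feature_table(m)
}

#' Write a feature table as TSV (samples x features)
#' @param table counts matrix. @param path destination.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_long_table(df, path)
}

parse_taxon_string <- function(x) {
  out <- matrix("", length(x), length(TAXON_RANKS),
                dimnames = list(NULL, TAXON_RANKS))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) next
    parts <- trimws(strsplit(x[i], ";", fixed = TRUE)[[1]])
    parts <- sub("^[dkpcofgs]__", "", parts)
    n <- min(length(parts), length(TAXON_RANKS))
    if (n > 0) out[i, seq_len(n)] <- parts[seq_len(n)]
  }
  out
}

#' Read a taxonomy table
#'
#' Two-column TSV (`Feature ID`, `Taxon`) with semicolon-delimited ranks;
#' QIIME-style `p__` prefixes are tolerated and stripped. Returns a data
#' frame with one row per feature and explicit (possibly empty) columns for
#' domain, phylum, class, order, family and genus.
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  df <- read_long_table(path, check.names = FALSE)
  nm <- tolower(gsub("[ _-]", "", names(df)))
  fid_col <- which(nm %in% c("featureid", "otuid", "#otuid"))[1]
  tax_col <- which(nm == "taxon")[1]
  if (is.na(fid_col) || is.na(tax_col))
    stopf("parse error in %s: need 'Feature ID' and 'Taxon' columns", path)
  fid <- as.character(df[[fid_col]])
  if (anyDuplicated(fid))
    stopf("duplicate feature id(s) in taxonomy: %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  ranks <- parse_taxon_string(as.character(df[[tax_col]]))
  data.frame(feature_id = fid, ranks, stringsAsFactors = FALSE)
}

#' Write a taxonomy table in the two-column convention
#' @param taxonomy data frame from [read_taxonomy()]. @param path destination.
#' @export
write_taxonomy <- function(taxonomy, path) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__")
  taxon <- apply(taxonomy[, TAXON_RANKS, drop = FALSE], 1, function(r) {
    keep <- nzchar(r)
    if (!any(keep)) return("")
    last <- max(which(keep))
    paste0(prefixes[seq_len(last)], r[seq_len(last)], collapse = "; ")
  })
  write_long_table(
    data.frame(`Feature ID` = taxonomy$feature_id, Taxon = taxon,
               check.names = FALSE), path)
}

#' Does a feature lack a phylum assignment?
#' @param taxonomy taxonomy data frame. @param feature_ids ids to query.
#' @return logical vector.
#' @export
phylum_unassigned <- function(taxonomy, feature_ids = taxonomy$feature_id) {
  i <- match(feature_ids, taxonomy$feature_id)
  out <- rep(TRUE, length(feature_ids)) # unknown features count as unassigned
  out[!is.na(i)] <- !nzchar(taxonomy$phylum[i[!is.na(i)]])
  out
}

#' Validate a rooted phylogeny
#' @param tree an `ape::phylo`.
#' @return the tree, invisibly validated.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape 'phylo' object")
  # every phylo has a unique basal node; a basal polytomy (e.g. a star
  # tree) is accepted and read as rooted at the hub, which is what the
  # phylogenetic metrics need
  if (anyDuplicated(tree$tip.label)) stopf("tree tip labels must be unique")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stopf("tree must have nonnegative branch lengths")
  tree
}

SAMPLE_COLS <- c("sample_id", "infant_id", "age_group", "age_days",
                 "collection_datetime", "sex", "melatonin_pg_per_g")

#' Read per-sample metadata
#'
#' Columns: sample_id, infant_id, age_group (2/4/6 months), age_days,
#' collection_datetime (ISO-8601), sex (female/male), melatonin_pg_per_g
#' (optional). Validates uniqueness, parseability and that age_days is
#' ordered consistently with age_group within each infant.
#' @param path file path.
#' @export
read_sample_metadata <- function(path) {
  df <- read_long_table(path)
  validate_sample_metadata(df, src = path)
}

validate_sample_metadata <- function(df, src = "metadata") {
  miss <- setdiff(SAMPLE_COLS[1:6], names(df))
  if (length(miss))
    stopf("parse error in %s: missing column(s) %s", src,
          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("integrity error in %s: duplicate sample id(s) %s", src,
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$age_group %in% AGE_GROUPS))
    stopf("integrity error in %s: age_group must be one of %s", src,
          paste(AGE_GROUPS, collapse = "/"))
  if (!all(df$sex %in% c("female", "male")))
    stopf("integrity error in %s: sex must be female/male", src)
  if (anyNA(df$age_days) || any(df$age_days <= 0))
    stopf("integrity error in %s: age_days must be positive", src)
  df$collection_datetime <- parse_datetime(df$collection_datetime)
  if (!"melatonin_pg_per_g" %in% names(df)) df$melatonin_pg_per_g <- NA_real_
  if (any(df$melatonin_pg_per_g < 0, na.rm = TRUE))
    stopf("integrity error in %s: melatonin must be nonnegative", src)
  # age_days must increase with age_group within infant
  for (id in unique(df$infant_id)) {
    sub <- df[df$infant_id == id, ]
    med <- tapply(sub$age_days, factor(sub$age_group, AGE_GROUPS), stats::median)
    med <- med[!is.na(med)]
    if (length(med) > 1 && any(diff(med) <= 0))
      stopf("integrity error in %s: age_days not increasing across age groups for infant %s",
            src, id)
  }
  df
}

QUEST_COLS <- c("infant_id", "age_group", "bisq_night_sleep_h",
                "bisq_latency_h", "bisq_bedtime_clock_h", "bisq_n_awakenings",
                "bcq_attunement", "asq_composite")

#' Read questionnaire records (BISQ variables, BCQ attunement, ASQ composite)
#' @param path file path.
#' @export
read_questionnaires <- function(path) {
  df <- read_long_table(path)
  miss <- setdiff(QUEST_COLS[1:2], names(df))
  if (length(miss)) stopf("parse error in %s: missing %s", path,
                          paste(miss, collapse = ", "))
  for (col in QUEST_COLS[-(1:2)]) if (!col %in% names(df)) df[[col]] <- NA_real_
  key <- paste(df$infant_id, df$age_group)
  if (anyDuplicated(key))
    stopf("integrity error in %s: more than one questionnaire record for %s",
          path, paste(unique(key[duplicated(key)]), collapse = ", "))
  df[, QUEST_COLS]
}

#' Read epoch-level actimetry (long format)
#'
#' Columns: infant_id, age_group, timestamp, activity, wear (0/1).
#' @param path file path.
#' @export
read_actimetry <- function(path) {
  df <- read_long_table(path)
  need <- c("infant_id", "age_group", "timestamp", "activity", "wear")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("parse error in %s: missing %s", path,
                          paste(miss, collapse = ", "))
  df$timestamp <- parse_datetime(df$timestamp)
  if (any(!is.finite(df$activity)) || any(df$activity < 0))
    stopf("integrity error in %s: activity must be finite and >= 0", path)
  df$wear <- as.logical(df$wear)
  df
}

#' Read the 15-minute sleep/wake diary
#'
#' Columns: infant_id, age_group, interval_start, state (sleep/wake).
#' Intervals are half-open `[start, start + 15 min)`.
#' @param path file path.
#' @export
read_diary <- function(path) {
  df <- read_long_table(path)
  need <- c("infant_id", "age_group", "interval_start", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("parse error in %s: missing %s", path,
                          paste(miss, collapse = ", "))
  if (!all(df$state %in% c("sleep", "wake")))
    stopf("integrity error in %s: state must be sleep/wake", path)
  df$interval_start <- parse_datetime(df$interval_start)
  df
}

#' Read feeding events
#'
#' Columns: infant_id, age_group, feed_time.
#' @param path file path.
#' @export
read_feedings <- function(path) {
  df <- read_long_table(path)
  need <- c("infant_id", "age_group", "feed_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("parse error in %s: missing %s", path,
                          paste(miss, collapse = ", "))
  df$feed_time <- parse_datetime(df$feed_time)
  df
}

#' Write any per-record result set as TSV
#'
#' Header + one row per record; missing values are empty fields; column
#' order is preserved; reals carry 15 significant digits so write/read
#' round-trips are exact for integers and <= 1e-12 relative for reals.
#' Datetime columns are serialized as ISO-8601.
#'
#' @param records data frame. @param path destination.
#' @export
write_long_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_datetime(df[[nm]])
    else if (is.numeric(df[[nm]])) df[[nm]] <- vapply(df[[nm]], function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE,
                                              trim = TRUE), "")
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("I/O error writing %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [write_long_table()]
#' @param path file path. @param ... passed to `read.delim`.
#' @export
read_long_table <- function(path, ...) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tryCatch(
    utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                      stringsAsFactors = FALSE, ...),
    error = function(e) stopf("parse error in %s: %s", path,
                              conditionMessage(e)))
}

#' Load a full cohort bundle from disk
#'
#' Reads every input the pipeline consumes and enforces cross-referential
#' integrity: duplicate ids fail, metadata samples missing from the feature
#' table are reported in `$unmatched_samples`, and features must all be
#' tree tips (required by the phylogenetic metrics).
#'
#' @param dir directory holding the standard file layout (see
#'   [write_cohort_bundle()]), or a named list of paths with elements
#'   `feature_table`, `taxonomy`, `tree`, `metadata`, `questionnaires`,
#'   `actimetry`, `diary`, `feedings`.
#' @return a list with elements `table`, `taxonomy`, `tree`, `metadata`,
#'   `questionnaires`, `actimetry`, `diary`, `feedings`,
#'   `unmatched_samples`.
#' @export
load_cohort_bundle <- function(dir) {
  paths <- if (is.list(dir)) dir else bundle_paths(dir)
  meta <- read_sample_metadata(paths$metadata)
  table <- read_feature_table(paths$feature_table, sample_ids = meta$sample_id)
  taxonomy <- read_taxonomy(paths$taxonomy)
  tree <- validate_tree(ape::read.tree(paths$tree))
  quest <- read_questionnaires(paths$questionnaires)
  actimetry <- read_actimetry(paths$actimetry)
  diary <- read_diary(paths$diary)
  feedings <- read_feedings(paths$feedings)

  unmatched <- setdiff(meta$sample_id, rownames(table))
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips))
    stopf("integrity error: feature id(s) not in tree: %s",
          paste(utils::head(missing_tips, 10), collapse = ", "))
  list(table = table, taxonomy = taxonomy, tree = tree, metadata = meta,
       questionnaires = quest, actimetry = actimetry, diary = diary,
       feedings = feedings, unmatched_samples = unmatched)
}

bundle_paths <- function(dir) {
  list(feature_table = file.path(dir, "feature_table.tsv"),
       taxonomy = file.path(dir, "taxonomy.tsv"),
       tree = file.path(dir, "tree.nwk"),
       metadata = file.path(dir, "metadata.tsv"),
       questionnaires = file.path(dir, "questionnaires.tsv"),
       actimetry = file.path(dir, "actimetry.tsv"),
       diary = file.path(dir, "diary.tsv"),
       feedings = file.path(dir, "feedings.tsv"))
}

#' Write a cohort bundle in the standard file layout
#' @param bundle list as returned by [load_cohort_bundle()] or
#'   [generate_cohort()]. @param dir destination directory (created).
#' @return the directory, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- bundle_paths(dir)
  write_feature_table(bundle$table, p$feature_table)
  write_taxonomy(bundle$taxonomy, p$taxonomy)
  ape::write.tree(bundle$tree, p$tree)
  write_long_table(bundle$metadata, p$metadata)
  write_long_table(bundle$questionnaires, p$questionnaires)
  write_long_table(bundle$actimetry, p$actimetry)
  write_long_table(bundle$diary, p$diary)
  write_long_table(bundle$feedings, p$feedings)
  if (!is.null(bundle$ground_truth))
    jsonlite::write_json(bundle$ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
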