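# Gut microbiota temporal volatility: per infant-age and beta metric, the
# median Euclidean distance of the group's samples to their centroid in a
# 3-axis PCoA embedding of the cohort distance matrix.

#' Temporal volatility from one beta-diversity matrix
#'
#' One PCoA is computed on the full cohort matrix (`scope = "cohort"`,
#' the default: a shared space makes volatilities comparable across
#' infants and avoids degenerate per-group embeddings for 2-3 samples;
#' `scope = "group"` re-embeds each group on its own for the alternative
#' reading). The centroid of each infant-age group with >= 2 samples is
#' the per-axis mean of its coordinates; volatility is the median
#' Euclidean distance of the group's points to that centroid. If fewer
#' than `n_axes` positive eigenvalues exist, all positive axes are used
#' and the count recorded.
#'
#' @param dm distance matrix (samples x samples) for one beta metric.
#' @param metadata sample metadata with sample_id, infant_id, age_group.
#' @param n_axes embedding dimension (default 3).
#' @param scope "cohort" (one shared embedding) or "group".
#' @return list(records = data.frame(infant_id, age_group, n_samples,
#'   volatility, n_axes_used), exclusions, scope).
#' @export
compute_volatility <- function(dm, metadata, n_axes = 3,
                               scope = c("cohort", "group")) {
  scope <- match.arg(scope)
  dm <- as.matrix(dm)
  if (nrow(metadata) == 0) stopf("empty metadata")
  meta <- metadata[metadata$sample_id %in% rownames(dm), ]
  unmatched <- setdiff(metadata$sample_id, rownames(dm))
  keys <- unique(meta[, c("infant_id", "age_group")])
  recs <- list(); excl <- list()

  emb <- NULL
  if (scope == "cohort") {
    ax <- min(n_axes, pcoa_n_positive(dm))
    emb <- pcoa_embed(dm, n_axes = ax)
  }
  for (k in seq_len(nrow(keys))) {
    sid <- meta$sample_id[meta$infant_id == keys$infant_id[k] &
                            meta$age_group == keys$age_group[k]]
    if (length(sid) < 2) {
      excl[[length(excl) + 1L]] <- data.frame(
        infant_id = keys$infant_id[k], age_group = keys$age_group[k],
        reason = sprintf("fewer than 2 samples (%d)", length(sid)))
      next
    }
    if (scope == "cohort") {
      pts <- emb$coordinates[sid, , drop = FALSE]
      ax_used <- ncol(pts)
    } else {
      sub_dm <- dm[sid, sid, drop = FALSE]
      ax_used <- min(n_axes, pcoa_n_positive(sub_dm))
      pts <- if (ax_used == 0) # all points coincide
        matrix(0, length(sid), 1) else
          pcoa_embed(sub_dm, n_axes = ax_used)$coordinates
    }
    centroid <- colMeans(pts)
    d <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
    recs[[length(recs) + 1L]] <- data.frame(
      infant_id = keys$infant_id[k], age_group = keys$age_group[k],
      n_samples = length(sid), volatility = stats::median(d),
      n_axes_used = ax_used, stringsAsFactors = FALSE)
  }
  empty_rec <- data.frame(infant_id = character(), age_group = integer(),
                          n_samples = integer(), volatility = double(),
                          n_axes_used = integer())
  empty_excl <- data.frame(infant_id = character(), age_group = integer(),
                           reason = character())
  list(records = if (length(recs)) do.call(rbind, recs) else empty_rec,
       exclusions = if (length(excl)) do.call(rbind, excl) else empty_excl,
       scope = scope, unmatched = unmatched)
}

#' Volatility records joined with age and sex, ready for modeling
#'
#' Adds each group's age_days (median over its samples) and sex; no
#' statistics are computed here (the association module owns the models).
#'
#' @param records volatility records (one beta metric), from
#'   [compute_volatility()].
#' @param metadata sample metadata.
#' @return data.frame(infant_id, age_group, age_days, sex, n_samples,
#'   volatility).
#' @export
volatility_vs_age_summary <- function(records, metadata) {
  out <- records
  out$age_days <- NA_real_; out$sex <- NA_character_
  for (i in seq_len(nrow(out))) {
    sub <- metadata[metadata$infant_id == out$infant_id[i] &
                      metadata$age_group == out$age_group[i], ]
    if (nrow(sub) == 0)
      stopf("integrity error: no metadata for infant %s age %s",
            out$infant_id[i], out$age_group[i])
    out$age_days[i] <- stats::median(sub$age_days)
    out$sex[i] <- sub$sex[1]
  }
  out[, c("infant_id", "age_group", "age_days", "sex", "n_samples",
          "volatility")]
}
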