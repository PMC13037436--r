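# Feature-table filtering, rarefaction-bootstrapped alpha/beta diversity,
# genus collapsing and principal coordinates analysis.
#
# Conventions (documented because implementations differ):
#   * Shannon entropy in bits (log base 2); Pielou = shannon / log2(observed),
#     undefined below 2 observed features.
#   * Faith PD includes the connection to the root.
#   * Weighted UniFrac is the non-normalized variant (normalized available
#     via a flag).
#   * Rarefaction is subsampling WITHOUT replacement to exactly `depth`;
#     per-sample sub-seeds are derived from (seed, sample_id, replicate) so
#     subsetting samples never perturbs other samples' draws.

#' Filter a feature table the way the upstream 16S workflow does
#'
#' Order of operations: (1) drop features with no phylum assignment,
#' (2) drop features whose total count across all samples is below
#' `min_feature_total`, (3) drop samples whose remaining depth is below
#' `min_depth`. The exclusion report lists every dropped id with its reason.
#'
#' @param table counts matrix (samples x features).
#' @param taxonomy taxonomy data frame ([read_taxonomy()]).
#' @param min_feature_total features below this total are discarded
#'   (default 10, i.e. a total of 9 is dropped and 10 kept).
#' @param min_depth minimum retained sample depth (default 3035).
#' @return list(table, exclusions = data.frame(id, kind, reason)).
#' @export
filter_table <- function(table, taxonomy, min_feature_total = 10,
                         min_depth = 3035) {
  table <- feature_table(table)
  excl <- list()
  no_phylum <- colnames(table)[phylum_unassigned(taxonomy, colnames(table))]
  if (length(no_phylum)) {
    excl[[length(excl) + 1L]] <- data.frame(
      id = no_phylum, kind = "feature", reason = "phylum unassigned")
    table <- table[, setdiff(colnames(table), no_phylum), drop = FALSE]
  }
  totals <- colSums(table)
  low <- colnames(table)[totals < min_feature_total]
  if (length(low)) {
    excl[[length(excl) + 1L]] <- data.frame(
      id = low, kind = "feature",
      reason = sprintf("total frequency < %d", min_feature_total))
    table <- table[, setdiff(colnames(table), low), drop = FALSE]
  }
  depths <- rowSums(table)
  shallow <- rownames(table)[depths < min_depth]
  if (length(shallow)) {
    excl[[length(excl) + 1L]] <- data.frame(
      id = shallow, kind = "sample",
      reason = sprintf("depth < %d after feature filters", min_depth))
    table <- table[setdiff(rownames(table), shallow), , drop = FALSE]
  }
  if (nrow(table) == 0) stopf("no samples retained after filtering")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), kind = character(), reason = character())
  list(table = table, exclusions = exclusions)
}

# ---- phylogeny indexing ---------------------------------------------------

# Edge-by-tip incidence of a rooted tree: M[e, t] = 1 iff tip t descends
# from edge e. Shared by Faith PD and both UniFrac variants.
tree_index <- function(tree, feature_ids) {
  validate_tree(tree)
  missing <- setdiff(feature_ids, tree$tip.label)
  if (length(missing))
    stopf("feature id(s) absent from tree: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  nt <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  nnode <- nt + tree$Nnode
  # accumulate descendant tip sets bottom-up
  desc <- vector("list", nnode)
  for (t in seq_len(nt)) desc[[t]] <- t
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; chi <- post$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  ne <- nrow(tree$edge)
  ii <- integer(0); jj <- integer(0)
  for (e in seq_len(ne)) {
    tips <- desc[[tree$edge[e, 2]]]
    ii <- c(ii, rep.int(e, length(tips))); jj <- c(jj, tips)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(ne, nt))
  colnames(M) <- tree$tip.label
  list(incidence = M[, feature_ids, drop = FALSE],
       lengths = tree$edge.length)
}

# branch_counts: edges x samples matrix of counts descending from each edge
branch_counts <- function(idx, counts) {
  as.matrix(idx$incidence %*% t(counts))
}

# ---- alpha kernels --------------------------------------------------------

#' Alpha diversity kernels for a block of samples
#'
#' observed = number of nonzero features; shannon = -sum p log2 p (bits);
#' pielou = shannon / log2(observed), missing when observed < 2;
#' faith_pd = total branch length of the minimal root-connected subtree
#' spanning the observed tips. All-zero samples get all metrics missing.
#'
#' @param counts counts matrix (samples x features) or a single vector.
#' @param tree rooted phylogeny covering all features (only needed for
#'   faith_pd; pass NULL to skip it).
#' @param idx precomputed [tree_index()] (internal fast path).
#' @return data.frame(sample_id, observed_features, shannon, pielou,
#'   faith_pd).
#' @export
alpha_diversity <- function(counts, tree = NULL, idx = NULL) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, 1, dimnames = list("sample", names(counts)))
  depths <- rowSums(counts)
  obs <- rowSums(counts > 0)
  p <- counts / ifelse(depths > 0, depths, NA)
  pl <- p * log2(p)
  pl[counts == 0] <- 0
  shannon <- -rowSums(pl)
  pielou <- ifelse(obs >= 2, shannon / log2(obs), NA_real_)
  faith <- rep(NA_real_, nrow(counts))
  if (!is.null(tree) || !is.null(idx)) {
    if (is.null(idx)) idx <- tree_index(tree, colnames(counts))
    pres <- branch_counts(idx, counts) > 0
    faith <- as.numeric(crossprod(pres, idx$lengths))
  }
  empty <- depths == 0
  out <- data.frame(sample_id = rownames(counts),
                    observed_features = ifelse(empty, NA_real_, obs),
                    shannon = ifelse(empty, NA_real_, shannon),
                    pielou = pielou,
                    faith_pd = ifelse(empty, NA_real_, faith),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- rarefaction ----------------------------------------------------------

# Subsample one count vector without replacement to exactly `depth`
# (multivariate hypergeometric draw realized by index sampling).
rarefy_vector <- function(x, depth) {
  total <- sum(x)
  if (total < depth) stopf("sample depth %d below rarefaction depth %d",
                           total, depth)
  if (total == depth) return(x)
  picks <- sample.int(total, depth)
  tabulate(findInterval(picks - 1, cumsum(x)) + 1L, nbins = length(x))
}

#' Rarefy every sample of a table to a fixed depth
#'
#' @param table counts matrix (samples x features), all depths >= `depth`.
#' @param depth target depth.
#' @param seed master seed; each sample uses a sub-seed derived from
#'   (seed, sample_id, replicate).
#' @param replicate bootstrap replicate index entering the sub-seed.
#' @return counts matrix with every row summing to exactly `depth`.
#' @export
rarefy_table <- function(table, depth, seed, replicate = 1L) {
  out <- table
  for (s in rownames(table)) {
    sub <- derive_seed(seed, "rarefy", s, replicate)
    out[s, ] <- with_seed(sub, rarefy_vector(table[s, ], depth))
  }
  out
}

#' Bootstrap-averaged rarefied alpha diversity
#'
#' Each of `n_boot` replicates independently rarefies every sample to
#' `depth` and computes all four alpha metrics; the arithmetic mean across
#' replicates is reported per sample. Deterministic under `seed`.
#'
#' @inheritParams rarefy_table
#' @param tree rooted phylogeny covering the features.
#' @param n_boot number of rarefaction replicates (default 100).
#' @return long data.frame(sample_id, metric, value).
#' @export
bootstrapped_alpha <- function(table, tree, depth = 3035, n_boot = 100,
                               seed = 1L) {
  if (any(rowSums(table) < depth))
    stopf("sample(s) below rarefaction depth %d: %s", depth,
          paste(rownames(table)[rowSums(table) < depth], collapse = ", "))
  idx <- tree_index(tree, colnames(table))
  acc <- NULL
  for (b in seq_len(n_boot)) {
    r <- rarefy_table(table, depth, seed, replicate = b)
    a <- alpha_diversity(r, idx = idx)
    m <- as.matrix(a[, ALPHA_METRICS])
    acc <- if (is.null(acc)) m else acc + m
  }
  acc <- acc / n_boot
  out <- data.frame(sample_id = rep(rownames(table), times = length(ALPHA_METRICS)),
                    metric = rep(ALPHA_METRICS, each = nrow(table)),
                    value = as.vector(acc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- beta kernels ---------------------------------------------------------

#' All four beta diversity matrices for one counts matrix
#'
#' bray_curtis = sum|u-v| / sum(u+v) on counts; jaccard = 1 - |shared
#' presences| / |union presences|; unweighted_unifrac = unshared branch
#' length / total branch length over branches leading to tips present in
#' the union; weighted_unifrac = sum_b l_b |p_b(u) - p_b(v)| on relative
#' abundances (non-normalized; `normalized = TRUE` divides by
#' sum_b l_b (p_b(u) + p_b(v))).
#'
#' @param counts counts matrix (samples x features).
#' @param tree rooted phylogeny covering the features.
#' @param normalized use the normalized weighted UniFrac variant.
#' @param idx precomputed [tree_index()].
#' @return named list of symmetric zero-diagonal matrices, one per metric.
#' @export
beta_diversity <- function(counts, tree = NULL, normalized = FALSE,
                           idx = NULL) {
  sid <- rownames(counts)
  out <- list()
  out$bray_curtis <- as.matrix(vegan::vegdist(counts, method = "bray"))
  out$jaccard <- as.matrix(vegan::vegdist(counts > 0, method = "jaccard",
                                          binary = TRUE))
  if (is.null(idx) && !is.null(tree)) idx <- tree_index(tree, colnames(counts))
  if (!is.null(idx)) {
    B <- branch_counts(idx, counts)           # edges x samples
    l <- idx$lengths
    A <- B > 0
    lA <- l * A
    shared <- crossprod(A, lA)                # sum l over branches in both
    per <- colSums(lA)
    union <- outer(per, per, "+") - shared
    uw <- (union - shared) / union
    uw[union == 0] <- NA_real_
    diag(uw) <- 0
    out$unweighted_unifrac <- uw
    depths <- rowSums(counts)
    P <- sweep(B, 2, ifelse(depths > 0, depths, NA), "/")
    W <- as.matrix(stats::dist(t(l * P), method = "manhattan"))
    if (normalized) {
      tot <- colSums(l * P)
      W <- W / outer(tot, tot, "+")
    }
    diag(W) <- 0
    out$weighted_unifrac <- W
  }
  for (nm in names(out)) dimnames(out[[nm]]) <- list(sid, sid)
  out
}

#' Pairwise beta diversity kernels for two count vectors
#' @param u,v count vectors over the same features.
#' @param tree rooted phylogeny (tips cover the features).
#' @return named numeric vector over the four metrics.
#' @export
beta_kernels <- function(u, v, tree = NULL) {
  feats <- names(u) %||% paste0("f", seq_along(u))
  m <- rbind(u = u, v = v)
  colnames(m) <- feats
  if (sum(u) == 0 && sum(v) == 0)
    return(c(bray_curtis = NA_real_, jaccard = NA_real_,
             unweighted_unifrac = NA_real_, weighted_unifrac = NA_real_))
  d <- beta_diversity(m, tree)
  vapply(d, function(x) x["u", "v"], 0)
}

#' Bootstrap-averaged rarefied beta diversity
#'
#' Element-wise mean of `n_boot` distance matrices, each computed on an
#' independent rarefaction of all samples; symmetry and the zero diagonal
#' are preserved exactly.
#'
#' @inheritParams bootstrapped_alpha
#' @param normalized normalized weighted UniFrac flag.
#' @return named list of averaged distance matrices, one per metric.
#' @export
bootstrapped_beta <- function(table, tree, depth = 3035, n_boot = 100,
                              seed = 1L, normalized = FALSE) {
  if (any(rowSums(table) < depth))
    stopf("sample(s) below rarefaction depth %d: %s", depth,
          paste(rownames(table)[rowSums(table) < depth], collapse = ", "))
  idx <- tree_index(tree, colnames(table))
  acc <- NULL
  for (b in seq_len(n_boot)) {
    r <- rarefy_table(table, depth, seed, replicate = b)
    d <- beta_diversity(r, idx = idx, normalized = normalized)
    acc <- if (is.null(acc)) d else Map(`+`, acc, d)
  }
  lapply(acc, function(m) {
    m <- m / n_boot
    m <- (m + t(m)) / 2  # guard numeric symmetry
    diag(m) <- 0
    m
  })
}

# ---- genus collapsing -----------------------------------------------------

#' Collapse ASV counts to genus-level relative abundances
#'
#' Counts are summed by genus label; ASVs without a genus are grouped under
#' their finest resolved rank prefixed `unclassified_`. Per-sample relative
#' abundances sum to 1. Also returns the top-k genera by mean relative
#' abundance across samples.
#'
#' @param table counts matrix (samples x features), typically post-filter.
#' @param taxonomy taxonomy data frame.
#' @param top_k how many leading genera to report (default 5).
#' @return list(rel_abundance = samples x genera matrix, top_genera).
#' @export
collapse_to_genus <- function(table, taxonomy, top_k = 5) {
  if (nrow(taxonomy) == 0) stopf("empty taxonomy")
  i <- match(colnames(table), taxonomy$feature_id)
  if (anyNA(i))
    stopf("taxonomy missing feature(s): %s",
          paste(utils::head(colnames(table)[is.na(i)], 10), collapse = ", "))
  labels <- vapply(i, function(k) {
    g <- taxonomy$genus[k]
    if (nzchar(g)) return(g)
    ranks <- unlist(taxonomy[k, TAXON_RANKS])
    finest <- ranks[max(c(0, which(nzchar(ranks))))]
    if (length(finest) && nzchar(finest))
      paste0("unclassified_", finest) else "unclassified_unknown"
  }, "")
  agg <- t(rowsum(t(table), labels))            # samples x genera
  depths <- rowSums(agg)
  rel <- agg / ifelse(depths > 0, depths, NA)
  top <- names(sort(colMeans(rel, na.rm = TRUE), decreasing = TRUE))
  top <- setdiff(top, grep("^unclassified_", top, value = TRUE))
  list(rel_abundance = rel, top_genera = utils::head(top, top_k))
}

# ---- principal coordinates ------------------------------------------------

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of -D^2/2 followed by a symmetric
#' eigendecomposition; coordinates are eigenvector * sqrt(eigenvalue) for
#' the `n_axes` largest positive eigenvalues. No correction is applied for
#' negative eigenvalues (they are simply not retained). Sign convention:
#' each axis is flipped so its largest-magnitude coordinate is positive.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to retain (default 3); errors if fewer
#'   positive eigenvalues exist.
#' @return list(coordinates = samples x n_axes, eigenvalues,
#'   n_positive).
#' @export
pcoa_embed <- function(dm, n_axes = 3) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < n_axes + 1) stopf("PCoA needs >= %d samples, got %d", n_axes + 1, n)
  D2 <- dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  if (length(pos) < n_axes)
    stopf("only %d positive eigenvalue(s), need %d", length(pos), n_axes)
  if (n_axes == 0) {
    # degenerate embedding (all points coincide): zero-dimensional space
    coords <- matrix(0, n, 0, dimnames = list(rownames(dm), NULL))
    return(list(coordinates = coords, eigenvalues = numeric(0),
                n_positive = length(pos)))
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), n_axes)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  list(coordinates = coords, eigenvalues = e$values[keep],
       n_positive = length(pos))
}

# Number of positive PCoA eigenvalues (used by volatility to degrade
# gracefully on tiny cohorts).
pcoa_n_positive <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(e > max(abs(e)) * 1e-8)
}
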