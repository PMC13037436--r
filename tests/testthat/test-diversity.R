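# Filters, alpha/beta kernels, rarefaction bootstrap, genus collapse, PCoA.

make_table <- function(m) feature_table(m)

test_that("filter order and boundaries follow the protocol", {
  # features: f_low total 9 (dropped), f_ok total 10 (kept), f_big kept,
  # f_nophy dropped for missing phylum regardless of abundance
  m <- rbind(s1 = c(f_low = 4, f_ok = 5, f_big = 3030, f_nophy = 3000),
             s2 = c(5, 5, 3200, 10))
  tax <- data.frame(feature_id = c("f_low", "f_ok", "f_big", "f_nophy"),
                    domain = "Bacteria",
                    phylum = c("Firmicutes", "Firmicutes", "Firmicutes", ""),
                    class = "", order = "", family = "",
                    genus = c("g1", "g1", "g2", ""))
  res <- filter_table(make_table(m), tax, min_feature_total = 10,
                      min_depth = 3035)
  expect_setequal(colnames(res$table), c("f_ok", "f_big"))
  # s1 post-filter depth = 5 + 3030 = 3035 retained;
  # s2 = 5 + 3200 = 3205 retained
  expect_setequal(rownames(res$table), c("s1", "s2"))
  expect_setequal(res$exclusions$id[res$exclusions$kind == "feature"],
                  c("f_low", "f_nophy"))
  expect_match(res$exclusions$reason[res$exclusions$id == "f_nophy"],
               "phylum")
  # push s1 just under the depth boundary: 3034 -> dropped
  m2 <- m; m2["s1", "f_big"] <- 3029
  res2 <- filter_table(make_table(m2), tax)
  expect_identical(rownames(res2$table), "s2")
  expect_match(res2$exclusions$reason[res2$exclusions$id == "s1"],
               "depth < 3035")
  expect_error(filter_table(make_table(m), tax, min_depth = 1e7),
               "no samples retained")
})

test_that("planted low-frequency features land in the exclusion report", {
  cfg <- tiny_cohort_config()
  ft <- simulate_feature_table(cfg, seed = 13)
  res <- filter_table(ft$table, ft$taxonomy)
  planted <- ft$ground_truth$rare_features
  dropped_low <- res$exclusions$id[grepl("frequency", res$exclusions$reason)]
  dropped_any <- res$exclusions$id[res$exclusions$kind == "feature"]
  # every planted rare feature is excluded; those with a phylum must be
  # excluded specifically by the frequency rule
  expect_true(all(planted %in% dropped_any))
  with_phylum <- setdiff(planted, ft$ground_truth$phylum_unassigned_features)
  expect_true(all(with_phylum %in% dropped_low))
})

test_that("alpha kernels match their closed forms", {
  u16 <- matrix(rep(3, 16), 1, dimnames = list("u", paste0("f", 1:16)))
  a <- alpha_diversity(u16)
  expect_identical(a$observed_features, 16)
  expect_close(a$shannon, 4, 1e-12)
  expect_close(a$pielou, 1, 1e-12)

  m <- matrix(c(2, 1, 1), 1, dimnames = list("s", c("a", "b", "c")))
  expect_close(alpha_diversity(m)$shannon, 1.5, 1e-12)

  tr <- worked_tree()
  cnt <- rbind(sA = c(A = 1, B = 0, C = 0, D = 0),
               sAB = c(1, 1, 0, 0), sAC = c(1, 0, 1, 0))
  expect_equal(alpha_diversity(cnt, tree = tr)$faith_pd, c(2, 3, 4))

  z <- matrix(0, 1, 4, dimnames = list("z", c("A", "B", "C", "D")))
  az <- alpha_diversity(z, tree = worked_tree())
  expect_true(all(is.na(az[, -1])))
  # single-feature sample: pielou undefined
  one <- matrix(c(5, 0), 1, dimnames = list("o", c("a", "b")))
  expect_true(is.na(alpha_diversity(one)$pielou))
})

test_that("shannon/pielou/faith invariants hold on random tables", {
  set.seed(42)
  tr <- ape::rcoal(12, tip.label = paste0("t", 1:12))
  idx_feats <- tr$tip.label
  for (i in 1:20) {
    x <- rpois(12, lambda = sample(1:20, 1))
    names(x) <- idx_feats
    if (sum(x) == 0) next
    m <- matrix(x, 1, dimnames = list("s", idx_feats))
    a <- alpha_diversity(m, tree = tr)
    if (a$observed_features >= 1)
      expect_lte(a$shannon, log2(max(a$observed_features, 1)) + 1e-12)
    # faith monotone under adding an observed tip
    absent <- idx_feats[x == 0]
    if (length(absent)) {
      x2 <- x; x2[absent[1]] <- 1
      m2 <- matrix(x2, 1, dimnames = list("s", idx_feats))
      expect_gte(alpha_diversity(m2, tree = tr)$faith_pd, a$faith_pd)
    }
  }
  # equality iff uniform
  u <- matrix(rep(7, 8), 1, dimnames = list("s", paste0("t", 1:8)))
  au <- alpha_diversity(u)
  expect_close(au$shannon, log2(8), 1e-12)
})

test_that("rarefaction hits the depth exactly and is seed-stable", {
  set.seed(1)
  m <- matrix(rpois(40, 400), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  m <- feature_table(m)
  r <- rarefy_table(m, 1000, seed = 5)
  expect_true(all(rowSums(r) == 1000))
  expect_true(all(r <= m))
  expect_identical(rarefy_table(m, 1000, seed = 5), r)
  # per-sample sub-seeds: dropping a sample leaves the others' draws alone
  r_sub <- rarefy_table(m[-1, ], 1000, seed = 5)
  expect_identical(r_sub, r[-1, ])
  expect_error(rarefy_table(m, 10^7, seed = 5), "below rarefaction depth")
})

test_that("bootstrap alpha behaves at the no-variability boundary", {
  tr <- worked_tree()
  # depth equals sample total -> every replicate identical to single shot
  m <- matrix(c(10, 20, 30, 40), 1, dimnames = list("s", c("A", "B", "C", "D")))
  ba <- bootstrapped_alpha(feature_table(m), tr, depth = 100, n_boot = 5,
                           seed = 3)
  single <- alpha_diversity(m, tree = tr)
  for (met in ALPHA_METRICS)
    expect_identical(ba$value[ba$metric == met],
                     unname(unlist(single[met])))
  # fixed seed reproducibility
  m2 <- matrix(rpois(8, 500) + 200, 2, 4,
               dimnames = list(c("x", "y"), c("A", "B", "C", "D")))
  b1 <- bootstrapped_alpha(feature_table(m2), tr, depth = 300, n_boot = 10,
                           seed = 9)
  b2 <- bootstrapped_alpha(feature_table(m2), tr, depth = 300, n_boot = 10,
                           seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrapped_alpha(feature_table(m2), tr, depth = 1e6,
                                  n_boot = 2, seed = 1),
               "below rarefaction depth")
})

test_that("n_boot = 1 agrees with n_boot = 100 within Monte-Carlo error", {
  tr <- ape::rcoal(10, tip.label = paste0("f", 1:10))
  set.seed(8)
  m <- matrix(rpois(10, 800), 1, dimnames = list("s", paste0("f", 1:10)))
  m <- feature_table(m)
  b100 <- bootstrapped_alpha(m, tr, depth = 2000, n_boot = 100, seed = 1)
  b1 <- bootstrapped_alpha(m, tr, depth = 2000, n_boot = 1, seed = 2)
  # replicate SE from a reference set of independent rarefactions
  reps <- vapply(1:50, function(b) {
    r <- rarefy_table(m, 2000, seed = 100 + b)
    alpha_diversity(r, tree = tr)$shannon
  }, 0)
  se <- stats::sd(reps)
  expect_lt(abs(b1$value[b1$metric == "shannon"] -
                  b100$value[b100$metric == "shannon"]), 3 * se + 1e-9)
})

test_that("beta kernels match closed forms and bounds", {
  expect_close(beta_kernels(c(a = 6, b = 2), c(a = 2, b = 2))["bray_curtis"],
               1 / 3, 1e-12)
  st <- star_tree()
  ks <- beta_kernels(c(A = 1, B = 1, C = 0, D = 0),
                     c(A = 0, B = 0, C = 1, D = 1), tree = st)
  expect_close(ks["unweighted_unifrac"], 1, 1e-12)
  expect_close(ks["jaccard"], 1, 1e-12)
  same <- beta_kernels(c(A = 3, B = 1, C = 2, D = 0),
                       c(A = 3, B = 1, C = 2, D = 0), tree = st)
  expect_close(same, rep(0, 4), 1e-12)
  # weighted UniFrac hand computation on the worked tree:
  # u = (A=2), v = (B=2) as proportions 1 on sibling unit branches -> 2
  wu <- beta_kernels(c(A = 2, B = 0, C = 0, D = 0),
                     c(A = 0, B = 2, C = 0, D = 0), tree = worked_tree())
  expect_close(wu["weighted_unifrac"], 2, 1e-12)
  # both empty -> missing
  expect_true(all(is.na(beta_kernels(c(A = 0, B = 0), c(A = 0, B = 0)))))
})

test_that("beta matrices are symmetric, zero-diagonal and bounded", {
  set.seed(14)
  tr <- ape::rcoal(8, tip.label = paste0("f", 1:8))
  m <- matrix(rpois(40, 30), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:8)))
  d <- beta_diversity(feature_table(m), tr)
  for (nm in names(d)) {
    expect_close(d[[nm]], t(d[[nm]]), 1e-12)
    expect_close(diag(d[[nm]]), rep(0, 5), 1e-12)
  }
  for (nm in c("bray_curtis", "jaccard", "unweighted_unifrac"))
    expect_true(all(d[[nm]] >= -1e-12 & d[[nm]] <= 1 + 1e-12))
})

test_that("bootstrapped beta is reproducible and controls duplicates", {
  set.seed(4)
  tr <- ape::rcoal(10, tip.label = paste0("f", 1:10))
  base <- rpois(10, 600) + 50
  m <- rbind(orig = base, dup = base,
             other = rpois(10, 500) + 50)
  colnames(m) <- paste0("f", 1:10)
  m <- feature_table(m)
  bb1 <- bootstrapped_beta(m, tr, depth = 2000, n_boot = 20, seed = 6)
  bb2 <- bootstrapped_beta(m, tr, depth = 2000, n_boot = 20, seed = 6)
  expect_identical(bb1, bb2)
  for (nm in names(bb1))
    expect_close(bb1[[nm]], t(bb1[[nm]]), 1e-12)
  # duplicate-sample control: averaged distance between identical count
  # vectors stays within same-sample rarefaction noise (99th percentile)
  null_draws <- vapply(1:40, function(b) {
    r1 <- with_seed_draw(m["orig", ], 2000, 1000 + b)
    r2 <- with_seed_draw(m["orig", ], 2000, 2000 + b)
    sum(abs(r1 - r2)) / sum(r1 + r2)
  }, 0)
  expect_lte(bb1$bray_curtis["orig", "dup"],
             stats::quantile(null_draws, 0.99) + 1e-9)
})

test_that("genus collapse normalizes and ranks correctly", {
  m <- rbind(s = c(a1 = 3, a2 = 7, b1 = 10))
  tax <- data.frame(feature_id = c("a1", "a2", "b1"), domain = "Bacteria",
                    phylum = "Firmicutes", class = "", order = "",
                    family = c("", "", "Lachnospiraceae"),
                    genus = c("GenusA", "GenusA", ""))
  g <- collapse_to_genus(feature_table(m), tax)
  expect_close(g$rel_abundance["s", "GenusA"], 0.5, 1e-12)
  expect_true("unclassified_Lachnospiraceae" %in% colnames(g$rel_abundance))
  expect_close(rowSums(g$rel_abundance), 1, 1e-12)
  expect_error(collapse_to_genus(feature_table(m), tax[0, ]), "empty taxonomy")
  # planted dominants surface as the top-5
  ft <- simulate_feature_table(tiny_cohort_config(), seed = 17)
  filt <- filter_table(ft$table, ft$taxonomy)
  gg <- collapse_to_genus(filt$table, ft$taxonomy, top_k = 5)
  expect_setequal(gg$top_genera, ft$ground_truth$top_genera)
})

test_that("pcoa reproduces geometry and fixes signs deterministically", {
  # 2-point closed form
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa_embed(d, n_axes = 1)
  expect_close(sort(p$coordinates[, 1]), c(-1.5, 1.5), 1e-12)
  # Euclidean distances of known 3-D points are reproduced
  set.seed(10)
  pts <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  dm <- as.matrix(dist(pts))
  emb <- pcoa_embed(dm, n_axes = 3)
  expect_close(as.matrix(dist(emb$coordinates)), dm, 1e-9)
  # agreement with an independent dense-solve oracle
  expect_close(as.matrix(dist(emb$coordinates)), oracle_pcoa_dists(dm), 1e-8)
  # permutation invariance of the geometry
  perm <- sample(10)
  emb2 <- pcoa_embed(dm[perm, perm], n_axes = 3)
  expect_close(as.matrix(dist(emb2$coordinates))[rownames(dm), rownames(dm)],
               dm, 1e-9)
  # not enough positive eigenvalues -> named error (3 collinear points
  # have exactly one positive axis)
  line <- matrix(c(0, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  line[, 1] <- c(0, 1, 2)
  dml <- as.matrix(dist(line))
  expect_error(pcoa_embed(dml, n_axes = 2), "positive eigenvalue")
})
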