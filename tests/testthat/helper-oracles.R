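# Independent brute-force oracles and small fixture builders.
# Oracles deliberately re-derive each quantity from its definition rather
# than calling the package's own code paths.

# --- cosinor: direct normal-equations solve ------------------------------
oracle_cosinor <- function(t, y, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% beta)
  list(mesor = beta[1], a = beta[2], b = beta[3],
       amplitude = sqrt(beta[2]^2 + beta[3]^2),
       r_squared = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2))
}

# --- nonparametric circadian metrics: double-loop formulas ----------------
oracle_is <- function(x, p = 24) {
  n <- length(x); d <- n / p
  xbar <- mean(x)
  num <- 0
  for (h in seq_len(p)) {
    xh <- mean(x[seq(h, n, by = p)])
    num <- num + (xh - xbar)^2
  }
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  n * num / (p * den)
}

oracle_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  xbar <- mean(x)
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  n * num / ((n - 1) * den)
}

oracle_ra <- function(x, p = 24) {
  prof <- numeric(p)
  for (h in seq_len(p)) prof[h] <- mean(x[seq(h, length(x), by = p)])
  wmean <- function(s, width)
    mean(prof[((s - 1 + 0:(width - 1)) %% p) + 1])
  m10 <- max(vapply(1:p, wmean, 0, width = 10))
  l5 <- min(vapply(1:p, wmean, 0, width = 5))
  if (m10 + l5 == 0) 0 else (m10 - l5) / (m10 + l5)
}

# --- PCoA via an independent route (stats::cmdscale) ----------------------
oracle_pcoa_dists <- function(dm, k = 3) {
  co <- stats::cmdscale(stats::as.dist(dm), k = k)
  as.matrix(stats::dist(co))
}

# --- worked trees ---------------------------------------------------------
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
star_tree <- function() ape::read.tree(text = "(A:1,B:1,C:1,D:1);")

# --- scaled-down synthetic cohort for fast unit tests ---------------------
# (full-size defaults are exercised by the acceptance suite)
tiny_cohort_config <- function() {
  cfg <- default_cohort_config()
  cfg$n_infants <- 6
  cfg$library_size <- list(meanlog = log(4500), sdlog = 0.1, min = 3500)
  cfg$activity$days_mean <- 4
  cfg$activity$days_sd <- 1
  cfg$n_emerging_features <- 15
  cfg$n_rare_features <- 5
  cfg
}

# random regular-minute activity series spanning whole days
random_hourly_series <- function(days = 4, seed = 1) {
  set.seed(seed)
  abs(stats::rnorm(days * 24, 10, 4))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

# independent rarefaction draw used by the duplicate-control null
with_seed_draw <- function(x, depth, seed) {
  set.seed(seed)
  total <- sum(x)
  picks <- sample.int(total, depth)
  tabulate(findInterval(picks - 1, cumsum(x)) + 1L, nbins = length(x))
}
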