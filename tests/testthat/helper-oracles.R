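# Independent oracles and fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up from its definition:
# p_adj(i) = min over ranks j >= rank(i) of p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Spearman by definition: mid-rank each column, then Pearson.
spearman_bruteforce <- function(Y) {
  R <- apply(as.matrix(Y), 2, rank)
  stats::cor(R)
}

# OLS residuals through the explicit normal equations.
resid_bruteforce <- function(Y, X) {
  B <- solve(t(X) %*% X, t(X) %*% as.matrix(Y))
  as.matrix(Y) - X %*% B
}

# Adjusted Rand index between two label vectors (contingency form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  isTRUE(all.equal(ari(a, b), 1))
}

# Small default simulation shared by several tests.
small_sim <- function(n = 300, seed = 1, ...) {
  simulate_cohort(sim_config(n = n, seed = seed, ...))
}

# A cohort whose only possible exclusions are the planted missing-exposure
# rows: exact parity counts plus extra participants with missing parity, and
# any naturally occurring |z| > threshold metric outlier shrunk back towards
# the mean (fixture construction of the "no MRI outliers" condition; the
# exclusion logic itself is tested with planted outliers elsewhere).
clean_bookkeeping_sim <- function(parity_counts, n_missing, seed = 1,
                                  sd_threshold = 4) {
  n <- sum(parity_counts) + n_missing
  sim <- simulate_cohort(sim_config(n = n, seed = seed,
                                    parity_counts = parity_counts))
  margin <- sd_threshold - 0.2

  # hemisphere quality scores: shrink participants extreme on the average
  qc <- (sim$cohort$qc_score_lh + sim$cohort$qc_score_rh) / 2
  bad <- abs(qc - mean(qc)) > margin * sd(qc)
  for (v in c("qc_score_lh", "qc_score_rh")) {
    sim$cohort[[v]][bad] <- mean(sim$cohort[[v]]) +
      0.3 * (sim$cohort[[v]][bad] - mean(sim$cohort[[v]]))
  }

  # compartment-mean volumes: shrink extreme rows towards the column means
  meta <- dk_regions()
  for (comp in c("cortical", "subcortical")) {
    cols <- intersect(names(sim$features),
                      meta$region[meta$compartment == comp])
    gm <- rowMeans(sim$features[, cols])
    bad <- which(abs(gm - mean(gm)) > margin * sd(gm))
    mid <- colMeans(sim$features[, cols])
    for (i in bad) {
      sim$features[i, cols] <- mid + 0.3 * (sim$features[i, cols] - mid)
    }
  }
  sim
}
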