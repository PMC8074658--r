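# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (double loops, full
# enumeration) so they share no code with the implementation paths.

# plug-in mutual information by direct summation over cells, in bits
oracle_mi <- function(m) {
  n <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  I <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      p <- m[i, j] / n
      if (p > 0) I <- I + p * log2(p / ((rs[i] / n) * (cs[j] / n)))
    }
  }
  max(I, 0)
}

# uncorrected Pearson chi-squared by direct summation (no row dropping)
oracle_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(ifelse(E > 0, (m - E)^2 / E, 0))
}

# empirical power by explicit sort-and-count
oracle_power <- function(dep, null, level = 0.05) {
  thr <- sort(null)[ceiling((1 - level) * length(null))]
  sum(dep > thr) / length(dep)
}

# Rand index by looping over all unordered sample pairs
oracle_rand <- function(a, b) {
  M <- length(a)
  agree <- 0
  for (i in 1:(M - 1)) {
    for (j in (i + 1):M) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / choose(M, 2)
}

# a random pair with optional ties, for property loops
random_pair <- function(n, tie_prob = 0) {
  x <- runif(n)
  y <- runif(n)
  if (tie_prob > 0) {
    x <- ifelse(runif(n) < tie_prob, round(x, 1), x)
    y <- ifelse(runif(n) < tie_prob, round(y, 1), y)
  }
  mic_pair(x, y)
}

# two unequal clusters with cluster-linked x structure: the equipartition of
# the y-axis misses the cluster boundary, the back-search can recover it
fig8_config <- function(n = 60, frac = 0.3) {
  n2 <- round(n * frac)
  n1 <- n - n2
  x <- c(runif(n1, 0, 0.5), runif(n2, 0.5, 1))
  y <- c(runif(n1, 0, 1), runif(n2, 2, 3))
  mic_pair(x, y)
}
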