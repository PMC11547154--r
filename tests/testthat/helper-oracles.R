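# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (mirrors the conventional two-sided doubling rule, capped at 1).
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

perm_mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Spearman rs as explicit Pearson product-moment on midranks.
ranks_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Global Needleman-Wunsch score of two strings (linear gaps), plain R.
nw_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- (0:m) * gap
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i * gap
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

# Local alignment score as the maximum Needleman-Wunsch score over all
# substring pairs (0 for the empty alignment). Independent of the DP-with-
# reset formulation used by the implementation.
sw_substring_oracle <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, nw_score(sa, substr(b, j1, j2),
                                 match, mismatch, gap))
    }
  }
  best
}

# Exhaustive recursion over all gapped local alignments (tiny inputs only).
sw_recursive_oracle <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  # score of best alignment path starting exactly at (i, j)
  from <- function(i, j) {
    if (i > length(av) || j > length(bv)) return(0)
    s <- if (av[i] == bv[j]) match else mismatch
    max(0,
        s + from(i + 1, j + 1),
        gap + from(i + 1, j),
        gap + from(i, j + 1))
  }
  for (i in seq_along(av)) for (j in seq_along(bv))
    best <- max(best, from(i, j))
  best
}

# Two-group log-rank chi-square computed directly from the O-E /
# hypergeometric-variance definition.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (oe^2) / v
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a fast cohort spec for simulation-heavy tests
small_null_spec <- function(seed, n = 30) {
  cohort_spec(n_patients = n, n_normal = n, n_donors = 5, n_pm_samples = 5,
              methylation_shift = 0, metastasis_shift = list(),
              pm_reversal = 0, with_ct = FALSE, seed = seed)
}
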