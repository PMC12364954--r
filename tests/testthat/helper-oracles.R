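# Independent oracles used to verify the package's statistics. Each is a
# deliberately naive route (textbook formula, brute force, exhaustive
# enumeration) that shares no code with the implementation it checks.

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch's t-test on log2(x + c), closed form with Welch-Satterthwaite df.
oracle_welch_log2 <- function(a, b, pseudocount = 0.01) {
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  n1 <- length(la); n2 <- length(lb)
  v1 <- sum((la - mean(la))^2) / (n1 - 1)
  v2 <- sum((lb - mean(lb))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(la) - mean(lb)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

# Pearson correlation via the raw textbook sums formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Spearman as the Pearson of mid-ranks.
oracle_spearman <- function(x, y)
  oracle_pearson(rank(x, ties.method = "average"),
                 rank(y, ties.method = "average"))

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, M) draw subsets: successes are the elements 1..K.
oracle_hyper_tail <- function(N, K, M, s) {
  if (s == 0) return(1)
  if (M == 0) return(if (s > 0) 0 else 1)
  subsets <- utils::combn(N, M)
  overlap <- colSums(subsets <= K)
  mean(overlap >= s)
}

# Maximum relative error of hypergeom_upper_tail() against enumeration over
# every (N <= n_max, K <= N, M <= N, 0 <= s <= min(K, M)).
hyper_grid_max_rel_err <- function(n_max) {
  worst <- 0
  for (N in 1:n_max) for (M in 0:N) {
    subsets <- if (M > 0) utils::combn(N, M) else NULL
    for (K in 0:N) {
      overlap <- if (M > 0) colSums(subsets <= K) else 0L
      for (s in 0:min(K, M)) {
        truth <- if (s == 0) 1 else mean(overlap >= s)
        got <- cernet::hypergeom_upper_tail(N, K, M, s)
        err <- if (truth == 0) abs(got) else abs(got - truth) / truth
        worst <- max(worst, err)
      }
    }
  }
  worst
}

# All permutations of 1..n (for the exact Spearman null at small n).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
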