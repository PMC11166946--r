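# Independent oracles used across the suite. Each recomputes the target
# quantity by brute force or closed form, never through the code path it
# checks.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a_idx) {
    a <- pooled[a_idx]; b <- pooled[-a_idx]
    sum(outer(a, b, ">")) # U statistic of the first group
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_null <- apply(combos, 2, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu))
}

# Position-by-position running-sum enrichment score.
oracle_gsea_es <- function(ranked, set, weight = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% set
  k <- sum(hit)
  w <- abs(ranked)^weight
  denom <- sum(w[hit])
  running <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    running <- running + if (hit[i]) {
      if (denom > 0) unname(w[i]) / denom else 1 / k
    } else {
      -1 / (N - k)
    }
    best_pos <- max(best_pos, running)
    best_neg <- min(best_neg, running)
  }
  # maximum-magnitude deviation; the positive extremum wins exact ties
  # (tie detected with a tolerance: the scan accumulates rounding error)
  if (best_pos >= -best_neg - 1e-9) best_pos else best_neg
}

# Van der Waerden statistic and p from the formula directly.
oracle_vdw <- function(x, g) {
  g <- as.factor(g)
  N <- length(x)
  A <- qnorm(rank(x) / (N + 1))
  s2 <- sum(A^2) / (N - 1)
  Tstat <- sum(tapply(A, g, function(a) length(a) * mean(a)^2)) / s2
  list(statistic = unname(Tstat),
       p.value = pchisq(Tstat, df = nlevels(g) - 1, lower.tail = FALSE))
}

# Hypergeometric upper tail P(X >= ov) by exhaustive enumeration of draws.
oracle_hyper_tail <- function(ov, term_size, universe_size, n_draw) {
  combos <- utils::combn(universe_size, n_draw)
  in_term <- seq_len(term_size)
  mean(apply(combos, 2, function(draw) sum(draw %in% in_term) >= ov))
}

# Disjoint overlap compartments by direct set arithmetic.
oracle_partition_counts <- function(named_sets) {
  labels <- names(named_sets)
  genes <- unique(unlist(named_sets))
  key <- vapply(genes, function(g) {
    paste(labels[vapply(named_sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(key)
}
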