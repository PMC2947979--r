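# Independent brute-force oracles used to cross-check the implementation.

# Per-base depth by explicit enumeration.
bf_depth <- function(reads, chrom, n, strand = "both") {
  d <- numeric(n)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    if (strand != "both") {
      s <- if (reads$strand[i] == "*") "+" else reads$strand[i]
      if (s != strand) next
    }
    idx <- (reads$start[i] + 1):reads$end[i]
    d[idx] <- d[idx] + reads$weight[i]
  }
  d
}

bf_covered_length <- function(reads, chrom, start, end, n) {
  d <- bf_depth(reads, chrom, n)
  sum(d[(start + 1):end] > 0)
}

# Geometric tail by direct pmf summation.
bf_geom_tail <- function(L, p) {
  if (p == 1) return(if (L <= 1) 1 else 0)
  ks <- seq.int(L, L + ceiling(log(1e-16) / log(1 - p)) + 10)
  sum(p * (1 - p)^(ks - 1))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration, using the
# same "probability at most observed" two-sided rule as stats::fisher.test.
bf_fisher_two_sided <- function(a, ta, b, tb) {
  m <- a + b                       # first-column margin
  lo <- max(0, m - tb)
  hi <- min(ta, m)
  xs <- lo:hi
  probs <- dhyper(xs, ta, tb, m)
  p_obs <- dhyper(a, ta, tb, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Maximum pair count by exhaustive recursion over all valid structures
# (no memoization: independent of the DP).
bf_max_pairs <- function(seq, min_loop = 3,
                         allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  bases <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  can_pair <- function(i, j) {
    paste0(bases[i], bases[j]) %in% allowed && j - i > min_loop
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 1L):j) {
      if (can_pair(i, k)) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(bases))
}

# Phasing upper-tail probability by enumerating all placements of n
# occupied slots among the m*D window slots (register slots are
# 0, D, 2D, ... shifted by r).
bf_phasing_tail <- function(k, n, m, D, register = 0L) {
  slots <- seq_len(m * D) - 1L
  in_reg <- (slots %% D) == register
  sets <- utils::combn(m * D, n)
  hits <- apply(sets, 2, function(s) sum(in_reg[s]) >= k)
  mean(hits)
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
bf_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(s) sum(ranks[s]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
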