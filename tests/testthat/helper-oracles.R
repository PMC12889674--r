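# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (findOverlaps etc.) so that agreement is informative.

# 0-based half-open overlap width of two intervals
bp_overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# best single-overlap conservation: data frames with chrom/start0/end0
oracle_conservation <- function(ref, oth) {
  tot <- sum(ref$end0 - ref$start0)
  if (tot == 0) return(0)
  best_sum <- 0
  for (i in seq_len(nrow(ref))) {
    best <- 0
    for (j in seq_len(nrow(oth))) {
      if (ref$chrom[i] != oth$chrom[j]) next
      best <- max(best, bp_overlap(ref$start0[i], ref$end0[i],
                                   oth$start0[j], oth$end0[j]))
    }
    best_sum <- best_sum + best
  }
  best_sum / tot
}

# exhaustive greedy SPM merge on a data frame chrom/start0/end0/spm
oracle_spm_merge <- function(df) {
  picked <- integer(0)
  alive <- rep(TRUE, nrow(df))
  while (any(alive)) {
    idx <- which(alive)
    o <- idx[order(-df$spm[idx], df$chrom[idx], df$start0[idx])][1]
    picked <- c(picked, o)
    for (j in which(alive))
      if (df$chrom[j] == df$chrom[o] &&
          bp_overlap(df$start0[j], df$end0[j], df$start0[o], df$end0[o]) > 0)
        alive[j] <- FALSE
  }
  sort(picked)
}

# two-sided Fisher exact p by full hypergeometric enumeration of tables
# with the observed margins; built from choose(), not dhyper
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up written out directly
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# joint log-probability of (path, data) under a Bernoulli HMM, computed
# straight from the definition
oracle_joint_logprob <- function(pi, A, E, path, V, seq_starts) {
  lp <- 0
  for (t in seq_along(path)) {
    lp <- lp + if (t %in% seq_starts) log(pi[path[t]])
               else log(A[path[t - 1], path[t]])
    lp <- lp + sum(V[t, ] * log(E[path[t], ]) +
                   (1 - V[t, ]) * log(1 - E[path[t], ]))
  }
  lp
}
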