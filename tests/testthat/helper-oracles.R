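# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the library calls) used by the implementation.

# upper-tail binomial probability by direct log-space summation
oracle_binom_tail <- function(k, N, p) {
  if (k <= 0) return(1)
  x <- k:N
  sum(exp(lchoose(N, x) + x * log(p) + (N - x) * log1p(-p)))
}

# Benjamini-Hochberg step-up by definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  ranked <- p[ord] * m / seq_len(m)
  q[ord] <- rev(cummin(rev(ranked)))
  pmin(q, 1)
}

# O(m^2) LD scores: all-pairs adjusted r^2 within the window
oracle_ld_scores <- function(dosage, pos, annotations, window_bp) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  out <- matrix(0, m, ncol(annotations))
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (abs(pos[k] - pos[j]) > window_bp) next
      r2 <- stats::cor(dosage[, j], dosage[, k])^2
      r2a <- r2 - (1 - r2) / (n - 2)
      out[j, ] <- out[j, ] + r2a * annotations[k, ]
    }
  }
  colnames(out) <- colnames(annotations)
  out
}

# O(n^2) ssGSEA running sum, written from the definition
oracle_ssgsea <- function(values, gene_set, alpha) {
  n <- length(values)
  ord <- order(-values)
  genes <- names(values)[ord]
  r_stat <- n:1
  hit <- genes %in% gene_set
  denom_hit <- sum(abs(r_stat[hit])^alpha)
  n_miss <- n - sum(hit)
  es <- 0
  for (i in seq_len(n)) {
    p_hit <- sum(ifelse(hit[seq_len(i)], abs(r_stat[seq_len(i)])^alpha, 0)) /
      denom_hit
    p_miss <- sum(!hit[seq_len(i)]) / n_miss
    es <- es + (p_hit - p_miss)
  }
  es
}

# smallest subset of posterior probabilities reaching the level
oracle_min_credible_size <- function(pp, level) {
  m <- length(pp)
  best <- m
  for (mask in 1:(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    if (sum(pp[members]) >= level) best <- min(best, length(members))
  }
  best
}
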