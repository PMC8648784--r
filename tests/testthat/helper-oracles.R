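# Independent oracles, deliberately written as direct enumerations/loops
# so they share no code with the package implementations they check.

# Two-tailed Fisher p by explicit enumeration of the full table support
# with choose(), probability-mass convention.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  tot <- choose(m + n, k)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / tot, numeric(1))
  obs <- choose(m, a) * choose(n, k - a) / tot
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Enrichment score by materializing the entire running sum.
es_oracle <- function(ranking, gene_set, exponent = 1) {
  ord <- order(-ranking, names(ranking))
  w <- ranking[ord]
  hit <- names(w) %in% gene_set
  nr <- sum(abs(w[hit])^exponent)
  inc <- numeric(length(w))
  inc[hit] <- if (nr == 0) 0 else abs(w[hit])^exponent / nr
  inc[!hit] <- -1 / sum(!hit)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Step-up BH from its definition: p_adj_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank_j).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}
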