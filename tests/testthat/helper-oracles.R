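# Independent brute-force oracles, coded from first principles and kept
# deliberately separate from the package's implementation paths.

# Midranks by definition: rank of x_i = (#{j: x_j < x_i}) + (#{j: x_j == x_i} + 1)/2
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Pearson correlation via the raw sum formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  if (den == 0) return(NA_real_)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))
}

# Naive-Bayes word-presence log-score, evaluated with explicit loops:
# P(w|s) = (m_s(w) + p_w) / 2, p_w = (n_w + 0.5) / (N + 1).
oracle_score_species <- function(query_kmers, ts) {
  kmers <- unique(query_kmers)
  n_species <- length(ts$species_labels)
  scores <- numeric(n_species)
  names(scores) <- ts$species_labels
  for (s in ts$species_labels) {
    total <- 0
    for (w in kmers) {
      n_w <- 0
      for (s2 in ts$species_labels)
        if (any(w == ts$kmer_index[[s2]])) n_w <- n_w + 1
      p_w <- (n_w + 0.5) / (n_species + 1)
      m <- if (any(w == ts$kmer_index[[s]])) 1 else 0
      total <- total + log((m + p_w) / 2)
    }
    scores[s] <- total
  }
  scores
}
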