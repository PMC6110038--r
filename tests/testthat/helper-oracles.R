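# Independent brute-force oracles. These recompute every quantity by direct
# summation / exhaustive scan, sharing no code with the package internals
# beyond the exported inputs they check.

# Entropy by direct summation over a level interval.
oracle_entropy <- function(p, lo, hi) {
  tot <- 0
  for (k in lo:hi) {
    pk <- p[k + 1]
    if (pk > 0) tot <- tot - pk * log2(pk)
  }
  tot
}

# Exhaustive scan for the smallest k in [lo, hi-1] whose cumulative entropy
# (recomputed from scratch at each candidate) reaches half the interval total.
oracle_half_entropy <- function(p, lo, hi) {
  target <- oracle_entropy(p, lo, hi) / 2
  for (k in lo:(hi - 1)) {
    if (oracle_entropy(p, lo, k) >= target - 1e-12) return(k)
  }
  hi - 1
}

# Independent four-way segmentation built on the scan above.
oracle_segment <- function(p, kl, ku) {
  ks2 <- oracle_half_entropy(p, kl, ku)
  ks1 <- oracle_half_entropy(p, kl, ks2)
  ks3 <- oracle_half_entropy(p, ks2 + 1, ku)
  c(ks1, ks2, ks3)
}

# Per-bin entropy contributions.
oracle_bin_entropy <- function(p) ifelse(p > 0, -p * log2(p), 0)

# A deterministic richly-occupied random density for oracle sweeps.
rich_pdf <- function(seed) random_pdf(seed, occupied = 32 + (seed %% 225))
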