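# Independent oracles used across test files. These deliberately use a
# different algorithmic route than the package implementation.

# Exhaustive minimal-cost switch/flip explanation of a disagreement
# pattern. Operations: flip one position (cost 1 flip), toggle a suffix
# starting at position >= 2 (cost 1 switch); global orientation free.
# Returns c(n_switch, n_flip) of the minimum (total, then flips).
oracle_switch_flip <- function(d) {
  d <- as.logical(d)
  n <- length(d)
  best <- c(Inf, Inf)
  consider <- function(cand) {
    if (sum(cand) < sum(best) ||
        (sum(cand) == sum(best) && cand[2] < best[2])) best <<- cand
  }
  sw_pos <- if (n >= 2) 2:n else integer(0)
  for (o in c(FALSE, TRUE)) {
    base <- xor(d, o)
    for (mask in 0:(2^length(sw_pos) - 1)) {
      chosen <- sw_pos[bitwAnd(mask, 2^(seq_along(sw_pos) - 1)) > 0]
      pat <- base
      for (s in chosen) pat[s:n] <- !pat[s:n]
      consider(c(length(chosen), sum(pat)))
    }
  }
  c(n_switch = best[1], n_flip = best[2])
}

# Naive N50: largest length L in the set such that elements >= L cover
# at least half the total (scan over candidate lengths).
oracle_n50 <- function(lengths) {
  if (length(lengths) == 0 || sum(lengths) == 0) return(0)
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
  min(lengths)
}

# Poisson upper tail P(X >= k | lambda) by direct summation
oracle_pois_tail <- function(k, lambda, kmax = 1000L) {
  if (k <= 0) return(1)
  sum(exp(-lambda) * lambda^(k:kmax) / factorial(k:kmax))
}

# Exact two-sided binomial p-value by summing all outcomes with
# probability <= that of the observed count
oracle_binom_two_sided <- function(k, n, p = 0.5) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Longest alternating CN run by brute force over all sub-runs
oracle_longest_alternating <- function(states, k) {
  n <- length(states)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    seg <- states[i:j]
    if (length(seg) >= 2 && all(diff(seg) != 0) &&
        length(unique(seg)) <= k)
      best <- max(best, length(seg))
  }
  best
}

# Build two phasings of n SNPs on one block where `flipped` marks the
# SNPs whose haplotype assignment is inverted in the second phasing.
make_phasing_pair <- function(flipped) {
  n <- length(flipped)
  a <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L, ref = "A",
                  alt = "G", hp1_allele = "G", hp2_allele = "A",
                  block_id = "chr1_b1", stringsAsFactors = FALSE)
  b <- a
  b$hp1_allele <- ifelse(flipped, "A", "G")
  b$hp2_allele <- ifelse(flipped, "G", "A")
  list(a = a, b = b)
}

# swap HP1/HP2 labels of a phasing table
swap_haplotypes <- function(snps) {
  tmp <- snps$hp1_allele
  snps$hp1_allele <- snps$hp2_allele
  snps$hp2_allele <- tmp
  snps
}
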