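# Independent enumeration oracles, kept deliberately separate from the
# package's code paths.

# Two-sided Fisher p by exhaustive hypergeometric enumeration using
# log-binomial coefficients (the package uses dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  p_obs <- probs[x == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact HWE p by enumeration over heterozygote counts at the fixed allele
# margin, counting genotype configurations with choose() directly.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  ways <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    # configurations: choose carriers of minor-homozygote, then hets, times
    # the 2^h orderings of the het allele pair
    choose(n, hom_minor) * choose(n - hom_minor, h) * 2^h
  }, numeric(1))
  probs <- ways / choose(2 * n, n_minor)
  p_obs <- probs[hets == n_Aa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
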