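#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic variant: given the observed
#' allele counts, the probability of every heterozygote count consistent
#' with them is evaluated under HWE, and the p-value is the sum of
#' probabilities no greater than that of the observed configuration
#' (two-sided, the standard convention).  Probabilities are computed by
#' the stable ratio recurrence over heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative integers, total > 0).
#' @return Exact p-value; monomorphic variants return 1 by convention.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n_AA <- as.integer(n_AA); n_Aa <- as.integer(n_Aa); n_aa <- as.integer(n_aa)
  if (any(is.na(c(n_AA, n_Aa, n_aa))) || any(c(n_AA, n_Aa, n_aa) < 0))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("total genotype count must be > 0")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # recurrence: P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  # with nAA(h) = (nA - h)/2 etc. computed on the rare/common split
  probs[1] <- 1
  if (length(hets) > 1L) for (i in seq_len(length(hets) - 1L)) {
    h <- hets[i]
    n_rr <- (rare - h) / 2
    n_cc <- (max(nA, na) - h) / 2
    probs[i + 1L] <- probs[i] * 4 * n_rr * n_cc / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
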