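#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test of the heterozygote count given the allele
#' counts: all heterozygote counts with the parity of the rare-allele
#' count are enumerated with the classic probability recurrence, and the
#' two-sided p-value is the total probability of configurations no more
#' probable than the observed one. A one-sided alternative targeting
#' heterozygote excess is also available.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @param alternative `"two.sided"` (default, as in vcftools' HWE filter)
#'   or `"excess.het"`.
#' @return p-value in (0, 1\]. Monomorphic loci return 1 by convention.
#' @examples
#' hwe_exact_test(25, 50, 25)   # ideal proportions, p near 1
#' hwe_exact_test(0, 50, 0)     # all heterozygotes, tiny p
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa,
                           alternative = c("two.sided", "excess.het")) {
  alternative <- match.arg(alternative)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype is required")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  r <- min(n_A, n_a)                 # rare-allele count
  if (r == 0L) return(1)             # monomorphic
  hets <- seq.int(r %% 2L, r, by = 2L)

  # unnormalized probabilities by upward recurrence:
  # P(h + 2) / P(h) = 4 * homR(h) * homC(h) / ((h + 1)(h + 2))
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1L)) {
      h <- hets[k]
      hom_r <- (r - h) / 2
      hom_c <- n - h - hom_r
      w[k + 1L] <- w[k] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
      if (w[k + 1L] > 1e290) w <- w / w[k + 1L]  # rescale against overflow
    }
  }
  probs <- w / sum(w)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  p <- switch(alternative,
    two.sided = sum(probs[probs <= probs[obs] * (1 + 1e-9)]),
    excess.het = sum(probs[hets >= n_Aa]))
  min(1, p)
}
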