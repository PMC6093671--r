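# Small in-code fixtures and independent oracles shared across test files.

# genotype matrix from a plain samples x loci integer matrix
make_geno <- function(calls, chrom = NULL, pos = NULL, depth = NULL) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  if (is.null(pos)) pos <- 1000L * seq_len(ncol(calls))
  if (is.null(chrom)) chrom <- rep("chr1", ncol(calls))
  geno_matrix(calls,
              data.frame(chrom = chrom, pos = as.integer(pos),
                         ref = rep("A", ncol(calls)),
                         alt = rep("C", ncol(calls)),
                         stringsAsFactors = FALSE),
              depth = depth)
}

# independent HWE oracle: direct log-multinomial enumeration of genotype
# configurations conditional on the allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa,
                       alternative = c("two.sided", "excess.het")) {
  alternative <- match.arg(alternative)
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  if (min(n_A, 2 * n - n_A) == 0) return(1)
  hets <- seq(n_A %% 2, min(n_A, 2 * n - n_A), by = 2)
  logw <- vapply(hets, function(h) {
    aa <- (n_A - h) / 2
    bb <- n - h - aa
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2)
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  p <- if (alternative == "two.sided")
    sum(probs[probs <= obs * (1 + 1e-9)])
  else sum(probs[hets >= n_Aa])
  min(1, p)
}

# independent method-of-moments oracle: direct linear solve of the
# three-equation moment system (pre-clamping)
mom_oracle <- function(counts, expect) {
  a <- rbind(c(expect[["e00"]], 0, 0),
             c(expect[["e10"]], expect[["e11"]], 0),
             c(expect[["e20"]], expect[["e21"]], expect[["n"]]))
  solve(a, c(counts[["n_ibs0"]], counts[["n_ibs1"]], counts[["n_ibs2"]]))
}

# audit that no retained within-window pair exceeds r2_max, using the
# same anchoring as the pruner
ld_postcondition_ok <- function(g, window, step, r2_max) {
  for (ch in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == ch)
    if (length(idx) < 2) next
    for (start in seq(1, max(length(idx) - 1, 1), by = step)) {
      win <- idx[start:min(start + window - 1, length(idx))]
      if (length(win) < 2) next
      cc <- suppressWarnings(
        stats::cor(g$calls[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      if (any(r2 > r2_max)) return(FALSE)
    }
  }
  TRUE
}

# unordered edge keys for set comparisons
edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))
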