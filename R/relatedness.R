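#' Identity-by-state class counts for a pair of dosage vectors
#'
#' Loci where either genotype is missing are excluded. IBS2: equal
#' dosages; IBS0: opposite homozygotes (0 vs 2); IBS1: everything else.
#'
#' @param g1,g2 integer dosage vectors of equal length (`NA` = missing).
#' @return Named integer vector `(n_ibs0, n_ibs1, n_ibs2)`.
#' @examples
#' ibs_counts(c(0, 1, NA), c(1, 1, 2))  # (0, 1, 1)
#' @export
ibs_counts <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  d1 <- g1[ok]; d2 <- g2[ok]
  n2 <- sum(d1 == d2)
  n0 <- sum(abs(d1 - d2) == 2L)
  c(n_ibs0 = n0, n_ibs1 = length(d1) - n0 - n2, n_ibs2 = n2)
}

#' Expected IBS class totals conditional on IBD state
#'
#' For each locus with alt frequency p (q = 1 - p), under random mating:
#' P(IBS0|IBD0) = 2p^2q^2; P(IBS1|IBD0) = 4p^3q + 4pq^3;
#' P(IBS2|IBD0) = p^4 + q^4 + 4p^2q^2; P(IBS1|IBD1) = 2p^2q + 2pq^2;
#' P(IBS2|IBD1) = p^3 + q^3 + p^2q + pq^2; P(IBS2|IBD2) = 1.
#' The per-locus probabilities are summed over the supplied locus set.
#' Loci at boundary frequencies (0 or 1) carry no information about IBD
#' and are skipped with a warning.
#'
#' @param freqs per-locus alt-allele frequencies.
#' @return Named numeric vector of sums: `e00`, `e10`, `e20`, `e11`,
#'   `e21`, and `n` (the locus count used; `e22 = n`).
#' @export
expected_ibs_by_ibd <- function(freqs) {
  bad <- is.na(freqs) | freqs <= 0 | freqs >= 1
  if (any(bad)) {
    warning(sum(bad), " locus/loci at boundary/undefined frequency skipped")
    freqs <- freqs[!bad]
  }
  p <- freqs; q <- 1 - p
  c(e00 = sum(2 * p^2 * q^2),
    e10 = sum(4 * p^3 * q + 4 * p * q^3),
    e20 = sum(p^4 + q^4 + 4 * p^2 * q^2),
    e11 = sum(2 * p^2 * q + 2 * p * q^2),
    e21 = sum(p^3 + q^3 + p^2 * q + p * q^2),
    n = length(p))
}

#' Method-of-moments IBD estimate for one pair
#'
#' The moments cascade: z0 = n_ibs0 / e00; z1 = (n_ibs1 - z0 e10) / e11;
#' z2 = (n_ibs2 - z0 e20 - z1 e21) / N. The raw solution is then clamped
#' to \[0, 1\] component-wise and renormalized to sum to one, and
#' pi-hat = z1/2 + z2. The unclamped solution is attached as attribute
#' `"raw"` (it solves the 3x3 moment system exactly).
#'
#' @param counts named vector from [ibs_counts()].
#' @param expect named vector from [expected_ibs_by_ibd()] computed on
#'   the same locus set.
#' @return Named numeric vector `(z0, z1, z2, pi_hat)`; all `NA` with a
#'   warning when the pair has no informative loci.
#' @export
mom_ibd <- function(counts, expect) {
  n <- counts[["n_ibs0"]] + counts[["n_ibs1"]] + counts[["n_ibs2"]]
  if (n == 0) {
    warning("no pairwise-complete loci; IBD undefined")
    out <- c(z0 = NA_real_, z1 = NA_real_, z2 = NA_real_,
             pi_hat = NA_real_)
    return(out)
  }
  z0 <- counts[["n_ibs0"]] / expect[["e00"]]
  z1 <- (counts[["n_ibs1"]] - z0 * expect[["e10"]]) / expect[["e11"]]
  z2 <- (counts[["n_ibs2"]] - z0 * expect[["e20"]] -
           z1 * expect[["e21"]]) / n
  raw <- c(z0 = z0, z1 = z1, z2 = z2)
  z <- pmin(pmax(raw, 0), 1)
  z <- z / sum(z)
  out <- c(z, pi_hat = z[["z1"]] / 2 + z[["z2"]])
  attr(out, "raw") <- raw
  out
}

#' Pairwise method-of-moments IBD for a whole collection
#'
#' Computes a record for every unordered sample pair: IBS class counts
#' over pairwise-complete loci, the constrained (z0, z1, z2) and pi-hat.
#' Plug-in allele frequencies are estimated once from the full matrix
#' (no small-sample bias correction); loci with boundary or undefined
#' frequency are excluded from both the counts and the expectations so
#' the two always refer to the same locus set. Missing genotypes are
#' handled by pairwise-complete deletion.
#'
#' @param g a [geno_matrix()] with at least two samples.
#' @param freqs optional frequency vector overriding the plug-in
#'   estimate (same length as loci of `g`).
#' @return A data frame of class `relatedness_table` with columns `id1`,
#'   `id2`, `n`, `ibs0`, `ibs1`, `ibs2`, `z0`, `z1`, `z2`, `pi_hat`.
#' @export
pairwise_ibd <- function(g, freqs = NULL) {
  if (n_samples(g) < 2L) stop("at least two samples are required")
  if (is.null(freqs)) freqs <- suppressWarnings(allele_frequencies(g))
  if (length(freqs) != n_loci(g))
    stop("freqs must match the locus count")
  use <- which(!is.na(freqs) & freqs > 0 & freqs < 1)
  x <- g$calls[, use, drop = FALSE]
  p <- freqs[use]; q <- 1 - p

  m <- (!is.na(x)) * 1
  a0 <- (x == 0L & !is.na(x)) * 1
  a1 <- (x == 1L & !is.na(x)) * 1
  a2 <- (x == 2L & !is.na(x)) * 1

  nmat <- tcrossprod(m)
  i0 <- tcrossprod(a0, a2); i0 <- i0 + t(i0)
  i2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  i1 <- nmat - i0 - i2

  e00l <- 2 * p^2 * q^2
  e10l <- 4 * p^3 * q + 4 * p * q^3
  e20l <- p^4 + q^4 + 4 * p^2 * q^2
  e11l <- 2 * p^2 * q + 2 * p * q^2
  e21l <- p^3 + q^3 + p^2 * q + p * q^2
  esum <- function(el) tcrossprod(m * rep(el, each = nrow(m)), m)
  e00 <- esum(e00l); e10 <- esum(e10l); e20 <- esum(e20l)
  e11 <- esum(e11l); e21 <- esum(e21l)

  z0 <- i0 / e00
  z1 <- (i1 - z0 * e10) / e11
  z2 <- (i2 - z0 * e20 - z1 * e21) / nmat
  cl <- function(z) pmin(pmax(z, 0), 1)
  z0c <- cl(z0); z1c <- cl(z1); z2c <- cl(z2)
  tot <- z0c + z1c + z2c
  z0c <- z0c / tot; z1c <- z1c / tot; z2c <- z2c / tot
  pi_hat <- z1c / 2 + z2c

  ids <- sample_ids(g)
  ut <- which(upper.tri(nmat), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  rec <- data.frame(
    id1 = ids[ut[, 1L]], id2 = ids[ut[, 2L]],
    n = nmat[ut], ibs0 = i0[ut], ibs1 = i1[ut], ibs2 = i2[ut],
    z0 = z0c[ut], z1 = z1c[ut], z2 = z2c[ut], pi_hat = pi_hat[ut],
    stringsAsFactors = FALSE)
  undef <- rec$n == 0
  if (any(undef)) {
    warning(sum(undef), " pair(s) with no pairwise-complete loci; ",
            "records flagged NA")
    rec[undef, c("z0", "z1", "z2", "pi_hat")] <- NA_real_
  }
  class(rec) <- c("relatedness_table", "data.frame")
  attr(rec, "n_loci_used") <- length(use)
  rec
}

#' @export
print.relatedness_table <- function(x, ...) {
  cat("relatedness_table:", nrow(x), "pairs over",
      attr(x, "n_loci_used") %||% NA, "loci\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Observed heterozygosity by individual
#'
#' Fraction of non-missing calls that are heterozygous (dosage 1). In a
#' collection containing collapsed triploids the distribution of these
#' values is bimodal, which is the basis of ploidy classification.
#'
#' @param g a [geno_matrix()].
#' @return Data frame with `sample_id`, `n_het`, `n_obs`, `het`;
#'   all-missing samples get `NA` with a warning.
#' @export
per_individual_heterozygosity <- function(g) {
  n_het <- rowSums(g$calls == 1L, na.rm = TRUE)
  n_obs <- rowSums(!is.na(g$calls))
  if (any(n_obs == 0))
    warning(sum(n_obs == 0), " sample(s) with no non-missing calls")
  data.frame(sample_id = sample_ids(g), n_het = n_het, n_obs = n_obs,
             het = ifelse(n_obs > 0, n_het / n_obs, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
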