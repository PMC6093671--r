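#' Thin loci by minimum base-pair distance
#'
#' Greedy left-to-right scan within each chromosome: a locus is kept iff
#' its position is at least `min_bp` (1-based inclusive distance) from
#' the last kept locus. Retained loci on a chromosome are therefore
#' pairwise at least `min_bp` apart.
#'
#' @param g a [geno_matrix()] (loci sorted by chrom, pos — guaranteed by
#'   the constructor).
#' @param min_bp minimum distance in base pairs.
#' @return Filtered `geno_matrix`.
#' @export
thin_by_distance <- function(g, min_bp) {
  keep <- logical(n_loci(g))
  last_pos <- NULL
  last_chrom <- NULL
  for (j in seq_len(n_loci(g))) {
    ch <- g$loci$chrom[j]
    if (!identical(ch, last_chrom) ||
        g$loci$pos[j] - last_pos >= min_bp) {
      keep[j] <- TRUE
      last_chrom <- ch
      last_pos <- g$loci$pos[j]
    }
  }
  subset_loci(g, keep)
}

#' Filter loci then samples by missingness
#'
#' Drops loci whose missing-call fraction exceeds `max_missing_rate`,
#' then drops samples whose missing fraction over the *surviving* loci
#' exceeds the same rate (the per-locus and per-sample reading of a 20%
#' missing-data cap).
#'
#' @param g a [geno_matrix()].
#' @param max_missing_rate maximum tolerated missing fraction in \[0, 1\].
#' @return Filtered `geno_matrix`.
#' @export
filter_missingness <- function(g, max_missing_rate) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1)
  if (n_loci(g) > 0) {
    locus_miss <- colMeans(is.na(g$calls))
    g <- subset_loci(g, locus_miss <= max_missing_rate)
  }
  if (n_loci(g) > 0) {
    sample_miss <- rowMeans(is.na(g$calls))
    g <- subset_samples(g, sample_miss <= max_missing_rate)
  }
  g
}

#' Filter loci by minor allele frequency
#'
#' Retains loci with `min(f, 1 - f) > min_maf` (strict inequality). Loci
#' with undefined frequency (no non-missing calls) are dropped with a
#' warning.
#'
#' @param g a [geno_matrix()].
#' @param min_maf MAF threshold (strict).
#' @return Filtered `geno_matrix`.
#' @export
filter_maf <- function(g, min_maf) {
  maf <- suppressWarnings(minor_allele_frequencies(g))
  if (anyNA(maf))
    warning(sum(is.na(maf)), " locus/loci with undefined frequency dropped")
  subset_loci(g, !is.na(maf) & maf > min_maf)
}

#' Cap loci at a mean-depth percentile
#'
#' Removes putative paralogue-collapse artifacts: loci whose mean read
#' depth lies strictly above the stated empirical percentile (linear
#' interpolation, `stats::quantile` type 7) of the per-locus mean-depth
#' distribution are dropped. Skipped with a warning when no depth
#' information is available.
#'
#' @param g a [geno_matrix()].
#' @param percentile percentile in \[0, 100\] (default 90).
#' @return Filtered `geno_matrix`.
#' @export
filter_depth_percentile <- function(g, percentile = 90) {
  md <- g$loci$mean_depth
  if (all(is.na(md))) {
    warning("no depth information; depth-percentile filter skipped")
    return(g)
  }
  cut <- stats::quantile(md, percentile / 100, na.rm = TRUE, type = 7,
                         names = FALSE)
  subset_loci(g, is.na(md) | md <= cut)
}

#' Filter loci by the Hardy-Weinberg exact test
#'
#' Drops loci whose exact HWE p-value (see [hwe_exact_test()]) is below
#' `alpha`.
#'
#' @param g a [geno_matrix()].
#' @param alpha removal threshold on the p-value (strict `p < alpha`).
#' @param alternative passed to [hwe_exact_test()].
#' @return Filtered `geno_matrix`.
#' @export
filter_hwe <- function(g, alpha, alternative = "two.sided") {
  if (alpha <= 0) return(g)
  p <- hwe_pvalues(g, alternative)
  subset_loci(g, !(p < alpha))
}

#' @rdname filter_hwe
#' @return `hwe_pvalues()` returns the vector of per-locus exact p-values.
#' @export
hwe_pvalues <- function(g, alternative = "two.sided") {
  n0 <- colSums(g$calls == 0L, na.rm = TRUE)
  n1 <- colSums(g$calls == 1L, na.rm = TRUE)
  n2 <- colSums(g$calls == 2L, na.rm = TRUE)
  vapply(seq_len(n_loci(g)), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0L) return(1)
    hwe_exact_test(n0[j], n1[j], n2[j], alternative)
  }, numeric(1))
}

#' Prune loci for linkage disequilibrium
#'
#' Sliding window of `window` retained SNPs advancing by `step` SNPs
#' within each chromosome (the classic `indep-pairwise` scheme). Within a
#' window, while any pair of loci has squared Pearson correlation of
#' dosages (pairwise-complete) above `r2_max`, the member with the lower
#' minor allele frequency is removed (ties: the later position). Passes
#' repeat until no window contains a violating pair, so the postcondition
#' — no retained within-window pair with r-squared above `r2_max` — holds
#' at termination. Zero-variance loci correlate with nothing and are
#' treated as r-squared 0.
#'
#' @param g a [geno_matrix()].
#' @param window window size in SNP count (>= 2).
#' @param step window advance in SNP count (1 <= step <= window).
#' @param r2_max maximum tolerated squared correlation.
#' @return Filtered `geno_matrix`.
#' @export
ld_prune <- function(g, window = 10L, step = 3L, r2_max = 0.5) {
  stopifnot(window >= 2L, step >= 1L, step <= window)
  maf <- suppressWarnings(minor_allele_frequencies(g))
  keep <- rep(TRUE, n_loci(g))
  chroms <- g$loci$chrom
  repeat {
    removed <- FALSE
    for (ch in unique(chroms)) {
      idx <- which(keep & chroms == ch)
      if (length(idx) < 2L) next
      for (start in seq.int(1L, max(length(idx) - 1L, 1L), by = step)) {
        win <- idx[start:min(start + window - 1L, length(idx))]
        win <- win[keep[win]]
        repeat {
          win <- win[keep[win]]
          if (length(win) < 2L) break
          viol <- find_r2_violation(g$calls, win, r2_max)
          if (is.null(viol)) break
          drop <- pick_prune_victim(viol, maf, g$loci$pos)
          keep[drop] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  subset_loci(g, keep)
}

# first locus pair (in order) within `win` with r^2 > r2_max, else NULL
find_r2_violation <- function(calls, win, r2_max) {
  cc <- suppressWarnings(
    stats::cor(calls[, win, drop = FALSE],
               use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  r2 <- cc^2
  r2[lower.tri(r2, diag = TRUE)] <- 0
  hit <- which(r2 > r2_max, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  c(win[hit[1L, 1L]], win[hit[1L, 2L]])
}

# removal rule: lower MAF loses; tie -> later position loses
pick_prune_victim <- function(pair, maf, pos) {
  m <- maf[pair]
  m[is.na(m)] <- -Inf
  if (m[1L] < m[2L]) return(pair[1L])
  if (m[2L] < m[1L]) return(pair[2L])
  pair[which.max(pos[pair])]
}

#' Run the standard SNP filter cascade
#'
#' Applies, in order: positional thinning, missingness (loci then
#' samples), mean-depth percentile cap, Hardy-Weinberg exact filter and
#' the MAF filter, recording survivor counts per step. (Bi-allelic
#' selection and the per-genotype minimum depth are applied at VCF read
#' time by [read_vcf()].)
#'
#' @param g a [geno_matrix()].
#' @param thin_bp minimum distance between neighbouring SNPs (default 10).
#' @param max_missing maximum missing fraction per locus and sample
#'   (default 0.2, i.e. at least 80% called).
#' @param depth_percentile mean-depth cap percentile (default 90);
#'   `NULL` skips the step.
#' @param hwe_alpha HWE removal threshold (default 1e-4); 0 skips.
#' @param min_maf MAF threshold, strict (default 0.05); `NULL` skips.
#' @return A list with `geno` (the filtered matrix) and `report` (a
#'   `filter_report` data frame: step, loci/samples before and after).
#' @export
filter_cascade <- function(g, thin_bp = 10L, max_missing = 0.2,
                           depth_percentile = 90, hwe_alpha = 1e-4,
                           min_maf = 0.05) {
  report <- new_filter_report()
  run <- function(g, name, fun) {
    before <- c(n_loci(g), n_samples(g))
    g2 <- fun(g)
    report <<- add_filter_step(report, name, before,
                               c(n_loci(g2), n_samples(g2)))
    g2
  }
  g <- run(g, "thin", function(x) thin_by_distance(x, thin_bp))
  g <- run(g, "missingness", function(x) filter_missingness(x, max_missing))
  if (!is.null(depth_percentile))
    g <- run(g, "depth_percentile",
             function(x) filter_depth_percentile(x, depth_percentile))
  if (hwe_alpha > 0)
    g <- run(g, "hwe", function(x) filter_hwe(x, hwe_alpha))
  if (!is.null(min_maf))
    g <- run(g, "maf", function(x) filter_maf(x, min_maf))
  list(geno = g, report = report)
}

new_filter_report <- function() {
  structure(data.frame(step = character(0),
                       loci_before = integer(0), loci_after = integer(0),
                       samples_before = integer(0),
                       samples_after = integer(0),
                       stringsAsFactors = FALSE),
            class = c("filter_report", "data.frame"))
}

add_filter_step <- function(report, name, before, after) {
  row <- data.frame(step = name,
                    loci_before = before[1], loci_after = after[1],
                    samples_before = before[2], samples_after = after[2],
                    stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(report), row),
            class = c("filter_report", "data.frame"))
}
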