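#' Replace missing dosages by the locus mean
#'
#' Each missing call becomes its locus's mean dosage over non-missing
#' calls (equivalent to mean-allele-frequency imputation on the dosage
#' scale); observed entries are untouched.
#'
#' @param g a [geno_matrix()] or a numeric matrix with `NA`s.
#' @return A complete numeric matrix.
#' @export
mean_impute <- function(g) {
  x <- if (inherits(g, "geno_matrix")) g$calls else g
  x <- matrix(as.numeric(x), nrow = nrow(x), dimnames = dimnames(x))
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    j <- which(n_obs == 0)[1L]
    lab <- if (inherits(g, "geno_matrix"))
      paste0(g$loci$chrom[j], ":", g$loci$pos[j]) else paste("column", j)
    stop("locus ", lab, " has no non-missing calls; cannot impute")
  }
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2L]]
  x
}

#' Center and scale a numeric table
#'
#' Subtracts each column mean and divides by the population (divide-by-n)
#' standard deviation. Zero-variance columns cannot be scaled and are
#' dropped with a warning.
#'
#' @param x numeric matrix with at least 2 rows.
#' @return Standardized matrix; attributes `center` and `scale` hold the
#'   statistics used.
#' @export
center_scale <- function(x) {
  if (nrow(x) < 2L) stop("at least two samples are required")
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  keep <- sd_pop > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance column(s) dropped")
  out <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L,
               sd_pop[keep], "/")
  attr(out, "center") <- mu[keep]
  attr(out, "scale") <- sd_pop[keep]
  out
}

#' Principal component analysis of a standardized genotype table
#'
#' Singular value decomposition of the (already centered/scaled) table;
#' scores are projections onto the top-k right singular directions and
#' explained variance fractions are squared singular values over their
#' total. Component sign is normalized so the largest-magnitude loading
#' of each component is positive, making outputs reproducible.
#'
#' @param x standardized numeric matrix (see [center_scale()]).
#' @param k number of components, at most `min(nrow(x) - 1, ncol(x))`.
#' @return Object of class `pca_result`: `scores` (n x k),
#'   `explained` (length k), `explained_all` (full spectrum),
#'   `loadings` (p x k), `k`.
#' @export
pca_genotypes <- function(x, k = 5L) {
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k > kmax) stop("k must be <= min(samples - 1, loci) = ", kmax)
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, explained = ev[seq_len(k)],
                 explained_all = ev, loadings = loadings, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", x$k, "components\n")
  cat("  explained:",
      paste0(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U test for two groups
#'
#' Rank-sum U statistic with midranks for ties. The p-value is exact (by
#' enumeration) when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return List with `U` (for group a), `p.value`, `n_a`, `n_b`,
#'   `method`.
#' @export
mann_whitney_u <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  n_a <- length(values_a); n_b <- length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (n_a + n_b) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       n_a = n_a, n_b = n_b,
       method = if (exact) "exact" else "normal approximation")
}

#' Bonferroni adjustment
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of comparisons (>= 1).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, p * m)
}

#' Correlate two sets of PC scores
#'
#' Pearson correlation of every column pair of two score tables over the
#' same samples (e.g. SNP-derived vs SSR-derived PCs 1-5), with
#' t-distribution p-values Bonferroni-adjusted for the 25 comparisons.
#'
#' @param scores_a,scores_b numeric matrices with identical row counts
#'   (same samples, same order).
#' @param m Bonferroni multiplier; defaults to the number of pairs.
#' @return List of matrices `r`, `p`, `p_adj` (rows = columns of
#'   `scores_a`).
#' @export
correlate_pc_sets <- function(scores_a, scores_b,
                              m = ncol(scores_a) * ncol(scores_b)) {
  if (nrow(scores_a) != nrow(scores_b))
    stop("score tables must cover the same samples in the same order")
  ka <- ncol(scores_a); kb <- ncol(scores_b)
  r <- matrix(NA_real_, ka, kb)
  p <- matrix(NA_real_, ka, kb)
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      ct <- stats::cor.test(scores_a[, i], scores_b[, j],
                            method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  dimnames(r) <- dimnames(p) <-
    list(colnames(scores_a) %||% paste0("A", seq_len(ka)),
         colnames(scores_b) %||% paste0("B", seq_len(kb)))
  list(r = r, p = p, p_adj = bonferroni_adjust(p, m))
}

#' Mann-Whitney group tests along principal components
#'
#' Tests whether two groups of samples differ along each requested
#' component, Bonferroni-adjusting the p-values.
#'
#' @param pca a `pca_result`.
#' @param groups factor/character vector over the score rows with
#'   exactly two levels (samples with `NA` group are dropped).
#' @param components component indices to test (default 1:2).
#' @param m Bonferroni multiplier (default 25, the conventional budget
#'   when five PCs are examined against five groupings/PCs).
#' @return Data frame: `component`, `U`, `p`, `p_adj`, `n_a`, `n_b`.
#' @export
group_pc_tests <- function(pca, groups, components = 1:2, m = 25) {
  keep <- !is.na(groups)
  groups <- as.character(groups[keep])
  lv <- sort(unique(groups))
  if (length(lv) != 2L)
    stop("exactly two groups are required (got ",
         length(lv), ")")
  sc <- pca$scores[keep, , drop = FALSE]
  out <- lapply(components, function(cmp) {
    mw <- mann_whitney_u(sc[groups == lv[1L], cmp],
                         sc[groups == lv[2L], cmp])
    data.frame(component = cmp, U = mw$U, p = mw$p.value,
               p_adj = bonferroni_adjust(mw$p.value, m),
               n_a = mw$n_a, n_b = mw$n_b, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
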