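#' Construct a genotype matrix of alt-allele dosages
#'
#' The central container of the package: a samples x loci matrix of
#' alt-allele dosage calls (0, 1, 2 or `NA` for missing) for bi-allelic
#' SNPs, together with per-locus coordinates and, optionally, per-genotype
#' read depths.
#'
#' Loci are stored sorted by (chromosome, position); the constructor sorts
#' the columns if needed and refuses duplicated (chromosome, position)
#' coordinates. Positions are 1-based as in VCF.
#'
#' @param calls integer matrix, samples in rows (rownames are sample IDs),
#'   loci in columns; entries must be 0, 1, 2 or `NA`.
#' @param loci data frame with one row per locus and columns `chrom`,
#'   `pos`, `ref`, `alt`; an optional `mean_depth` column is recomputed
#'   from `depth` when depths are supplied.
#' @param depth optional integer matrix of per-genotype read depths with
#'   the same dimensions as `calls`.
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `loci` and `depth`.
#' @examples
#' calls <- rbind(s1 = c(0L, 1L), s2 = c(2L, NA))
#' loci <- data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                    ref = "A", alt = "C")
#' g <- geno_matrix(calls, loci)
#' n_loci(g)
#' @export
geno_matrix <- function(calls, loci, depth = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols))
    stop("`loci` lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(loci) != ncol(calls))
    stop("locus count (", nrow(loci), ") does not match call columns (",
         ncol(calls), ")")
  ids <- rownames(calls)
  if (is.null(ids)) stop("`calls` must carry sample IDs as rownames")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  if (any(loci$pos < 1L)) stop("positions must be >= 1")
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos): ", key[duplicated(key)][1L])
  ord <- order(loci$chrom, loci$pos)
  if (any(ord != seq_along(ord))) {
    loci <- loci[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  rownames(loci) <- NULL
  if (!is.null(depth)) {
    if (!all(dim(depth) == dim(calls)))
      stop("`depth` dimensions must match `calls`")
    storage.mode(depth) <- "integer"
    rownames(depth) <- ids
    loci$mean_depth <- locus_mean_depth(calls, depth)
  } else if (is.null(loci$mean_depth)) {
    loci$mean_depth <- rep(NA_real_, nrow(loci))
  }
  structure(list(calls = calls, loci = loci, depth = depth),
            class = "geno_matrix")
}

# mean read depth per locus over genotypes that were actually called
locus_mean_depth <- function(calls, depth) {
  called <- !is.na(calls)
  num <- colSums(depth * called, na.rm = TRUE)
  den <- colSums(called & !is.na(depth))
  ifelse(den > 0, num / den, NA_real_)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", n_samples(x), "samples x", n_loci(x), "loci\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%; depth table: %s\n",
              100 * miss, if (is.null(x$depth)) "absent" else "present"))
  if (n_loci(x) > 0) {
    cat("  chromosomes:",
        paste(utils::head(unique(x$loci$chrom), 5), collapse = ", "),
        if (length(unique(x$loci$chrom)) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' Dimensions and identifiers of a genotype matrix
#' @param g a `geno_matrix`.
#' @return `n_samples()`/`n_loci()` return counts; `sample_ids()` the row
#'   identifiers.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$calls)

#' @rdname n_samples
#' @export
sample_ids <- function(g) rownames(g$calls)

#' Subset a genotype matrix by loci or samples
#'
#' @param g a `geno_matrix`.
#' @param idx logical or integer index over loci (`subset_loci`) or
#'   samples (`subset_samples`).
#' @return A `geno_matrix` restricted to the selected loci/samples.
#' @export
subset_loci <- function(g, idx) {
  geno_matrix(g$calls[, idx, drop = FALSE],
              g$loci[idx, , drop = FALSE],
              if (is.null(g$depth)) NULL else g$depth[, idx, drop = FALSE])
}

#' @rdname subset_loci
#' @export
subset_samples <- function(g, idx) {
  geno_matrix(g$calls[idx, , drop = FALSE], g$loci,
              if (is.null(g$depth)) NULL else g$depth[idx, , drop = FALSE])
}

#' Per-locus alternate-allele frequencies
#'
#' Plug-in allele frequency at each locus: summed dosage over twice the
#' number of non-missing calls. Missing calls contribute to neither
#' numerator nor denominator. Loci with no non-missing call get `NA`
#' (flagged with a warning), never a silent zero.
#'
#' @param g a `geno_matrix`.
#' @return Numeric vector of frequencies in \[0, 1\] (or `NA`), named
#'   `chrom:pos`.
#' @examples
#' g <- geno_matrix(rbind(a = 0L, b = NA, c = 1L),
#'                  data.frame(chrom = "1", pos = 10L, ref = "A", alt = "G"))
#' allele_frequencies(g)  # 1 alt allele / 4 observed alleles = 0.25
#' @export
allele_frequencies <- function(g) {
  n_obs <- colSums(!is.na(g$calls))
  freq <- ifelse(n_obs > 0, colSums(g$calls, na.rm = TRUE) / (2 * n_obs),
                 NA_real_)
  if (anyNA(freq))
    warning(sum(is.na(freq)), " locus/loci with no non-missing calls; ",
            "frequency undefined (NA)")
  names(freq) <- paste0(g$loci$chrom, ":", g$loci$pos)
  freq
}

#' Per-locus minor allele frequency
#'
#' Computed from integer allele counts (`min(ac, an - ac) / an`) rather
#' than by folding the frequency, so a locus at 95% alt frequency gives
#' exactly the same MAF as one at 5% and threshold comparisons are not
#' disturbed by floating-point rounding.
#'
#' @param g a `geno_matrix`.
#' @return `min(f, 1 - f)`; always in \[0, 0.5\] (`NA` when undefined).
#' @export
minor_allele_frequencies <- function(g) {
  an <- 2 * colSums(!is.na(g$calls))
  ac <- colSums(g$calls, na.rm = TRUE)
  out <- ifelse(an > 0, pmin(ac, an - ac) / an, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " locus/loci with no non-missing calls; ",
            "MAF undefined (NA)")
  names(out) <- paste0(g$loci$chrom, ":", g$loci$pos)
  out
}

#' Read a sample-metadata table
#'
#' Delimited text (tab by default) with a header; must contain a
#' `sample_id` column. Conventional further columns are `species`,
#' `origin` and `harvest`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata must have a `sample_id` column")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  meta
}
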