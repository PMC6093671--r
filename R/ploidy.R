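#' Classify ploidy from individual heterozygosity with fixed thresholds
#'
#' Samples with observed heterozygosity at or below `low` are called
#' diploid, at or above `high` triploid; values strictly inside the open
#' gap are ambiguous. The default thresholds (0.335, 0.345) are the pair
#' that cleanly separated the two clusters in a diverse apple
#' collection; data-driven splitting (see [find_valley_split()]) is
#' preferred for other collections.
#'
#' @param het_records data frame from [per_individual_heterozygosity()]
#'   (needs `sample_id` and `het`).
#' @param low diploid upper threshold.
#' @param high triploid lower threshold.
#' @return Data frame of class `ploidy_calls`: `sample_id`, `het`,
#'   `class` (diploid / triploid / ambiguous), `method`, `low`, `high`.
#' @export
classify_fixed <- function(het_records, low = 0.335, high = 0.345) {
  if (low >= high) stop("thresholds must satisfy low < high")
  het <- het_records$het
  cls <- ifelse(is.na(het), NA_character_,
                ifelse(het <= low, "diploid",
                       ifelse(het >= high, "triploid", "ambiguous")))
  warn_extreme_het(het, high)
  structure(data.frame(sample_id = het_records$sample_id, het = het,
                       class = cls, method = "fixed-thresholds",
                       low = low, high = high, stringsAsFactors = FALSE),
            class = c("ploidy_calls", "data.frame"))
}

# a value far above the triploid cluster is suspicious (possible higher
# ploidy or contamination) but never called tetraploid
warn_extreme_het <- function(het, high) {
  far <- !is.na(het) & het > high + 0.25
  if (any(far))
    warning(sum(far), " sample(s) with heterozygosity far above the ",
            "triploid threshold; check for contamination or higher ploidy")
}

#' Data-driven split of a bimodal heterozygosity distribution
#'
#' Exhaustive one-dimensional two-means: every split of the sorted
#' values into a lower and an upper cluster is scored by total
#' within-cluster sum of squares, and the minimizer is returned as the
#' boundary pair (maximum of the lower cluster, minimum of the upper).
#' Degenerate inputs are flagged with `no_split = TRUE`: all values
#' identical, no gap between the clusters, or an essentially unimodal
#' distribution. Unimodality is judged by the ratio of the optimal
#' within-cluster sum of squares to the total sum of squares: two
#' genuinely separated heterozygosity clusters leave only a few percent
#' of the variance within clusters, while the best split of a single
#' cluster of measurement noise still leaves well over a third (about
#' `1 - 2/pi` for a normal), so the cutoff 0.2 separates the regimes
#' with a wide margin.
#'
#' @param het numeric vector of per-sample heterozygosities (>= 4
#'   values).
#' @return List with `low`, `high` and `no_split`.
#' @export
find_valley_split <- function(het) {
  het <- het[!is.na(het)]
  if (length(het) < 4L) stop("at least 4 values are required")
  v <- sort(het)
  n <- length(v)
  if (v[1] == v[n])
    return(list(low = v[1], high = v[1], no_split = TRUE))
  css <- function(x) sum((x - mean(x))^2)
  wss <- vapply(seq_len(n - 1L), function(k)
    css(v[seq_len(k)]) + css(v[(k + 1L):n]), numeric(1))
  k <- which.min(wss)
  low <- v[k]; high <- v[k + 1L]
  list(low = low, high = high,
       no_split = low == high || wss[k] / css(v) > 0.2)
}

#' Classify ploidy via the valley split
#'
#' Runs [find_valley_split()] on the observed heterozygosities and
#' classifies with the resulting boundary pair (so no sample is
#' ambiguous unless the split degenerates).
#'
#' @inheritParams classify_fixed
#' @return A `ploidy_calls` data frame (see [classify_fixed()]).
#' @export
classify_valley <- function(het_records) {
  sp <- find_valley_split(het_records$het)
  if (sp$no_split) {
    warning("no valley found; all samples called diploid")
    out <- classify_fixed(het_records, low = max(het_records$het,
                                                 na.rm = TRUE),
                          high = max(het_records$het, na.rm = TRUE) + 1e-9)
  } else {
    out <- classify_fixed(het_records, low = sp$low, high = sp$high)
  }
  out$method <- if (sp$no_split) "valley-split (degenerate)"
                else "valley-split"
  out
}

#' Expected heterozygosity under Hardy-Weinberg proportions
#'
#' Disomic expectation 2pq per locus; trisomic expectation
#' 1 - p^3 - q^3 = 3pq. The trisomic/disomic ratio is exactly 3/2 for
#' every allele frequency, which is why collapsed triploid calls show
#' about 50% more heterozygosity than diploids in an equilibrium
#' population.
#'
#' @param freqs per-locus allele frequencies in (0, 1).
#' @param ploidy 2 or 3.
#' @return Mean expected heterozygosity over loci.
#' @export
hwe_het_expectation <- function(freqs, ploidy) {
  if (any(freqs <= 0) || any(freqs >= 1))
    stop("frequencies must lie strictly inside (0, 1)")
  p <- freqs; q <- 1 - p
  if (ploidy == 2) return(mean(2 * p * q))
  if (ploidy == 3) return(mean(1 - p^3 - q^3))
  stop("ploidy must be 2 or 3")
}
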