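#' Configuration for the germplasm-collection simulator
#'
#' The defaults emulate a diverse apple-type gene bank of 349 accessions:
#' 182 unrelated founders drawn under Hardy-Weinberg equilibrium, 42 clone
#' groups (31 of size two, one of size 15; 119 clonal members in total,
#' giving 77 clone duplicates), 24 parent-offspring crosses between
#' founders, and 66 triploids (19% of the collection) formed from an
#' unreduced diploid gamete plus a haploid gamete and collapsed to
#' diploid-style calls. Allele frequencies are uniform on (0.05, 0.5),
#' genotyping error within clone groups is 0.2% per call and 5% of calls
#' are set missing.
#'
#' `n_parent_offspring_pairs` is the number of simulated offspring; each
#' offspring contributes two (parent, child) ordered pairs to the truth
#' table. Clone sources, cross parents and triploid parents are disjoint
#' founder subsets so that the ground truth is unambiguous.
#'
#' @param n_loci number of unlinked SNP loci.
#' @param n_founders number of unrelated HWE founders.
#' @param freq_bounds lower/upper bounds of the uniform allele-frequency
#'   law, both inside (0, 1).
#' @param clone_group_sizes integer vector of clone-group sizes (>= 2 each;
#'   a group of size k is one source founder plus k - 1 propagated clones).
#' @param n_parent_offspring_pairs number of founder crosses (offspring).
#' @param n_triploids number of triploid accessions.
#' @param error_rate per-call genotyping error rate applied when
#'   propagating clones.
#' @param missing_rate i.i.d. per-call missingness rate.
#' @param seed integer random seed (mandatory: every simulated collection
#'   is reproducible).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 5000L,
                       n_founders = 182L,
                       freq_bounds = c(0.05, 0.5),
                       clone_group_sizes = c(15L, 6L, 5L, 5L, rep(4L, 5),
                                             3L, 3L, rep(2L, 31)),
                       n_parent_offspring_pairs = 24L,
                       n_triploids = 66L,
                       error_rate = 0.002,
                       missing_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci),
              n_founders = as.integer(n_founders),
              freq_bounds = as.numeric(freq_bounds),
              clone_group_sizes = as.integer(clone_group_sizes),
              n_parent_offspring_pairs = as.integer(n_parent_offspring_pairs),
              n_triploids = as.integer(n_triploids),
              error_rate = as.numeric(error_rate),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  if (length(cfg$freq_bounds) != 2 || cfg$freq_bounds[1] >= cfg$freq_bounds[2])
    stop("freq_bounds must be (lower, upper) with lower < upper")
  if (any(cfg$freq_bounds <= 0) || any(cfg$freq_bounds >= 1))
    stop("freq_bounds must lie strictly inside (0, 1)")
  if (cfg$error_rate < 0 || cfg$error_rate > 1 ||
      cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("rates must lie in [0, 1]")
  if (length(cfg$clone_group_sizes) && any(cfg$clone_group_sizes < 2L))
    stop("clone groups must have size >= 2")
  if (is.na(cfg$seed)) stop("a seed is required")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw per-locus allele frequencies
#'
#' @param cfg a [sim_config()]; uses its `n_loci`, `freq_bounds` and
#'   `seed`.
#' @return Numeric vector of i.i.d. Uniform(lower, upper) frequencies.
#' @export
draw_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  stats::runif(cfg$n_loci, cfg$freq_bounds[1], cfg$freq_bounds[2])
}

#' Simulate one diploid founder under Hardy-Weinberg equilibrium
#'
#' Dosage at each locus is Binomial(2, p), independent across loci.
#'
#' @param freqs per-locus alt-allele frequencies in (0, 1).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Integer dosage vector.
#' @export
simulate_founder <- function(freqs, seed = NULL) {
  if (any(freqs <= 0) || any(freqs >= 1))
    stop("frequencies must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(freqs), 2L, freqs)
}

#' Simulate a diploid offspring of two parents
#'
#' One allele is drawn uniformly from each parent's two alleles at every
#' locus, independently across loci (unlinked loci).
#'
#' @param parent_a,parent_b integer dosage vectors over the same loci.
#' @param seed optional seed.
#' @return Integer dosage vector.
#' @export
simulate_offspring <- function(parent_a, parent_b, seed = NULL) {
  if (length(parent_a) != length(parent_b))
    stop("parents must cover the same locus set")
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rbinom(length(parent_a), 1L, parent_a / 2)
  b <- stats::rbinom(length(parent_b), 1L, parent_b / 2)
  a + b
}

#' Simulate a triploid and collapse it to diploid-style calls
#'
#' The triploid arises from an unreduced diploid gamete (both alleles of
#' `parent_a`) fusing with a haploid gamete (one uniform allele of
#' `parent_b`). A diploid-style caller sees a heterozygous call whenever
#' the three alleles are not all identical (AAB and ABB both give dosage
#' 1), otherwise the homozygous dosage 0 or 2.
#'
#' @inheritParams simulate_offspring
#' @return Integer dosage vector of collapsed diploid-style calls.
#' @export
simulate_triploid <- function(parent_a, parent_b, seed = NULL) {
  if (length(parent_a) != length(parent_b))
    stop("parents must cover the same locus set")
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rbinom(length(parent_b), 1L, parent_b / 2)
  tri <- parent_a + b                       # alt alleles among the three
  ifelse(tri == 0L, 0L, ifelse(tri == 3L, 2L, 1L))
}

#' Propagate a clone with genotyping error
#'
#' Each call is independently replaced, with probability `error_rate`, by
#' a uniform draw from the other two dosage states (a symmetric error
#' model covering both miscalls and somatic mutation).
#'
#' @param source integer dosage vector.
#' @param error_rate per-call error probability in \[0, 1\].
#' @param seed optional seed.
#' @return Integer dosage vector.
#' @export
make_clone <- function(source, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- source
  hit <- which(stats::runif(length(source)) < error_rate & !is.na(source))
  if (length(hit)) {
    shift <- sample(c(1L, 2L), length(hit), replace = TRUE)
    out[hit] <- (source[hit] + shift) %% 3L
  }
  out
}

#' Simulate a full germplasm collection with ground truth
#'
#' Assembles founders (HWE), clone groups ([make_clone()]), diploid
#' offspring of founder crosses ([simulate_offspring()]) and collapsed
#' triploids ([simulate_triploid()]), then applies i.i.d. missingness.
#' Loci sit at consecutive multiples of 1,000 bp on one synthetic
#' chromosome, so positional thinning at typical distances is inert.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_collection` with elements
#'   \describe{
#'     \item{geno}{a [geno_matrix()] (no depth table);}
#'     \item{truth}{ground truth: `samples` (sample_id, ploidy,
#'       clone_group, role), `parent_offspring` (parent, child ordered
#'       pairs for diploid offspring), `triploid_parents` (sample,
#'       parent_a, parent_b);}
#'     \item{freqs}{the founder allele-frequency vector;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_groups <- length(cfg$clone_group_sizes)
  need <- n_groups + 2L * (cfg$n_parent_offspring_pairs > 0L) +
    2L * (cfg$n_triploids > 0L)
  if (cfg$n_founders < need)
    stop("config requests more clone sources / parents than founders")
  set.seed(cfg$seed)
  freqs <- stats::runif(cfg$n_loci, cfg$freq_bounds[1], cfg$freq_bounds[2])

  founders <- matrix(stats::rbinom(cfg$n_founders * cfg$n_loci, 2L,
                                   rep(freqs, each = cfg$n_founders)),
                     nrow = cfg$n_founders)
  f_ids <- sprintf("F%03d", seq_len(cfg$n_founders))
  rownames(founders) <- f_ids

  # disjoint founder roles: clone sources | cross parents | triploid parents
  pool <- sample(cfg$n_founders)
  src_idx <- pool[seq_len(n_groups)]
  if (n_groups > 0L) pool <- pool[-seq_len(n_groups)]

  n_total <- cfg$n_founders + sum(pmax(cfg$clone_group_sizes - 1L, 0L)) +
    cfg$n_parent_offspring_pairs + cfg$n_triploids
  calls <- matrix(NA_integer_, nrow = n_total, ncol = cfg$n_loci)
  calls[seq_len(cfg$n_founders), ] <- founders
  ids <- character(n_total)
  ids[seq_len(cfg$n_founders)] <- f_ids
  ploidy <- rep(2L, n_total)
  clone_group <- rep(NA_integer_, n_total)
  role <- rep("founder", n_total)
  clone_group[src_idx] <- seq_len(n_groups)
  at <- cfg$n_founders

  for (gi in seq_len(n_groups)) {
    src <- founders[src_idx[gi], ]
    for (ci in seq_len(cfg$clone_group_sizes[gi] - 1L)) {
      at <- at + 1L
      calls[at, ] <- make_clone(src, cfg$error_rate)
      ids[at] <- sprintf("G%02dC%02d", gi, ci)
      clone_group[at] <- gi
      role[at] <- "clone"
    }
  }

  po <- data.frame(parent = character(0), child = character(0),
                   stringsAsFactors = FALSE)
  if (cfg$n_parent_offspring_pairs > 0L) {
    n_half <- max(2L, ceiling(cfg$n_founders / 3))
    cross_pool <- pool[seq_len(min(length(pool), n_half))]
    if (cfg$n_parent_offspring_pairs > choose(length(cross_pool), 2))
      stop("config requests more distinct crosses than founder pairs allow")
    pairs_seen <- character(0)
    for (oi in seq_len(cfg$n_parent_offspring_pairs)) {
      repeat {
        pr <- sort(sample(cross_pool, 2L))
        key <- paste(pr, collapse = "-")
        if (!key %in% pairs_seen) break
      }
      pairs_seen <- c(pairs_seen, key)
      at <- at + 1L
      calls[at, ] <- simulate_offspring(founders[pr[1], ], founders[pr[2], ])
      ids[at] <- sprintf("O%03d", oi)
      role[at] <- "offspring"
      po <- rbind(po, data.frame(parent = f_ids[pr], child = ids[at],
                                 stringsAsFactors = FALSE))
    }
    pool <- setdiff(pool, cross_pool)
  }

  tp <- data.frame(sample = character(0), parent_a = character(0),
                   parent_b = character(0), stringsAsFactors = FALSE)
  if (cfg$n_triploids > 0L) {
    # parent_a (the unreduced gamete) is unique per triploid: two triploids
    # sharing it would carry the same full diploid genome and look clonal
    if (length(pool) < cfg$n_triploids + 1L)
      stop("not enough founders left for distinct triploid parents")
    pa_idx <- sample(pool, cfg$n_triploids)
    for (ti in seq_len(cfg$n_triploids)) {
      pr <- c(pa_idx[ti], sample(setdiff(pool, pa_idx[ti]), 1L))
      at <- at + 1L
      calls[at, ] <- simulate_triploid(founders[pr[1], ], founders[pr[2], ])
      ids[at] <- sprintf("T%03d", ti)
      ploidy[at] <- 3L
      role[at] <- "triploid"
      tp <- rbind(tp, data.frame(sample = ids[at], parent_a = f_ids[pr[1]],
                                 parent_b = f_ids[pr[2]],
                                 stringsAsFactors = FALSE))
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                   nrow = nrow(calls))
    calls[drop] <- NA_integer_
  }
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  loci <- data.frame(chrom = "sim1",
                     pos = 1000L * seq_len(cfg$n_loci),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  truth_samples <- data.frame(sample_id = ids, ploidy = ploidy,
                              clone_group = clone_group, role = role,
                              stringsAsFactors = FALSE)
  structure(list(geno = geno_matrix(calls, loci),
                 truth = list(samples = truth_samples,
                              parent_offspring = po,
                              triploid_parents = tp),
                 freqs = freqs,
                 config = cfg),
            class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  tab <- table(x$truth$samples$role)
  cat("sim_collection:", nrow(x$truth$samples), "samples x",
      x$config$n_loci, "loci\n  roles:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation truth table as delimited text
#'
#' @param sim a `sim_collection`.
#' @param path output path for the per-sample table; parent-offspring
#'   pairs go to `paste0(path, ".pairs")`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$parent_offspring, paste0(path, ".pairs"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
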