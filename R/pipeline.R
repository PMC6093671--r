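#' Pipeline configuration
#'
#' Every default equals the standard printed parameter of the workflow:
#' genotype depth 8, thinning 10 bp, 20% missingness cap, 90th-percentile
#' mean-depth cap, HWE alpha 1e-4, MAF 0.05 for the IBD stages and 0.01
#' for PCA, LD pruning 10/3/0.5, clone threshold pi-hat > 0.85,
#' first-degree band \[0.43, 0.52\], fixed heterozygosity thresholds
#' (0.335, 0.345) when the fixed ploidy method is selected.
#'
#' @param min_dp minimum per-genotype read depth at VCF read time.
#' @param thin_bp minimum distance between neighbouring SNPs.
#' @param max_missing maximum missing fraction per locus and sample.
#' @param depth_percentile mean-depth cap percentile (`NULL` to skip).
#' @param hwe_alpha HWE exact-test removal threshold (0 to skip).
#' @param maf_ibd MAF threshold before the IBD stages.
#' @param maf_pca MAF threshold before PCA.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param clone_threshold clone edge rule `pi_hat > clone_threshold`.
#' @param fd_low,fd_high first-degree band (closed).
#' @param ploidy_method `"valley"` (data-driven) or `"fixed"`.
#' @param het_low,het_high fixed ploidy thresholds.
#' @param pca_k number of principal components.
#' @param representative_rule `"random"` or `"lexicographic"` clone
#'   representative choice.
#' @param seed mandatory seed for every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_dp = 8L, thin_bp = 10L, max_missing = 0.2,
                            depth_percentile = 90, hwe_alpha = 1e-4,
                            maf_ibd = 0.05, maf_pca = 0.01,
                            prune_window = 10L, prune_step = 3L,
                            prune_r2 = 0.5, clone_threshold = 0.85,
                            fd_low = 0.43, fd_high = 0.52,
                            ploidy_method = c("valley", "fixed"),
                            het_low = 0.335, het_high = 0.345,
                            pca_k = 5L,
                            representative_rule = c("random",
                                                    "lexicographic"),
                            seed = 1L) {
  cfg <- list(min_dp = min_dp, thin_bp = thin_bp,
              max_missing = max_missing,
              depth_percentile = depth_percentile, hwe_alpha = hwe_alpha,
              maf_ibd = maf_ibd, maf_pca = maf_pca,
              prune_window = prune_window, prune_step = prune_step,
              prune_r2 = prune_r2, clone_threshold = clone_threshold,
              fd_low = fd_low, fd_high = fd_high,
              ploidy_method = match.arg(ploidy_method),
              het_low = het_low, het_high = het_high, pca_k = pca_k,
              representative_rule = match.arg(representative_rule),
              seed = as.integer(seed))
  if (is.na(cfg$seed)) stop("a seed is required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full gene bank genotype workflow
#'
#' Stage order: filter cascade -> pairwise IBD on all samples -> clone
#' network and deduplication -> individual heterozygosity and ploidy
#' classification -> exclusion of triploid (and ambiguous) samples ->
#' pairwise IBD recomputed on the unique diploids -> first-degree
#' network -> MAF/LD-pruned PCA with optional group tests.
#'
#' @param input a [geno_matrix()], a path to a VCF file, a
#'   [sim_config()] (the collection is simulated first) or a
#'   `sim_collection`.
#' @param metadata optional sample metadata data frame (see
#'   [read_sample_metadata()]); groupings `species`, `origin` and
#'   `harvest` with exactly two levels are tested along PC1/PC2.
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`; see Details.
#' @details The report carries the filter report, the clone network and
#'   summary (samples with a clonal relationship, unique genotypes,
#'   group count, largest group), ploidy calls and summary, the
#'   first-degree network and summary, an audit table of unclassified
#'   high-relatedness pairs (between the first-degree band and the clone
#'   threshold), the PCA result with any group tests, a per-sample
#'   disposition ledger, and the configuration echo.
#' @export
run_pipeline <- function(input, metadata = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  truth <- NULL
  if (inherits(input, "sim_config")) input <- simulate_collection(input)
  if (inherits(input, "sim_collection")) {
    truth <- input$truth
    input <- input$geno
  }
  if (is.character(input)) input <- read_vcf(input, config$min_dp)
  stopifnot(inherits(input, "geno_matrix"))
  all_ids <- sample_ids(input)

  fc <- filter_cascade(input, thin_bp = config$thin_bp,
                       max_missing = config$max_missing,
                       depth_percentile = config$depth_percentile,
                       hwe_alpha = config$hwe_alpha,
                       min_maf = config$maf_ibd)
  g <- fc$geno
  if (n_samples(g) < 2L) stop("pipeline aborted at stage 'filter': ",
                              "fewer than two samples survive")

  ibd_all <- pairwise_ibd(g)
  cl_net <- clone_network(ibd_all, threshold = config$clone_threshold,
                          nodes = sample_ids(g))
  cl_summary <- summarize_clonality(cl_net$components, n_samples(g))
  reps <- select_representatives(cl_net$components,
                                 rule = config$representative_rule,
                                 seed = config$seed)
  g_unique <- subset_samples(g, sample_ids(g) %in% reps)

  het <- per_individual_heterozygosity(g_unique)
  ploidy <- if (config$ploidy_method == "fixed")
    classify_fixed(het, config$het_low, config$het_high)
  else classify_valley(het)
  n_ambig <- sum(ploidy$class == "ambiguous", na.rm = TRUE)
  if (n_ambig)
    warning(n_ambig, " ambiguous-ploidy sample(s) excluded from the ",
            "first-degree stage")
  diploid_ids <- ploidy$sample_id[!is.na(ploidy$class) &
                                    ploidy$class == "diploid"]
  g_dip <- subset_samples(g_unique, sample_ids(g_unique) %in% diploid_ids)

  ibd_dip <- NULL; fd_net <- NULL; fd_summary <- NULL; audit <- NULL
  if (n_samples(g_dip) >= 2L) {
    ibd_dip <- pairwise_ibd(g_dip)
    fd_net <- first_degree_network(ibd_dip, low = config$fd_low,
                                   high = config$fd_high,
                                   nodes = sample_ids(g_dip))
    dd <- degree_distribution(fd_net)
    comp_sizes <- fd_net$components$size
    fd_summary <- list(n_with_edge = dd$n_connected,
                       n_isolated = dd$n_isolated,
                       n_edges = nrow(fd_net$edges),
                       largest_component = max(comp_sizes))
    in_audit <- !is.na(ibd_dip$pi_hat) &
      ibd_dip$pi_hat > config$fd_high &
      ibd_dip$pi_hat <= config$clone_threshold
    audit <- as.data.frame(ibd_dip)[in_audit,
                                    c("id1", "id2", "pi_hat"),
                                    drop = FALSE]
    rownames(audit) <- NULL
  }

  pca_out <- NULL
  if (n_samples(g_dip) >= 3L && n_loci(g_dip) >= 2L) {
    gp <- filter_maf(g_dip, config$maf_pca)
    gp <- ld_prune(gp, config$prune_window, config$prune_step,
                   config$prune_r2)
    x <- center_scale(mean_impute(gp))
    k <- min(config$pca_k, nrow(x) - 1L, ncol(x))
    pca <- pca_genotypes(x, k)
    tests <- pipeline_group_tests(pca, metadata, sample_ids(g_dip))
    pca_out <- list(pca = pca, n_loci = n_loci(gp), tests = tests)
  }

  disposition <- data.frame(sample_id = all_ids,
                            status = "filtered-out",
                            stringsAsFactors = FALSE)
  set_status <- function(d, ids, status) {
    d$status[d$sample_id %in% ids] <- status; d
  }
  disposition <- set_status(disposition, sample_ids(g), "clone-duplicate")
  disposition <- set_status(disposition, reps, "unique")
  disposition <- set_status(
    disposition, ploidy$sample_id[ploidy$class == "triploid"],
    "triploid-excluded")
  disposition <- set_status(
    disposition, ploidy$sample_id[ploidy$class == "ambiguous"],
    "ambiguous-excluded")
  disposition <- set_status(disposition, diploid_ids, "unique-diploid")

  structure(list(filter_report = fc$report,
                 geno_filtered = g,
                 ibd_all = ibd_all,
                 clone_network = cl_net,
                 clone_summary = cl_summary,
                 representatives = reps,
                 het = het, ploidy = ploidy,
                 ploidy_summary = list(
                   n_diploid = sum(ploidy$class == "diploid", na.rm = TRUE),
                   n_triploid = sum(ploidy$class == "triploid",
                                    na.rm = TRUE),
                   n_ambiguous = n_ambig,
                   low = ploidy$low[1], high = ploidy$high[1],
                   method = ploidy$method[1]),
                 ibd_diploid = ibd_dip,
                 first_degree_network = fd_net,
                 first_degree_summary = fd_summary,
                 audit_unclassified = audit,
                 pca = pca_out,
                 disposition = disposition,
                 truth = truth,
                 config = config,
                 version = as.character(utils::packageVersion("clonekin"))),
            class = "run_report")
}

# run two-level group tests for the conventional metadata groupings
pipeline_group_tests <- function(pca, metadata, ids) {
  if (is.null(metadata)) return(NULL)
  out <- list()
  for (grouping in intersect(c("species", "origin", "harvest"),
                             names(metadata))) {
    grp <- metadata[[grouping]][match(ids, metadata$sample_id)]
    lv <- unique(grp[!is.na(grp)])
    if (length(lv) != 2L) next
    tst <- group_pc_tests(pca, grp, components = seq_len(min(2L, pca$k)))
    tst$grouping <- grouping
    out[[grouping]] <- tst
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Summarize the clone stage
#'
#' @param components component data frame from [connected_components()]
#'   of the clone network.
#' @param n_samples number of samples that entered the clone stage.
#' @return List: `n_samples`, `n_clonal` (samples with at least one
#'   clonal relationship), `n_singleton`, `n_unique` (singletons plus
#'   one representative per group), `n_groups`, `largest_group`.
#' @export
summarize_clonality <- function(components, n_samples) {
  multi <- components$size > 1L
  groups <- unique(components$component[multi])
  sizes <- components$size[multi][!duplicated(components$component[multi])]
  list(n_samples = n_samples,
       n_clonal = sum(multi),
       n_singleton = sum(!multi),
       n_unique = sum(!multi) + length(groups),
       n_groups = length(groups),
       largest_group = if (length(sizes)) max(sizes) else 1L)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== gene bank genotype workflow report ==\n")
  cat("filter cascade:\n")
  print(as.data.frame(x$filter_report), row.names = FALSE)
  cs <- x$clone_summary
  cat(sprintf(paste0("clones: %d/%d samples with >=1 clonal ",
                     "relationship; %d unique genotypes in %d groups ",
                     "(largest %d)\n"),
              cs$n_clonal, cs$n_samples, cs$n_unique, cs$n_groups,
              cs$largest_group))
  ps <- x$ploidy_summary
  cat(sprintf("ploidy (%s, split %.3f/%.3f): %d diploid, %d triploid, %d ambiguous\n",
              ps$method, ps$low, ps$high, ps$n_diploid, ps$n_triploid,
              ps$n_ambiguous))
  if (!is.null(x$first_degree_summary)) {
    fs <- x$first_degree_summary
    cat(sprintf(paste0("first degree: %d samples with >=1 edge, %d ",
                       "edges, largest component %d\n"),
                fs$n_with_edge, fs$n_edges, fs$largest_component))
  }
  if (!is.null(x$pca)) {
    cat(sprintf("pca: %d loci, explained %s\n", x$pca$n_loci,
                paste0(sprintf("%.1f%%", 100 * x$pca$pca$explained),
                       collapse = ", ")))
  }
  cat("disposition:\n")
  print(table(x$disposition$status))
  invisible(x)
}
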