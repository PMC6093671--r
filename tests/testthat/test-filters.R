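test_that("positional thinning keeps a greedy per-chromosome spacing", {
  g <- make_geno(matrix(0:1, 2, 3, dimnames = list(c("a", "b"), NULL)),
                 pos = c(100L, 105L, 115L))
  gt <- thin_by_distance(g, 10L)
  expect_equal(gt$loci$pos, c(100L, 115L))
  # well-spaced input is untouched
  g2 <- make_geno(matrix(0:1, 2, 4, dimnames = list(c("a", "b"), NULL)),
                  pos = c(100L, 200L, 300L, 400L))
  expect_equal(thin_by_distance(g2, 10L)$loci$pos, g2$loci$pos)
  # same position on different chromosomes: both kept
  g3 <- make_geno(matrix(0:1, 2, 2, dimnames = list(c("a", "b"), NULL)),
                  chrom = c("chr1", "chr2"), pos = c(100L, 100L))
  expect_equal(n_loci(thin_by_distance(g3, 10L)), 2L)
})

test_that("missingness filter drops loci first, then samples on surviving loci", {
  calls <- matrix(0L, nrow = 10, ncol = 5,
                  dimnames = list(sprintf("s%02d", 1:10), NULL))
  calls[1:3, 1] <- NA          # locus 1: 30% missing -> dropped
  g <- make_geno(calls)
  gf <- filter_missingness(g, 0.2)
  expect_equal(n_loci(gf), 4L)
  expect_equal(n_samples(gf), 10L)

  # a sample missing at 25% of the *surviving* loci is dropped
  calls2 <- matrix(0L, nrow = 10, ncol = 8,
                   dimnames = list(sprintf("s%02d", 1:10), NULL))
  calls2[4:10, 1] <- NA                 # locus dropped in the locus pass
  calls2[1, 2:3] <- NA                  # 2/7 of surviving loci = 28.6%
  gf2 <- filter_missingness(make_geno(calls2), 0.2)
  expect_equal(n_loci(gf2), 7L)
  expect_false("s01" %in% sample_ids(gf2))
  # complete matrix is untouched
  g3 <- make_geno(matrix(1L, 3, 3, dimnames = list(c("a", "b", "c"), NULL)))
  gf3 <- filter_missingness(g3, 0.2)
  expect_equal(dim(gf3$calls), c(3L, 3L))
})

test_that("MAF filter folds frequencies and applies a strict threshold", {
  # freqs: 0.04 (dropped), 0.5 (kept), 0.95 -> MAF 0.05 (dropped, strict)
  g <- make_geno(cbind(c(rep(0L, 46), rep(1L, 4)),
                       rep(c(0L, 2L), 25),
                       c(rep(2L, 45), rep(1L, 5))))
  f <- allele_frequencies(g)
  expect_equal(unname(f), c(0.04, 0.5, 0.95))
  gf <- filter_maf(g, 0.05)
  expect_equal(n_loci(gf), 1L)
  expect_equal(unname(allele_frequencies(gf)), 0.5)
})

test_that("mean-depth percentile cap uses the linear-interpolation convention", {
  calls <- matrix(1L, nrow = 4, ncol = 10,
                  dimnames = list(letters[1:4], NULL))
  depth <- matrix(rep(1:10, each = 4), nrow = 4)
  g <- make_geno(calls, depth = depth)
  expect_equal(g$loci$mean_depth, as.numeric(1:10))
  gf <- filter_depth_percentile(g, 90)
  # 90th percentile of 1..10 (type 7) is 9.1: only depth 10 is above
  expect_equal(n_loci(gf), 9L)
  expect_false(10 %in% gf$loci$mean_depth)
  # all-equal depths and percentile 100 are identities
  gsame <- make_geno(calls, depth = matrix(5L, 4, 10))
  expect_equal(n_loci(filter_depth_percentile(gsame, 90)), 10L)
  expect_equal(n_loci(filter_depth_percentile(g, 100)), 10L)
  # no depth at all: skipped with a warning
  gnd <- make_geno(calls)
  expect_warning(gf2 <- filter_depth_percentile(gnd, 90), "skipped")
  expect_equal(n_loci(gf2), 10L)
})

test_that("HWE exact test agrees with the multinomial enumeration oracle", {
  expect_equal(hwe_exact_test(30, 0, 0), 1)            # monomorphic
  expect_gte(hwe_exact_test(25, 50, 25), 0.5)          # ideal proportions
  expect_lt(hwe_exact_test(0, 50, 0), 1e-4)            # all-het excess

  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    x <- stats::rmultinom(1, n, prob = stats::runif(3))
    p_pkg <- hwe_exact_test(x[1], x[2], x[3])
    p_orc <- hwe_oracle(x[1], x[2], x[3])
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
    p_pkg1 <- hwe_exact_test(x[1], x[2], x[3], "excess.het")
    p_orc1 <- hwe_oracle(x[1], x[2], x[3], "excess.het")
    expect_equal(p_pkg1, p_orc1, tolerance = 1e-12)
  }
})

test_that("HWE locus filter drops extreme deviations only", {
  # 25 samples all heterozygous: p far below 1e-4
  het_col <- rep(1L, 26)
  hwe_col <- c(rep(0L, 6), rep(1L, 13), rep(2L, 7))
  g <- make_geno(cbind(het_col, hwe_col),
                 pos = c(1000L, 2000L))
  expect_lt(hwe_pvalues(g)[1], 1e-4)
  gf <- filter_hwe(g, 1e-4)
  expect_equal(n_loci(gf), 1L)
  # alpha 0 disables the filter
  expect_equal(n_loci(filter_hwe(g, 0)), 2L)
})

test_that("LD pruning removes correlated loci and satisfies its postcondition", {
  set.seed(13)
  base <- matrix(sample(0:2, 40 * 20, TRUE), nrow = 40,
                 dimnames = list(sprintf("s%02d", 1:40), NULL))
  base[, 5] <- base[, 4]                # duplicated column
  g <- make_geno(base)
  gp <- ld_prune(g, window = 10, step = 3, r2_max = 0.5)
  expect_lt(n_loci(gp), n_loci(g))
  expect_true(ld_postcondition_ok(gp, 10, 3, 0.5))

  # three identical columns collapse to exactly one
  tri <- matrix(sample(0:2, 30 * 3, TRUE), nrow = 30,
                dimnames = list(sprintf("s%02d", 1:30), NULL))
  tri[, 2] <- tri[, 1]; tri[, 3] <- tri[, 1]
  gt <- ld_prune(make_geno(tri), window = 10, step = 3, r2_max = 0.5)
  expect_equal(n_loci(gt), 1L)

  # orthogonal columns are untouched
  orth <- cbind(rep(c(0L, 2L), each = 8),
                rep(rep(c(0L, 2L), each = 4), 2),
                rep(rep(c(0L, 2L), each = 2), 4))
  rownames(orth) <- sprintf("s%02d", 1:16)
  go <- ld_prune(make_geno(orth), window = 10, step = 3, r2_max = 0.5)
  expect_equal(n_loci(go), 3L)
})

test_that("every filter is idempotent at fixed parameters", {
  set.seed(55)
  calls <- matrix(sample(c(0:2, NA), 60 * 40, TRUE,
                         prob = c(.35, .2, .35, .1)),
                  nrow = 60, dimnames = list(sprintf("s%02d", 1:60), NULL))
  depth <- matrix(rpois(60 * 40, 30), nrow = 60)
  g <- make_geno(calls, pos = cumsum(sample(5:20, 40, TRUE)),
                 depth = depth)
  # the depth-percentile cap is excluded: re-applying an order-statistic
  # filter recomputes the percentile on the survivors, so it is one-shot
  # by construction (percentile 100 is its identity case)
  filters <- list(
    function(x) thin_by_distance(x, 10L),
    function(x) filter_missingness(x, 0.2),
    function(x) suppressWarnings(filter_maf(x, 0.05)),
    function(x) filter_hwe(x, 1e-4),
    function(x) ld_prune(x, 10, 3, 0.5))
  for (f in filters) {
    once <- f(g)
    twice <- f(once)
    expect_identical(twice$calls, once$calls)
    expect_identical(twice$loci, once$loci)
  }
})

test_that("the cascade runs in the documented order and logs survivor counts", {
  sim <- simulate_collection(sim_config(n_loci = 300L, n_founders = 25L,
                                        clone_group_sizes = 2L,
                                        n_parent_offspring_pairs = 2L,
                                        n_triploids = 3L, seed = 5))
  fc <- filter_cascade(sim$geno, depth_percentile = NULL)
  expect_s3_class(fc$geno, "geno_matrix")
  expect_equal(fc$report$step, c("thin", "missingness", "hwe", "maf"))
  expect_true(all(fc$report$loci_after <= fc$report$loci_before))
  expect_true(all(fc$report$samples_after <= fc$report$samples_before))
  # steps chain: each step's input is the previous step's output
  expect_equal(fc$report$loci_before[-1],
               fc$report$loci_after[-nrow(fc$report)])
})
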