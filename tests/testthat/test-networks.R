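rec_df <- function(...) {
  m <- rbind(...)
  data.frame(id1 = m[, 1], id2 = m[, 2], pi_hat = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

test_that("band inclusivity follows the clone and first-degree conventions", {
  rec <- rec_df(c("A", "B", "0.86"), c("A", "C", "0.85"),
                c("B", "C", "0.43"), c("C", "D", "0.52"),
                c("A", "D", "0.425"))
  cl <- clone_network(rec, threshold = 0.85)
  expect_equal(edge_keys(cl$edges$id1, cl$edges$id2), "A B")  # 0.85 excluded
  fd <- first_degree_network(rec, 0.43, 0.52)
  expect_setequal(edge_keys(fd$edges$id1, fd$edges$id2),
                  c("B C", "C D"))                  # both bounds included
  # isolated nodes are retained
  net <- build_network(rec, 0.9, 1, nodes = c("A", "B", "C", "D", "E"))
  expect_true("E" %in% net$nodes)
  expect_equal(nrow(net$edges), 0L)
  expect_error(build_network(rec[0, ], 0.4, 0.5), "node list")
})

test_that("connected components partition the node set", {
  rec <- rec_df(c("A", "B", "0.9"), c("B", "C", "0.9"))
  net <- build_network(rec, 0.85, 1, nodes = c("A", "B", "C", "D"))
  comp <- net$components
  expect_setequal(comp$node, c("A", "B", "C", "D"))
  abc <- comp$component[match(c("A", "B", "C"), comp$node)]
  expect_equal(length(unique(abc)), 1L)
  expect_equal(comp$size[comp$node == "D"], 1L)
  # no edges: all singletons
  net0 <- build_network(rec, 0.99, 1, nodes = c("A", "B"))
  expect_true(all(net0$components$size == 1L))
  # complete graph on 15 nodes is one component of 15
  ids <- sprintf("n%02d", 1:15)
  pairs <- t(combn(ids, 2))
  reck <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], pi_hat = 0.95,
                     stringsAsFactors = FALSE)
  netk <- clone_network(reck)
  expect_true(all(netk$components$size == 15L))
  # every member of the 15-clique has degree 14
  dd <- degree_distribution(netk)
  expect_true(all(dd$degrees$degree == 14L))
})

test_that("representative selection keeps one node per clonal group", {
  rec <- rec_df(c("A", "B", "0.9"))
  net <- build_network(rec, 0.85, 1, nodes = c("A", "B", "C"))
  kept <- select_representatives(net$components, rule = "random", seed = 1)
  expect_equal(length(kept), 2L)
  expect_true("C" %in% kept)
  expect_equal(sum(c("A", "B") %in% kept), 1L)
  # lexicographic rule is deterministic
  kept_lex <- select_representatives(net$components, "lexicographic")
  expect_setequal(kept_lex, c("A", "C"))
  # all singletons: identity
  net0 <- build_network(rec, 0.99, 1, nodes = c("A", "B"))
  expect_setequal(select_representatives(net0$components, "lexicographic"),
                  c("A", "B"))
  # seeded random rule is reproducible
  k1 <- select_representatives(net$components, "random", seed = 42)
  k2 <- select_representatives(net$components, "random", seed = 42)
  expect_identical(k1, k2)
})

test_that("degree distribution separates isolated from connected nodes", {
  rec <- rec_df(c("A", "B", "0.9"), c("A", "C", "0.9"), c("A", "D", "0.9"))
  net <- build_network(rec, 0.85, 1, nodes = c("A", "B", "C", "D", "E"))
  dd <- degree_distribution(net)
  deg <- setNames(dd$degrees$degree, dd$degrees$node)
  expect_equal(unname(deg[c("A", "B", "C", "D", "E")]),
               c(3L, 1L, 1L, 1L, 0L))
  expect_equal(dd$n_isolated, 1L)
  expect_equal(dd$n_connected, 4L)
})

test_that("edge-set comparison returns intersection and differences", {
  ea <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"))
  eb <- data.frame(id1 = c("C", "C"), id2 = c("B", "D"))
  cmp <- compare_networks(ea, eb)
  expect_equal(edge_keys(cmp$shared$id1, cmp$shared$id2), "B C")
  expect_equal(edge_keys(cmp$only_a$id1, cmp$only_a$id2), "A B")
  expect_equal(edge_keys(cmp$only_b$id1, cmp$only_b$id2), "C D")
  ident <- compare_networks(ea, ea)
  expect_equal(nrow(ident$shared), 2L)
  expect_equal(nrow(ident$only_a), 0L)
  disj <- compare_networks(ea, data.frame(id1 = "X", id2 = "Y"))
  expect_equal(nrow(disj$shared), 0L)
})

test_that("clone components recover simulated truth over many seeds", {
  for (seed in 1:20) {
    sim <- simulate_collection(
      sim_config(n_loci = 3000L, n_founders = 20L,
                 clone_group_sizes = c(4L, 3L, 2L, 2L),
                 n_parent_offspring_pairs = 3L, n_triploids = 4L,
                 error_rate = 0.005, missing_rate = 0.03, seed = seed))
    rec <- pairwise_ibd(sim$geno)
    net <- clone_network(rec, nodes = sample_ids(sim$geno))
    comp <- net$components
    got <- split(comp$node, comp$component)
    got <- got[vapply(got, length, 1L) > 1]
    tr <- sim$truth$samples
    want <- split(tr$sample_id[!is.na(tr$clone_group)],
                  tr$clone_group[!is.na(tr$clone_group)])
    norm <- function(l) sort(unname(vapply(
      l, function(x) paste(sort(x), collapse = ","), "")))
    expect_identical(norm(got), norm(want))
  }
})

test_that("the first-degree band is sensitive to true parent-offspring pairs", {
  hits <- 0L; total <- 0L; false_edges <- 0L; unrel_pairs <- 0L
  for (seed in 1:5) {
    sim <- simulate_collection(
      sim_config(n_loci = 5000L, n_founders = 24L,
                 clone_group_sizes = integer(0),
                 n_parent_offspring_pairs = 6L, n_triploids = 0L,
                 error_rate = 0, missing_rate = 0, seed = 100 + seed))
    rec <- pairwise_ibd(sim$geno)
    net <- first_degree_network(rec, nodes = sample_ids(sim$geno))
    ek <- edge_keys(net$edges$id1, net$edges$id2)
    po <- sim$truth$parent_offspring
    pk <- edge_keys(po$parent, po$child)
    hits <- hits + sum(pk %in% ek)
    total <- total + length(pk)
    tr <- sim$truth$samples
    founders <- tr$sample_id[tr$role == "founder"]
    unrel <- t(combn(founders, 2))
    uk <- edge_keys(unrel[, 1], unrel[, 2])
    false_edges <- false_edges + sum(uk %in% ek)
    unrel_pairs <- unrel_pairs + length(uk)
  }
  expect_gte(hits / total, 0.95)
  expect_lt(false_edges / unrel_pairs, 0.01)
})

test_that("no pair above the clone threshold survives deduplication", {
  sim <- simulate_collection(
    sim_config(n_loci = 3000L, n_founders = 15L,
               clone_group_sizes = c(3L, 2L),
               n_parent_offspring_pairs = 0L, n_triploids = 0L,
               error_rate = 0.002, missing_rate = 0.02, seed = 9))
  rec <- pairwise_ibd(sim$geno)
  net <- clone_network(rec, nodes = sample_ids(sim$geno))
  kept <- select_representatives(net$components, "random", seed = 9)
  g2 <- subset_samples(sim$geno, sample_ids(sim$geno) %in% kept)
  rec2 <- pairwise_ibd(g2)
  expect_true(all(rec2$pi_hat <= 0.85))
})
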