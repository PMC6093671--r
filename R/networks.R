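#' Threshold a relatedness table into a relationship network
#'
#' An undirected edge joins every pair whose pi-hat falls in the band
#' \[`low`, `high`\]; band inclusivity is configurable. The clone
#' convention is left-open (`pi_hat > 0.85`, strict as printed), the
#' first-degree convention closed at both ends (0.43 to 0.52 inclusive).
#' Samples without any in-band pair remain as isolated nodes.
#'
#' @param records a `relatedness_table` from [pairwise_ibd()] (or any
#'   data frame with `id1`, `id2`, `pi_hat`).
#' @param low,high band bounds, `low < high`.
#' @param include_low,include_high whether each bound is inclusive.
#' @param nodes optional node ID set; defaults to all IDs appearing in
#'   `records`. Required when `records` is empty.
#' @return An object of class `relationship_network`: list with `nodes`,
#'   `edges` (id1, id2, pi_hat), `band`, `components` (data frame node /
#'   component / size).
#' @export
build_network <- function(records, low, high,
                          include_low = TRUE, include_high = TRUE,
                          nodes = NULL) {
  if (low >= high) stop("band must satisfy low < high")
  if (is.null(nodes)) {
    if (nrow(records) == 0L)
      stop("empty record set and no node list supplied")
    nodes <- sort(unique(c(records$id1, records$id2)))
  }
  pv <- records$pi_hat
  lo <- if (include_low) pv >= low else pv > low
  hi <- if (include_high) pv <= high else pv < high
  sel <- !is.na(pv) & lo & hi
  edges <- records[sel, c("id1", "id2", "pi_hat"), drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges,
                        band = c(low = low, high = high),
                        include = c(low = include_low, high = include_high),
                        components = NULL),
                   class = "relationship_network")
  net$components <- connected_components(net)
  net
}

#' @rdname build_network
#' @param threshold clone threshold (edge iff `pi_hat > threshold`).
#' @export
clone_network <- function(records, threshold = 0.85, nodes = NULL)
  build_network(records, low = threshold, high = 1,
                include_low = FALSE, include_high = TRUE, nodes = nodes)

#' @rdname build_network
#' @export
first_degree_network <- function(records, low = 0.43, high = 0.52,
                                 nodes = NULL)
  build_network(records, low = low, high = high,
                include_low = TRUE, include_high = TRUE, nodes = nodes)

#' Connected components of a relationship network
#'
#' @param net a `relationship_network`.
#' @return Data frame with `node`, `component` (integer label) and
#'   `size`; singletons are their own components.
#' @export
connected_components <- function(net) {
  gr <- igraph::graph_from_data_frame(
    net$edges[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  comp <- igraph::components(gr)
  data.frame(node = igraph::V(gr)$name,
             component = unname(comp$membership),
             size = unname(comp$csize[comp$membership]),
             stringsAsFactors = FALSE)
}

#' Keep one representative per clonal group
#'
#' Singletons are always kept; from every multi-node component exactly
#' one node is retained, chosen at random (seeded) or as the
#' lexicographic minimum for fully deterministic output.
#'
#' @param components component data frame from [connected_components()].
#' @param rule `"random"` or `"lexicographic"`.
#' @param seed seed for the random rule.
#' @return Character vector of kept node IDs (in input node order).
#' @export
select_representatives <- function(components,
                                   rule = c("random", "lexicographic"),
                                   seed = NULL) {
  rule <- match.arg(rule)
  if (rule == "random" && !is.null(seed)) set.seed(seed)
  kept <- character(0)
  for (comp in split(components$node, components$component)) {
    kept <- c(kept,
              if (length(comp) == 1L) comp
              else if (rule == "lexicographic") min(comp)
              else sample(comp, 1L))
  }
  components$node[components$node %in% kept]
}

#' Degree distribution of a relationship network
#'
#' @param net a `relationship_network`.
#' @return List with `degrees` (data frame node / degree), `histogram`
#'   (table of degree counts), `n_isolated` (degree 0) and `n_connected`
#'   (degree >= 1).
#' @export
degree_distribution <- function(net) {
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$id1, net$edges$id2))
    deg[names(tab)] <- as.integer(tab)
  }
  list(degrees = data.frame(node = names(deg), degree = unname(deg),
                            stringsAsFactors = FALSE),
       histogram = table(degree = deg),
       n_isolated = sum(deg == 0L),
       n_connected = sum(deg >= 1L))
}

#' Compare two edge sets
#'
#' Unordered-edge set algebra for cross-marker comparisons (e.g. SNP- vs
#' SSR-derived first-degree edges).
#'
#' @param edges_a,edges_b data frames with columns `id1`, `id2`.
#' @return List of data frames `shared`, `only_a`, `only_b`.
#' @export
compare_networks <- function(edges_a, edges_b) {
  key <- function(e) {
    if (nrow(e) == 0L) return(character(0))
    paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2), sep = "\r")
  }
  ka <- key(edges_a); kb <- key(edges_b)
  unkey <- function(k) {
    if (!length(k))
      return(data.frame(id1 = character(0), id2 = character(0),
                        stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(id1 = parts[, 1L], id2 = parts[, 2L],
               stringsAsFactors = FALSE)
  }
  list(shared = unkey(intersect(ka, kb)),
       only_a = unkey(setdiff(ka, kb)),
       only_b = unkey(setdiff(kb, ka)))
}

#' @export
print.relationship_network <- function(x, ...) {
  sizes <- x$components$size[!duplicated(x$components$component)]
  cat("relationship_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges in band [",
      x$band["low"], ",", x$band["high"], "]\n")
  cat("  components:", length(sizes), "(largest:", max(sizes), ")\n")
  invisible(x)
}
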