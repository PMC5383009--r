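#' Construct a protein interaction network
#'
#' Builds the undirected simple graph used throughout the package. Nodes are
#' proteins identified by UniProtKB accession; edges are binary interactions.
#' Self-loops and parallel edges are rejected rather than silently simplified,
#' since upstream curation ([dedupe_and_deloop()]) is responsible for removing
#' them and an unclean edge set here indicates a bookkeeping error.
#'
#' @param edges two-column character matrix or data frame of accession pairs;
#'   may have zero rows.
#' @param nodes optional character vector of accessions; isolated nodes not
#'   present in `edges` are kept. Defaults to the accessions in `edges`.
#' @return an `igraph` object (undirected, simple) with vertex attributes
#'   `name` (accession), `label` (display abbreviation, defaults to the
#'   accession), `category` (one of `in_vivo_amyloid`, `in_vitro_amyloid`,
#'   `amyloid_related`, `other`) and logical `hub`, `bottleneck` role flags.
#' @export
protein_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("`edges` must have two columns")
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loop in edge input; run dedupe_and_deloop() first")
    key <- canonical_pair_key(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key))
      stop("duplicate edge in input; run dedupe_and_deloop() first")
  }
  verts <- sort(unique(c(as.vector(edges), as.character(nodes))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$label <- verts
  igraph::V(g)$category <- "other"
  igraph::V(g)$hub <- FALSE
  igraph::V(g)$bottleneck <- FALSE
  g
}

#' @rdname protein_network
#' @param g object to test
#' @export
is_protein_network <- function(g) igraph::is_igraph(g) && !igraph::is_directed(g)

# canonical unordered-pair key: lexicographically sorted accessions
canonical_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

node_names <- function(g) igraph::V(g)$name

#' Edge density
#'
#' Fraction of possible edges present, 2m / (n(n-1)).
#'
#' @param network a protein network
#' @return density in \[0, 1\]
#' @export
network_density <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2L) stop("degenerate-graph: density needs at least 2 nodes")
  2 * igraph::ecount(network) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all unordered *connected* node pairs.
#' Pairs in different components are excluded from the average (the
#' NetworkAnalyzer convention), so a single CPL is defined even when small
#' components sit beside the giant one.
#'
#' @param network a protein network
#' @return mean hop count (>= 1), or `NA_real_` with a warning when no pair of
#'   distinct nodes is connected (the "no-paths" sentinel)
#' @export
characteristic_path_length <- function(network) {
  if (igraph::ecount(network) == 0L) {
    warning("no-paths: no connected node pair")
    return(NA_real_)
  }
  igraph::mean_distance(network, directed = FALSE, unconnected = TRUE)
}

#' Local and mean clustering coefficients
#'
#' Local value for a node of degree k >= 2 is 2 e_N / (k (k - 1)) where e_N
#' counts edges among its neighbors; nodes of degree < 2 score 0 by default
#' and are included in the network mean. `exclude_low_degree = TRUE` drops
#' degree < 2 nodes from the mean instead, for comparison with tools that use
#' that convention.
#'
#' @param network a protein network
#' @param exclude_low_degree drop degree < 2 nodes from the mean?
#' @return list with `local` (named numeric vector) and `mean`
#' @export
clustering_coefficients <- function(network, exclude_low_degree = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0L) return(list(local = numeric(0), mean = NA_real_))
  loc <- igraph::transitivity(network, type = "localundirected", isolates = "zero")
  names(loc) <- node_names(network)
  deg <- igraph::degree(network)
  loc[deg < 2L] <- 0
  mean_cc <- if (exclude_low_degree) {
    if (any(deg >= 2L)) mean(loc[deg >= 2L]) else NA_real_
  } else mean(loc)
  list(local = loc, mean = mean_cc)
}

#' Betweenness centrality
#'
#' Shortest-path betweenness over unordered pairs of other nodes, with equal
#' split across tied shortest paths. Returned raw and normalized by
#' (n-1)(n-2)/2, the number of pairs that could route through a node.
#'
#' @param network a protein network
#' @return list with numeric vectors `raw` and `normalized`, named by accession
#' @export
betweenness_centrality <- function(network) {
  n <- igraph::vcount(network)
  raw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  names(raw) <- node_names(network)
  norm <- if (n >= 3L) raw / ((n - 1) * (n - 2) / 2) else raw * NA_real_
  list(raw = raw, normalized = norm)
}

#' Shortest path length between two proteins
#'
#' @param network a protein network
#' @param source,target accessions present in the network
#' @return minimum hop count; 0 when `source == target`; `NA_integer_` when
#'   the nodes sit in different components (unreachable sentinel)
#' @export
shortest_path_length <- function(network, source, target) {
  nm <- node_names(network)
  if (!source %in% nm || !target %in% nm)
    stop("missing-node: ", paste(setdiff(c(source, target), nm), collapse = ", "))
  d <- igraph::distances(network, v = source, to = target)[1L, 1L]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

#' Connected components and the giant component
#'
#' `network_components()` partitions the node set into connected components.
#' `giant_component()` returns the induced subgraph on the largest component;
#' ties are broken toward the component containing the smallest accession.
#'
#' @param network a protein network
#' @return for `network_components()`, a list of character vectors of
#'   accessions (each sorted), ordered by decreasing size then smallest member;
#'   for `giant_component()`, a protein network
#' @export
network_components <- function(network) {
  comp <- igraph::components(network)
  groups <- split(node_names(network), comp$membership)
  groups <- lapply(groups, sort)
  first <- vapply(groups, `[`, character(1), 1L)
  groups[order(-lengths(groups), first)]
}

#' @rdname network_components
#' @export
giant_component <- function(network) {
  keep <- network_components(network)[[1L]]
  igraph::induced_subgraph(network, keep)
}

#' Neighborhood subnetwork
#'
#' Induced subgraph on a set of center proteins plus every node within
#' `radius` hops of any center — e.g. a chaperone and its first neighbors.
#'
#' @param network a protein network
#' @param centers character vector of accessions (must be in the network)
#' @param radius hop radius (default 1)
#' @return a protein network
#' @export
subnetwork <- function(network, centers, radius = 1L) {
  if (length(centers) == 0L) stop("empty-input: no center nodes given")
  nm <- node_names(network)
  if (!all(centers %in% nm))
    stop("missing-node: ", paste(setdiff(centers, nm), collapse = ", "))
  hood <- igraph::ego(network, order = radius, nodes = centers)
  keep <- sort(unique(unlist(lapply(hood, function(v) v$name))))
  igraph::induced_subgraph(network, keep)
}

#' Full topology summary
#'
#' One-stop summary consumed by downstream reporting: size, density, mean
#' clustering coefficient, characteristic path length, degree histogram,
#' betweenness values and component structure.
#'
#' @param network a protein network
#' @return object of class `topology_summary`
#' @export
topology_summary <- function(network) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  deg <- igraph::degree(network)
  hist <- table(factor(deg, levels = sort(unique(deg))))
  comps <- network_components(network)
  out <- list(
    n = n, m = m,
    density = if (n >= 2L) network_density(network) else NA_real_,
    cc = clustering_coefficients(network)$mean,
    cpl = if (m > 0L) characteristic_path_length(network) else NA_real_,
    degree = deg,
    degree_histogram = stats::setNames(as.integer(hist), names(hist)),
    betweenness = betweenness_centrality(network),
    n_components = length(comps),
    giant_component_size = if (length(comps)) length(comps[[1L]]) else 0L
  )
  structure(out, class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Protein network: n = %d nodes, m = %d edges\n", x$n, x$m))
  cat(sprintf("  density          %.4f\n", x$density))
  cat(sprintf("  clustering (CC)  %.4f\n", x$cc))
  cat(sprintf("  path length (CPL) %.4f\n", x$cpl))
  cat(sprintf("  components       %d (giant: %d nodes)\n",
              x$n_components, x$giant_component_size))
  invisible(x)
}
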