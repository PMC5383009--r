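node_names_test <- function(g) igraph::V(g)$name

test_that("density, CPL, clustering and betweenness agree with hand-computed toy values", {
  # triangle
  tri <- protein_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(network_density(tri), 1.0)
  expect_equal(characteristic_path_length(tri), 1.0)
  expect_equal(clustering_coefficients(tri)$mean, 1.0)
  expect_equal(unname(betweenness_centrality(tri)$raw), c(0, 0, 0))

  # path A-B-C: distances 1,1,2; only B is an interior vertex
  path3 <- protein_network(rbind(c("A", "B"), c("B", "C")))
  expect_equal(characteristic_path_length(path3), 4 / 3)
  bc <- betweenness_centrality(path3)$raw
  expect_equal(bc[["B"]], 1)
  expect_equal(bc[["A"]], 0)

  # 4-node path: 3 edges of 6 possible
  path4 <- protein_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_equal(network_density(path4), 0.5)

  # star: center's neighbors unconnected, leaves have degree 1
  star <- protein_network(rbind(c("C0", "L1"), c("C0", "L2"), c("C0", "L3")))
  expect_equal(unname(clustering_coefficients(star)$local), rep(0, 4))

  # complete K4 and K5
  k_edges <- function(nm) t(utils::combn(nm, 2))
  k4 <- protein_network(k_edges(LETTERS[1:4]))
  expect_equal(characteristic_path_length(k4), 1.0)
  k5 <- protein_network(k_edges(LETTERS[1:5]))
  expect_equal(unname(betweenness_centrality(k5)$raw), rep(0, 5))

  # two disjoint edges: CPL averages the two intra-edge pairs only
  disj <- protein_network(rbind(c("A", "B"), c("C", "D")))
  expect_equal(characteristic_path_length(disj), 1.0)
})

test_that("CPL, clustering and betweenness match exhaustive oracles on every graph with <= 5 nodes", {
  for (n in 2:5) {
    for (adj in all_graphs(n)) {
      net <- network_from_adjacency(adj)
      if (sum(adj) > 0) {
        expect_equal(characteristic_path_length(net), oracle_cpl(adj))
      }
      expect_equal(unname(clustering_coefficients(net)$local),
                   oracle_local_clustering(adj))
      expect_equal(unname(betweenness_centrality(net)$raw),
                   oracle_betweenness(adj), tolerance = 1e-12)
    }
  }
})

test_that("CPL, clustering and betweenness match oracles on random graphs up to 12 nodes", {
  cases <- 0L
  for (seed in 1:50) {
    n <- 6L + (seed %% 7L)  # 6..12
    net <- random_network(n, p = 0.3, seed = seed)
    adj <- adjacency_of(net)
    if (sum(adj) == 0) next
    cases <- cases + 1L
    expect_equal(characteristic_path_length(net), oracle_cpl(adj))
    expect_equal(unname(clustering_coefficients(net)$local),
                 oracle_local_clustering(adj))
    expect_equal(unname(betweenness_centrality(net)$raw),
                 oracle_betweenness(adj), tolerance = 1e-10)
  }
  expect_gte(cases, 45L)
})

test_that("clustering mean: 30-node graph equals brute-force enumeration, both conventions", {
  net <- random_network(30, p = 0.2, seed = 99)
  adj <- adjacency_of(net)
  loc <- oracle_local_clustering(adj)
  expect_equal(clustering_coefficients(net)$mean, mean(loc))
  deg <- rowSums(adj)
  expect_equal(clustering_coefficients(net, exclude_low_degree = TRUE)$mean,
               mean(loc[deg >= 2]))
})

test_that("betweenness normalization preserves rank order and uses (n-1)(n-2)/2", {
  net <- random_network(15, p = 0.3, seed = 7)
  bc <- betweenness_centrality(net)
  expect_equal(order(bc$raw), order(bc$normalized))
  expect_equal(bc$normalized, bc$raw / (14 * 13 / 2))
})

test_that("shortest_path_length handles the two-step relay, self pairs and unreachable pairs", {
  # encoded relay: amyloid-beta reaches transthyretin via apolipoprotein A-I
  relay <- protein_network(rbind(c("P05067", "P02647"), c("P02647", "P02766")))
  expect_identical(shortest_path_length(relay, "P05067", "P02766"), 2L)
  expect_identical(shortest_path_length(relay, "P05067", "P05067"), 0L)
  two_comp <- protein_network(rbind(c("A", "B"), c("C", "D")))
  expect_true(is.na(shortest_path_length(two_comp, "A", "C")))
  expect_error(shortest_path_length(relay, "P05067", "ZZZ"), "missing-node")
})

test_that("components and giant component: sizes, tie-break, dyad separation", {
  two_tri <- protein_network(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                                   c("X", "Y"), c("Y", "Z"), c("X", "Z")))
  comps <- network_components(two_tri)
  expect_length(comps, 2L)
  expect_equal(unname(lengths(comps)), c(3L, 3L))
  # equal sizes: tie toward smallest member accession
  expect_equal(comps[[1L]], c("A", "B", "C"))
  expect_equal(sort(node_names_test(giant_component(two_tri))), c("A", "B", "C"))

  # a seed attached only to one private partner stays a separate dyad
  dyad <- protein_network(rbind(c("S1", "X"), c("X", "Y"), c("P01236", "PRLR")))
  comps <- network_components(dyad)
  expect_length(comps, 2L)
  expect_true(any(vapply(comps, identical, logical(1), c("P01236", "PRLR"))))

  conn <- protein_network(rbind(c("A", "B"), c("B", "C")))
  expect_length(network_components(conn), 1L)
})

test_that("subnetwork returns centers plus all nodes within the radius", {
  star <- protein_network(rbind(c("C0", "L1"), c("C0", "L2"), c("C0", "L3")))
  expect_equal(sort(node_names_test(subnetwork(star, "C0", 1))),
               c("C0", "L1", "L2", "L3"))
  path5 <- protein_network(cbind(paste0("P", 1:4), paste0("P", 2:5)))
  expect_equal(sort(node_names_test(subnetwork(path5, "P1", 1))), c("P1", "P2"))
  expect_error(subnetwork(star, character(0)), "empty-input")
  # random graph: node set equals brute-force neighbor union
  net <- random_network(20, p = 0.2, seed = 5)
  adj <- adjacency_of(net)
  centers <- c("N003", "N011")
  idx <- match(centers, sprintf("N%03d", 1:20))
  want <- sort(unique(c(centers, sprintf("N%03d", which(colSums(adj[idx, , drop = FALSE]) > 0)))))
  expect_equal(sort(node_names_test(subnetwork(net, centers, 1))), want)
})

test_that("degree sum equals 2m and density stays in [0,1] across generated graphs", {
  for (seed in 1:10) {
    net <- random_network(10 + seed, p = 0.25, seed = seed)
    expect_equal(sum(igraph::degree(net)), 2 * igraph::ecount(net))
    if (igraph::vcount(net) >= 2) {
      d <- network_density(net)
      expect_gte(d, 0); expect_lte(d, 1)
    }
  }
})

test_that("degenerate inputs signal the documented conditions", {
  single <- protein_network(matrix(character(0), 0, 2), nodes = "A")
  expect_error(network_density(single), "degenerate-graph")
  none <- protein_network(matrix(character(0), 0, 2), nodes = c("A", "B"))
  expect_warning(cpl <- characteristic_path_length(none), "no-paths")
  expect_true(is.na(cpl))
  expect_error(protein_network(rbind(c("A", "A"))), "self-loop")
  expect_error(protein_network(rbind(c("A", "B"), c("B", "A"))), "duplicate")
})
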