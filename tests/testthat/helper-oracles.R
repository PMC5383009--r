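# Independent brute-force oracles. Everything here works from a plain
# adjacency matrix and base R only, deliberately sharing no code path with
# the package implementations it checks.

adjacency_of <- function(network) {
  as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
}

# all-pairs shortest-path hop counts by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# mean distance over unordered connected pairs of distinct nodes
oracle_cpl <- function(adj) {
  d <- oracle_distances(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

# local clustering by explicit neighbor-pair enumeration; degree < 2 -> 0
oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (adj[nb[i], nb[j]] > 0) links <- links + 1L
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# betweenness by exhaustive enumeration of every shortest path: for each
# ordered pair (s, t), recursively list all shortest paths from the distance
# matrix and give each interior vertex 1/(number of paths) per unordered pair
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bc <- numeric(n)
  all_shortest_paths <- function(s, t) {
    if (s == t) return(list(s))
    preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
    out <- list()
    for (p in preds)
      out <- c(out, lapply(all_shortest_paths(s, p), function(path) c(path, t)))
    out
  }
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(d[s, t]) || d[s, t] < 2) next
    paths <- all_shortest_paths(s, t)
    w <- 1 / length(paths)
    for (path in paths) {
      interior <- path[-c(1L, length(path))]
      bc[interior] <- bc[interior] + w
    }
  }
  bc
}

# exact hypergeometric upper tail by direct summation of binomial terms
oracle_hypergeom_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand-applied BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1L):1L) if (m > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  pmin(adj, 1)[order(o)]
}

# independent minimal MCL: same matrix conventions, different code and a
# different cluster-extraction rule (components of the limit nonzero
# structure instead of attractor-system mass assignment)
oracle_mcl_membership <- function(adj, inflation = 1.8, expansion = 2L,
                                  self_loop = 1, prune = 1e-5, tol = 1e-8,
                                  maxit = 100L) {
  A <- adj
  diag(A) <- diag(A) + self_loop
  renorm <- function(M) {
    cs <- colSums(M); cs[cs == 0] <- 1
    t(t(M) / cs)
  }
  M <- renorm(A)
  for (it in seq_len(maxit)) {
    prev <- M
    P <- M
    for (e in seq_len(expansion - 1L)) P <- P %*% M
    M <- renorm(P^inflation)
    M[M < prune] <- 0
    M <- renorm(M)
    if (max(abs(M - prev)) < tol) break
  }
  S <- (M + t(M)) > 0
  comp <- integer(nrow(M))
  cid <- 0L
  for (v in seq_len(nrow(M))) {
    if (comp[v] > 0L) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[u] == 0L) {
        comp[u] <- cid
        stack <- c(stack, which(S[u, ] & comp == 0L))
      }
    }
  }
  comp
}

# brute-force DAG reachability (ancestors of each term) by repeated squaring
oracle_ancestors <- function(parent_edges, terms) {
  # parent_edges: data.frame(term, parent)
  reach <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    seen <- character(0)
    frontier <- parent_edges$parent[parent_edges$term == t]
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- unique(unlist(lapply(frontier, function(x)
        parent_edges$parent[parent_edges$term == x])))
      frontier <- setdiff(frontier, seen)
    }
    reach[[t]] <- seen
  }
  reach
}

# adjusted Rand index between two labelings (pair-counting definition)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# random simple graph as a protein network (G(n, p), named nodes)
random_network <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  network_from_adjacency(adj)
}

network_from_adjacency <- function(adj) {
  n <- nrow(adj)
  nm <- sprintf("N%03d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  protein_network(cbind(nm[idx[, 1L]], nm[idx[, 2L]]), nodes = nm)
}

# enumerate every labelled graph on n nodes as adjacency matrices
all_graphs <- function(n) {
  npairs <- n * (n - 1L) / 2L
  lapply(0:(2^npairs - 1L), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- bits
    adj + t(adj)
  })
}
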