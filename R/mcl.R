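#' MCL parameter set
#'
#' Parameters of the Markov Clustering algorithm. Inflation r controls
#' granularity: larger values fragment the graph into more, smaller clusters.
#' r = 1.8 is the conventional setting for protein interaction networks —
#' values above it tend to over-fragment biological networks. Expansion e is
#' the matrix-power step (random-walk length per iteration), self_loop_weight
#' is added to the diagonal before normalization so walks can stay put,
#' prune_threshold zeroes negligible entries to keep the iteration stable,
#' and convergence is declared when the flow matrix changes by less than
#' `convergence_tol` in max-norm.
#'
#' @param inflation inflation exponent r > 1 (default 1.8)
#' @param expansion matrix power e >= 2 (default 2)
#' @param self_loop_weight diagonal weight added before normalization
#'   (default 1)
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5)
#' @param convergence_tol max-norm change declaring convergence (default 1e-8)
#' @param max_iterations iteration cap (default 100)
#' @return an `mcl_params` list
#' @export
mcl_params <- function(inflation = 1.8, expansion = 2L, self_loop_weight = 1,
                       prune_threshold = 1e-5, convergence_tol = 1e-8,
                       max_iterations = 100L) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2L) stop("expansion must be >= 2")
  if (prune_threshold < 0) stop("prune_threshold must be >= 0")
  if (convergence_tol <= 0 || max_iterations < 1L)
    stop("tolerances must be positive")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop_weight = self_loop_weight,
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "mcl_params")
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1  # a fully pruned column: leave it zero rather than divide by 0
  sweep(M, 2L, cs, "/")
}

#' Markov Clustering (MCL)
#'
#' Native dense-matrix implementation of the MCL graph-clustering algorithm.
#' The column-stochastic flow matrix is built from the unweighted adjacency
#' matrix plus `self_loop_weight` on the diagonal; each iteration applies
#' expansion (matrix power `e`), inflation (entrywise power `r` followed by
#' column renormalization) and pruning of entries below the threshold
#' (followed by renormalization), until the matrix changes by less than the
#' convergence tolerance or the iteration cap is reached. Clusters are read
#' off the limit matrix: rows with retained mass are attractors, attractors
#' sharing a column belong to one attractor system, and every node is
#' assigned to the system receiving the largest share of its column mass
#' (ties toward the system containing the smallest accession). Flow cannot
#' cross connected components, so disconnected parts are never merged.
#'
#' @param network a non-empty protein network
#' @param params an [mcl_params()] set
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   accession vectors, decreasing size, each sorted), `params`,
#'   `iterations_used`, `converged`, `membership` (named integer vector)
#' @export
mcl_cluster <- function(network, params = mcl_params()) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty-input: network has no nodes")
  nm <- node_names(network)
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
  dimnames(A) <- list(nm, nm)
  diag(A) <- diag(A) + params$self_loop_weight
  M <- normalize_columns(A)

  converged <- FALSE
  iter <- 0L
  colsum_dev <- 0  # worst column-sum deviation after any inflation step
  for (iter in seq_len(params$max_iterations)) {
    M_prev <- M
    # expansion: e-th matrix power
    E <- M
    for (p in seq_len(params$expansion - 1L)) E <- E %*% M
    # inflation: entrywise power + column renormalization
    M <- normalize_columns(E^params$inflation)
    cs <- colSums(M)
    colsum_dev <- max(colsum_dev, max(abs(cs[cs > 0] - 1)))
    # pruning
    M[M < params$prune_threshold] <- 0
    M <- normalize_columns(M)
    if (max(abs(M - M_prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    message("MCL did not converge within ", params$max_iterations,
            " iterations; returning current partition")

  membership <- interpret_mcl_matrix(M, nm)
  clusters <- split(nm, membership)
  clusters <- lapply(clusters, sort)
  first <- vapply(clusters, `[`, character(1), 1L)
  clusters <- unname(clusters[order(-lengths(clusters), first)])
  memb <- integer(n); names(memb) <- nm
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  structure(list(clusters = clusters, params = params,
                 iterations_used = iter, converged = converged,
                 membership = memb, colsum_deviation = colsum_dev),
            class = "cluster_set")
}

# read a partition off the MCL limit matrix
interpret_mcl_matrix <- function(M, nm) {
  n <- nrow(M)
  attractors <- which(rowSums(M) > 0)
  if (length(attractors) == 0L) return(stats::setNames(seq_len(n), nm))
  # attractor systems: attractors co-occurring in any column are one system
  sys <- stats::setNames(seq_along(attractors), attractors)
  for (j in seq_len(n)) {
    rows <- attractors[M[attractors, j] > 0]
    if (length(rows) > 1L) {
      ids <- unique(sys[as.character(rows)])
      sys[sys %in% ids] <- min(ids)
    }
  }
  # merge attractors directly supporting each other (i attracted by i')
  for (i in attractors) {
    rows <- attractors[M[attractors, i] > 0]
    ids <- unique(c(sys[[as.character(i)]], sys[as.character(rows)]))
    if (length(ids) > 1L) sys[sys %in% ids] <- min(ids)
  }
  # assign every node to the system with the largest incoming mass;
  # ties toward the system containing the smallest accession
  sys_ids <- sort(unique(sys))
  memb <- integer(n)
  for (j in seq_len(n)) {
    mass <- vapply(sys_ids, function(s) {
      rows <- as.integer(names(sys)[sys == s])
      sum(M[rows, j])
    }, numeric(1))
    if (max(mass) == 0) {
      memb[j] <- -j  # isolated, fully pruned column: own singleton
    } else {
      best <- sys_ids[mass >= max(mass) - 1e-12]
      if (length(best) > 1L) {
        reps <- vapply(best, function(s) {
          rows <- as.integer(names(sys)[sys == s])
          min(nm[rows])
        }, character(1))
        best <- best[which.min(reps)]
      }
      memb[j] <- best[1L]
    }
  }
  stats::setNames(match(memb, sort(unique(memb))), nm)
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("MCL clustering (r = %.2f): %d clusters over %d nodes%s\n",
              x$params$inflation, length(sizes), sum(sizes),
              if (x$converged) sprintf(", converged in %d iterations",
                                       x$iterations_used)
              else " (NOT converged)"))
  cat("  sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Filter clusters by size
#'
#' Splits a cluster set into clusters with at least `min_size` members (kept,
#' in decreasing size order) and smaller ones (dropped but reported), the
#' usual pre-step before per-cluster enrichment: clusters of one or two
#' proteins carry too little signal to analyze.
#'
#' @param cluster_set a `cluster_set`
#' @param min_size minimum cluster size to keep (default 3)
#' @return list with `kept` and `dropped` (lists of accession vectors)
#' @export
filter_clusters <- function(cluster_set, min_size = 3L) {
  sizes <- lengths(cluster_set$clusters)
  list(kept = cluster_set$clusters[sizes >= min_size],
       dropped = cluster_set$clusters[sizes < min_size])
}

#' Inflation sweep
#'
#' Runs MCL once per inflation value (other parameters fixed) and tabulates
#' the granularity of each result; used to choose the inflation that avoids
#' over-fragmentation.
#'
#' @param network a protein network
#' @param inflations numeric vector of inflation values (non-empty)
#' @param params base [mcl_params()]; its inflation is overridden per run
#' @return data frame: `inflation`, `n_clusters`, `n_clusters_ge3`,
#'   `max_cluster_size`, `converged`
#' @export
inflation_sweep <- function(network, inflations = seq(1.8, 3.0, by = 0.2),
                            params = mcl_params()) {
  if (length(inflations) == 0L) stop("empty inflation list")
  rows <- lapply(inflations, function(r) {
    p <- params; p$inflation <- r
    cs <- mcl_cluster(network, p)
    sizes <- lengths(cs$clusters)
    data.frame(inflation = r, n_clusters = length(sizes),
               n_clusters_ge3 = sum(sizes >= 3L),
               max_cluster_size = max(sizes),
               converged = cs$converged)
  })
  do.call(rbind, rows)
}
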