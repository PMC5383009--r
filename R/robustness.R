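#' Lethality test: node removal trajectories
#'
#' Removes nodes one at a time — uniformly at random ("failure") or in
#' descending order of degree or betweenness centrality ("attack") — and
#' records the characteristic path length and giant-component fraction after
#' each removal. Attack order is by default computed once on the intact
#' network (`ranking_policy = "static"`); `"recomputed"` re-ranks after every
#' removal for sensitivity analysis. Failure trajectories are run once per
#' seed and averaged, with per-step standard deviation.
#'
#' When a removal leaves no connected pair, CPL is recorded as `NA` (the
#' no-paths sentinel) from that step on; otherwise CPL averages over the
#' remaining connected pairs.
#'
#' @param network a protein network with at least one edge
#' @param mode one of `"failure"`, `"degree_attack"`, `"betweenness_attack"`
#' @param max_fraction fraction of nodes to remove (default 0.2)
#' @param seeds integer vector of RNG seeds, required in failure mode (one
#'   trajectory per seed)
#' @param ranking_policy `"static"` (default) or `"recomputed"`
#' @return object of class `robustness_trajectory`: list with `mode`,
#'   `removed_fraction` (starting at 0), `cpl` (mean over seeds in failure
#'   mode), `cpl_sd` (failure mode only), `giant_fraction`, `seeds`,
#'   `ranking_policy`, `n0` initial node count
#' @export
lethality_test <- function(network,
                           mode = c("failure", "degree_attack", "betweenness_attack"),
                           max_fraction = 0.2, seeds = NULL,
                           ranking_policy = c("static", "recomputed")) {
  mode <- tryCatch(match.arg(mode), error = function(e)
    stop("invalid-mode: ", mode[1L]))
  ranking_policy <- match.arg(ranking_policy)
  if (igraph::ecount(network) == 0L)
    stop("no-paths: network has no connected pair")
  n0 <- igraph::vcount(network)
  n_steps <- max(1L, floor(max_fraction * n0))

  run_one <- function(order_fun) {
    g <- network
    cpl <- numeric(n_steps + 1L)
    giant <- numeric(n_steps + 1L)
    cpl[1L] <- characteristic_path_length(network)
    giant[1L] <- max(igraph::components(network)$csize) / n0
    static_order <- if (ranking_policy == "static") order_fun(g) else NULL
    for (s in seq_len(n_steps)) {
      victim <- if (ranking_policy == "static") static_order[s]
                else order_fun(g)[1L]
      g <- igraph::delete_vertices(g, victim)
      if (igraph::ecount(g) == 0L) {
        cpl[(s + 1L):(n_steps + 1L)] <- NA_real_
        giant[s + 1L] <- if (igraph::vcount(g))
          max(igraph::components(g)$csize) / n0 else 0
        if (s < n_steps) giant[(s + 2L):(n_steps + 1L)] <- NA_real_
        break
      }
      cpl[s + 1L] <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
      giant[s + 1L] <- max(igraph::components(g)$csize) / n0
    }
    list(cpl = cpl, giant = giant)
  }

  rank_by <- function(score_fun) function(g) {
    nm <- igraph::V(g)$name
    nm[order(-score_fun(g), nm)]
  }

  if (mode == "failure") {
    if (is.null(seeds) || length(seeds) == 0L)
      stop("missing-seeds: failure mode needs at least one seed")
    runs <- lapply(seeds, function(sd) {
      set.seed(sd)
      perm <- sample(node_names(network))
      run_one(function(g) perm[perm %in% igraph::V(g)$name])
    })
    cplm <- do.call(rbind, lapply(runs, `[[`, "cpl"))
    giantm <- do.call(rbind, lapply(runs, `[[`, "giant"))
    cpl <- colMeans(cplm)
    cpl_sd <- apply(cplm, 2L, stats::sd)
    giant <- colMeans(giantm)
  } else {
    score <- if (mode == "degree_attack") igraph::degree
             else function(g) igraph::betweenness(g, directed = FALSE)
    r <- run_one(rank_by(score))
    cpl <- r$cpl; giant <- r$giant; cpl_sd <- rep(NA_real_, length(cpl))
  }

  structure(list(
    mode = mode,
    removed_fraction = (0:n_steps) / n0,
    cpl = cpl, cpl_sd = cpl_sd, giant_fraction = giant,
    seeds = if (mode == "failure") as.integer(seeds) else integer(0),
    ranking_policy = ranking_policy, n0 = n0
  ), class = "robustness_trajectory")
}

#' Compare attack and failure trajectories
#'
#' Aligns trajectories from the same initial network into one table of
#' removed fraction vs CPL per mode, and computes an area-between-curves
#' statistic for every mode pair: the trapezoidal integral of
#' (CPL_mode1 - CPL_mode2) over the common removed-fraction range (positive
#' when mode1 degrades the network faster). Steps where either trajectory has
#' hit the no-paths sentinel are excluded from the area.
#'
#' @param trajectories list of `robustness_trajectory` objects on the same
#'   initial network
#' @return list with `table` (data frame: removed_fraction, one CPL column
#'   per mode) and `area` (data frame: mode_a, mode_b, area)
#' @export
attack_failure_report <- function(trajectories) {
  if (length(trajectories) < 2L)
    stop("need >= 2 trajectories to compare")
  n0 <- unique(vapply(trajectories, `[[`, numeric(1), "n0"))
  if (length(n0) != 1L)
    stop("incompatible-trajectories: different initial networks")
  len <- min(vapply(trajectories, function(t) length(t$cpl), integer(1)))
  frac <- trajectories[[1L]]$removed_fraction[seq_len(len)]
  modes <- vapply(trajectories, `[[`, character(1), "mode")
  if (anyDuplicated(modes))
    modes <- make.unique(modes, sep = "_")
  tab <- data.frame(removed_fraction = frac)
  for (i in seq_along(trajectories))
    tab[[modes[i]]] <- trajectories[[i]]$cpl[seq_len(len)]
  pairs <- utils::combn(seq_along(trajectories), 2L)
  area <- apply(pairs, 2L, function(ij) {
    d <- tab[[modes[ij[1L]]]] - tab[[modes[ij[2L]]]]
    ok <- !is.na(d)
    if (sum(ok) < 2L) return(NA_real_)
    x <- frac[ok]; y <- d[ok]
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  })
  list(table = tab,
       area = data.frame(mode_a = modes[pairs[1L, ]],
                         mode_b = modes[pairs[2L, ]],
                         area = area, stringsAsFactors = FALSE))
}
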