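#' Fit a power law to a histogram by log-log least squares
#'
#' Ordinary least squares of log10(value) on log10(x) over points with
#' positive x and positive value, the method network-analysis tools use for
#' degree distributions: `value = a * x^-gamma` with `a = 10^intercept` and
#' `gamma = -slope`. Zero-count bins are excluded (their log is undefined).
#' A maximum-likelihood exponent estimate for the discrete power law is
#' available via `method = "mle"`; note MLE estimates the exponent of the
#' sampled degrees directly and reports no prefactor or r-squared, and the
#' two methods generally disagree on noisy data.
#'
#' @param histogram named numeric vector: names are x values (e.g. degree k),
#'   values are positive heights (e.g. node counts P(k))
#' @param method `"ols"` (default) or `"mle"`
#' @return object of class `power_law_fit`: list with `a`, `gamma`,
#'   `r_squared`, `n_points`, `method`
#' @export
fit_power_law <- function(histogram, method = c("ols", "mle")) {
  method <- match.arg(method)
  x <- as.numeric(names(histogram))
  y <- as.numeric(histogram)
  keep <- !is.na(x) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("insufficient-points: need >= 3 positive (x, value) points")
  if (method == "mle") {
    # Hill-type estimator on degrees reconstructed from the histogram
    ks <- rep(x, times = round(y))
    kmin <- min(ks)
    gamma <- 1 + length(ks) / sum(log(ks / (kmin - 0.5)))
    fit <- list(a = NA_real_, gamma = gamma, r_squared = NA_real_,
                n_points = length(x), method = "mle")
    return(structure(fit, class = "power_law_fit"))
  }
  lx <- log10(x); ly <- log10(y)
  ols <- stats::lm(ly ~ lx)
  s <- suppressWarnings(summary(ols))  # "perfect fit" warning on exact laws
  fit <- list(a = 10^stats::coef(ols)[[1L]],
              gamma = -stats::coef(ols)[[2L]],
              r_squared = s$r.squared,
              n_points = length(x),
              method = "ols")
  structure(fit, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.power_law_fit <- function(x, var = "P(k)", ...) {
  sprintf("%s = %sk^-%s", var,
          format(round(x$a, 3), trim = TRUE),
          format(round(x$gamma, 3), trim = TRUE))
}

#' Degree-distribution fit for a network
#'
#' Tabulates the degree histogram P(k) (node counts per degree, k >= 1) and
#' fits the power law P(k) ~ k^-gamma.
#'
#' @param network a protein network
#' @param ... passed to [fit_power_law()]
#' @return a `power_law_fit`
#' @export
degree_distribution_fit <- function(network, ...) {
  deg <- igraph::degree(network)
  tab <- table(deg[deg > 0])
  fit_power_law(stats::setNames(as.numeric(tab), names(tab)), ...)
}

#' Classify the fitted degree exponent
#'
#' Scale-free networks have P(k) ~ k^-gamma; the regime depends on gamma:
#' below 2 the largest hubs swallow a finite fraction of all edges
#' (hub-dominated), between 2 and 3 is the classic scale-free regime, above 3
#' the tail is thin enough that the network behaves like a random graph.
#'
#' @param fit a `power_law_fit`
#' @return one of `"hub-dominated"`, `"classic scale-free"`, `"random-like tail"`
#' @export
degree_exponent_flag <- function(fit) {
  g <- fit$gamma
  if (g < 2) "hub-dominated"
  else if (g <= 3) "classic scale-free"
  else "random-like tail"
}

#' Clustering-degree scaling C(k)
#'
#' Computes the mean local clustering coefficient per degree class and fits
#' C(k) ~ k^-gamma. An exponent near 1 is the signature of hierarchical
#' modularity — densely clustered low-degree neighborhoods stitched together
#' by hubs.
#'
#' @param network a protein network
#' @return a `power_law_fit` (of the per-degree means), with the per-degree
#'   table attached as attribute `ck_table`
#' @export
ck_scaling <- function(network) {
  deg <- igraph::degree(network)
  loc <- clustering_coefficients(network)$local
  keep <- deg >= 2L
  ck <- tapply(loc[keep], deg[keep], mean)
  usable <- ck[ck > 0]
  if (length(usable) < 3L)
    stop("insufficient-points: need >= 3 degrees with positive mean clustering")
  fit <- fit_power_law(usable)
  attr(fit, "ck_table") <- data.frame(k = as.integer(names(ck)),
                                      mean_clustering = as.numeric(ck))
  fit
}

#' Erdos-Renyi null-model comparison
#'
#' Draws `replicates` uniform simple random graphs G(n, m) with exactly the
#' observed node and edge counts, computes mean clustering coefficient and
#' characteristic path length for each, and compares with the observed
#' values. The small-world verdict is: observed CC above the null mean AND
#' observed CPL at most the null mean plus two null standard deviations —
#' high transitivity without paying for it in path length.
#'
#' @param n,m node and edge counts of the observed network
#' @param cc_observed,cpl_observed observed statistics (optional; the verdict
#'   is `NA` when missing)
#' @param replicates number of random graphs (default 100)
#' @param seed RNG seed
#' @return object of class `null_model_comparison`
#' @export
null_model_comparison <- function(n, m, cc_observed = NA_real_,
                                  cpl_observed = NA_real_,
                                  replicates = 100L, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L || m < 0L || m > n * (n - 1L) / 2L)
    stop("invalid-parameters: need 2 <= n and 0 <= m <= n(n-1)/2")
  if (replicates < 1L) stop("invalid-parameters: replicates >= 1")
  set.seed(seed)
  cc <- numeric(replicates); cpl <- numeric(replicates)
  for (i in seq_len(replicates)) {
    g <- igraph::sample_gnm(n, m)
    loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    loc[igraph::degree(g) < 2L] <- 0
    cc[i] <- mean(loc)
    cpl[i] <- if (m > 0L)
      igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    else NA_real_
  }
  small_world <- if (is.na(cc_observed) || is.na(cpl_observed)) NA else
    (cc_observed > mean(cc)) &&
    (cpl_observed <= mean(cpl, na.rm = TRUE) + 2 * stats::sd(cpl))
  structure(list(
    replicates = replicates, seed = seed,
    cc_mean = mean(cc), cc_sd = stats::sd(cc),
    cpl_mean = mean(cpl, na.rm = TRUE), cpl_sd = stats::sd(cpl),
    cc_observed = cc_observed, cpl_observed = cpl_observed,
    small_world = small_world
  ), class = "null_model_comparison")
}

#' @export
print.null_model_comparison <- function(x, ...) {
  cat(sprintf("G(n,m) null model, %d replicates\n", x$replicates))
  cat(sprintf("  CC  observed %.4f vs null %.4f (sd %.4f)\n",
              x$cc_observed, x$cc_mean, x$cc_sd))
  cat(sprintf("  CPL observed %.4f vs null %.4f (sd %.4f)\n",
              x$cpl_observed, x$cpl_mean, x$cpl_sd))
  cat(sprintf("  small-world: %s\n", x$small_world))
  invisible(x)
}

#' Call hubs and bottlenecks
#'
#' Hubs are the top-N nodes by degree, bottlenecks the top-N by betweenness
#' centrality (defaults to the conventional N = 20). Ties at the cutoff are
#' broken by accession order; N larger than the network is clamped. The
#' returned network has the `hub` / `bottleneck` vertex roles updated.
#'
#' @param network a protein network
#' @param N list size (default 20)
#' @return object of class `centrality_call`: list with `hubs`,
#'   `bottlenecks`, `both` (accession vectors), `N`, `table` (accession,
#'   label, degree, betweenness, roles) and the role-annotated `network`
#' @export
call_hubs_bottlenecks <- function(network, N = 20L) {
  nm <- node_names(network)
  deg <- igraph::degree(network)
  btw <- betweenness_centrality(network)$raw
  N <- min(as.integer(N), length(nm))
  top <- function(score) nm[order(-score, nm)][seq_len(N)]
  hubs <- top(deg); bottlenecks <- top(btw)
  igraph::V(network)$hub <- nm %in% hubs
  igraph::V(network)$bottleneck <- nm %in% bottlenecks
  both <- intersect(hubs, bottlenecks)
  ord <- order(-deg, nm)
  tab <- data.frame(
    accession = nm[ord],
    label = igraph::V(network)$label[ord],
    degree = as.integer(deg[ord]),
    betweenness = unname(btw[ord]),
    hub = nm[ord] %in% hubs,
    bottleneck = nm[ord] %in% bottlenecks,
    stringsAsFactors = FALSE
  )
  structure(list(hubs = hubs, bottlenecks = bottlenecks, both = both,
                 N = N, table = tab, network = network),
            class = "centrality_call")
}
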