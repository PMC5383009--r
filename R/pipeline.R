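#' Pipeline configuration
#'
#' Bundles every setting of the full study — curation, topology, robustness,
#' clustering, enrichment — into one validated list. Seeds for all stochastic
#' stages are mandatory: nothing in the pipeline seeds itself from the clock.
#'
#' @param mitab_path PSI-MITAB 2.5 interaction file
#' @param seeds character vector of seed accessions (or `NULL` to use every
#'   protein in the file)
#' @param categories named list of accession vectors for [label_nodes()]
#'   (optional)
#' @param annotations an [annotation_map()] or `NULL` to skip enrichment
#' @param taxon taxon kept by curation (default 9606)
#' @param topn hub/bottleneck list size (default 20)
#' @param inflation MCL inflation (default 1.8)
#' @param min_cluster_size smallest cluster analyzed (default 3)
#' @param alpha enrichment significance level (default 0.05)
#' @param min_drivers minimum carriers for a significant call (default 3)
#' @param null_replicates random-graph replicates (default 100)
#' @param lethality_max_fraction fraction removed in the lethality test
#' @param lethality_seeds seeds for failure trajectories
#' @param rng_seed seed for the null model
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(mitab_path, seeds = NULL, categories = NULL,
                            annotations = NULL, taxon = 9606L, topn = 20L,
                            inflation = 1.8, min_cluster_size = 3L,
                            alpha = 0.05, min_drivers = 3L,
                            null_replicates = 100L,
                            lethality_max_fraction = 0.2,
                            lethality_seeds = 1:20, rng_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full interactome analysis pipeline
#'
#' Executes the study end to end: curation (parse, filter, dedup, seed
#' expansion), node labelling, topology summary with power-law fits and
#' null-model comparison, hub/bottleneck calling, the lethality test (random
#' failure plus degree- and betweenness-ordered attack), MCL clustering with
#' size filtering, and over-representation analysis on the whole network and
#' on every kept cluster (each cluster tested against the network as
#' background). Artifacts are written under `out_dir` when given.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for reports and exports
#' @return a `report_bundle` list: `filter_report`, `network`, `topology`,
#'   `degree_fit`, `ck_fit` (or `NULL` when the network is too regular),
#'   `null_model`, `centrality`, `robustness` (list of trajectories +
#'   `comparison`), `clusters`, `kept_clusters`, `enrichment` (list:
#'   `network`, per-cluster), `provenance`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$mitab_path))
    stop("io-error [assemble]: no such file: ", config$mitab_path)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  cur <- stage("assemble",
               curate_mitab(config$mitab_path, config$seeds, config$taxon))
  net <- cur$network
  if (!is.null(config$categories))
    net <- stage("label", label_nodes(net, config$categories))

  topo <- stage("topology", topology_summary(net))
  deg_fit <- tryCatch(degree_distribution_fit(net), error = function(e) NULL)
  ck_fit <- tryCatch(ck_scaling(net), error = function(e) NULL)
  null_cmp <- stage("null_model", null_model_comparison(
    topo$n, topo$m, cc_observed = topo$cc, cpl_observed = topo$cpl,
    replicates = config$null_replicates, seed = config$rng_seed))
  cent <- stage("centrality", call_hubs_bottlenecks(net, config$topn))
  net <- cent$network

  traj <- stage("lethality", list(
    failure = lethality_test(net, "failure",
                             max_fraction = config$lethality_max_fraction,
                             seeds = config$lethality_seeds),
    degree_attack = lethality_test(net, "degree_attack",
                                   max_fraction = config$lethality_max_fraction),
    betweenness_attack = lethality_test(net, "betweenness_attack",
                                        max_fraction = config$lethality_max_fraction)
  ))
  robust <- c(traj, list(comparison = attack_failure_report(traj)))

  cs <- stage("cluster", mcl_cluster(net, mcl_params(inflation = config$inflation)))
  kept <- filter_clusters(cs, config$min_cluster_size)

  enr <- NULL
  if (!is.null(config$annotations)) {
    map <- propagate_annotations(config$annotations)
    bg <- intersect(node_names(net), names(map$protein_to_terms))
    enr <- stage("enrich", c(
      list(network = enrich(bg, map, background = bg, alpha = config$alpha,
                            min_drivers = config$min_drivers)),
      stats::setNames(lapply(kept$kept, function(cl)
        enrich(intersect(cl, bg), map, background = bg,
               alpha = config$alpha, min_drivers = config$min_drivers)),
        paste0("cluster_", seq_along(kept$kept)))
    ))
  }

  bundle <- structure(list(
    filter_report = cur$report,
    network = net,
    topology = topo,
    degree_fit = deg_fit,
    ck_fit = ck_fit,
    null_model = null_cmp,
    centrality = cent,
    robustness = robust,
    clusters = cs,
    kept_clusters = kept,
    enrichment = enr,
    provenance = list(
      config = config[setdiff(names(config), c("annotations", "categories"))],
      r_version = as.character(getRversion()),
      igraph_version = as.character(utils::packageVersion("igraph")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits the machine-readable artifacts of a pipeline run: the filter report
#' and topology/null-model summaries as JSON, the network as GraphML + SIF +
#' edge TSV, hub/bottleneck and cluster tables and robustness trajectories as
#' TSV, and per-set enrichment tables as TSV.
#'
#' @param bundle a `report_bundle`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_report_json(bundle$filter_report, fp("filter_report.json"))
  t <- bundle$topology
  write_report_json(list(
    n = t$n, m = t$m, density = t$density, cc = t$cc, cpl = t$cpl,
    n_components = t$n_components,
    giant_component_size = t$giant_component_size,
    degree_fit = if (!is.null(bundle$degree_fit))
      format(bundle$degree_fit) else NULL,
    ck_fit = if (!is.null(bundle$ck_fit))
      format(bundle$ck_fit, var = "C(k)") else NULL,
    null_model = unclass(bundle$null_model)
  ), fp("topology_summary.json"))
  export_network(bundle$network, fp("network.graphml"), "graphml")
  export_network(bundle$network, fp("network.sif"), "sif")
  export_network(bundle$network, fp("network_edges.tsv"), "tsv")
  utils::write.table(bundle$centrality$table, fp("centrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- bundle$clusters
  utils::write.table(
    data.frame(cluster_id = rep(seq_along(cl$clusters), lengths(cl$clusters)),
               accession = unlist(cl$clusters)),
    fp("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rb <- bundle$robustness$comparison
  utils::write.table(rb$table, fp("lethality_cpl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rb$area, fp("lethality_area.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$enrichment)) {
    for (nm in names(bundle$enrichment))
      utils::write.table(bundle$enrichment[[nm]],
                         fp(sprintf("enrichment_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
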