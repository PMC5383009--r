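#!/usr/bin/env Rscript
# Builds the synthetic interactome study set: a scale-free backbone carrying
# the packaged amyloid seed accessions, three planted dense modules, planted
# over-represented annotation terms, a detached seed dyad, and a MITAB 2.5
# export with known contamination. Everything downstream (02-06) consumes
# these files; the ground truth written here is what the later stages are
# scored against.

suppressPackageStartupMessages(library(amyloidnet))

SEED <- 20170301L  # study seed; every stage below derives from it
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## scale-free backbone ---------------------------------------------------------
backbone <- generate_scale_free(353, edges_per_node = 2, seed = SEED)
bb_edges <- igraph::as_edgelist(backbone)
bb_nodes <- igraph::V(backbone)$name

## three planted dense modules on top of the backbone --------------------------
pp <- generate_planted_partition(c(25, 20, 15), p_in = 0.35, p_out = 0,
                                 seed = SEED + 1L)
set.seed(SEED + 2L)
module_nodes <- sample(bb_nodes, 60)
relabel <- stats::setNames(module_nodes,
                           names(pp$ground_truth$module_assignment))
pp_edges <- igraph::as_edgelist(pp$network)
pp_edges <- cbind(relabel[pp_edges[, 1L]], relabel[pp_edges[, 2L]])
module_of <- stats::setNames(unname(pp$ground_truth$module_assignment),
                             module_nodes)

## place the curated amyloid accessions ----------------------------------------
seeds <- amyloid_seed_proteins()
deg <- igraph::degree(backbone)
# the flagship amyloidogenic hub sits on the highest-degree node; the others
# are spread over the network (module members included); two in-vivo seeds are
# deliberately left out of the network, emulating seeds with no recorded
# interaction partners
absent <- c("P10997", "P0DJI9")
placed_in_vivo <- setdiff(seeds$in_vivo$accession, absent)
set.seed(SEED + 3L)
targets <- c(names(sort(deg, decreasing = TRUE))[1L],
             sample(setdiff(bb_nodes, names(sort(deg, decreasing = TRUE))[1L]),
                    length(placed_in_vivo) + nrow(seeds$related) - 1L))
rename <- stats::setNames(c(placed_in_vivo, seeds$related$accession), targets)
apply_rename <- function(x) ifelse(x %in% names(rename), rename[x], x)
all_edges <- rbind(bb_edges, pp_edges)
all_edges <- cbind(apply_rename(all_edges[, 1L]), apply_rename(all_edges[, 2L]))
all_edges <- unique(cbind(pmin(all_edges[, 1L], all_edges[, 2L]),
                          pmax(all_edges[, 1L], all_edges[, 2L])))
names(module_of) <- apply_rename(names(module_of))

## detached dyad: a hormone seed whose only partner is its receptor ------------
all_edges <- rbind(all_edges, c("P01236", "P16471"))
net <- protein_network(all_edges)
message(sprintf("synthetic interactome: %d nodes, %d edges (giant component %d)",
                igraph::vcount(net), igraph::ecount(net),
                length(network_components(net)[[1L]])))

## annotations with one planted term per module --------------------------------
gt <- structure(list(module_assignment = module_of, enriched_terms = list(),
                     seed_accessions = placed_in_vivo,
                     generator_seed = SEED),
                class = "planted_ground_truth")
ann <- generate_annotations(net, n_terms = 60, background_rate = 0.04,
                            ground_truth = gt,
                            planted = list(c(term = 5, module = "M1"),
                                           c(term = 12, module = "M2"),
                                           c(term = 33, module = "M3")),
                            enriched_rate = 0.85, seed = SEED + 4L)

## MITAB export with known contamination ---------------------------------------
con <- contamination_spec(n_nonhuman_rows = 40, n_chemical_rows = 20,
                          n_selfloop_rows = 10, n_duplicate_rows = 50)
w <- write_mitab(net, con, seed = SEED + 5L,
                 path = file.path(out, "interactions.mitab"))
message(sprintf("MITAB written: %d rows (%d clean edges + %d contaminants)",
                w$expected_report$rows_read, w$expected_report$clean_edges,
                w$expected_report$rows_read - w$expected_report$clean_edges))

utils::write.table(ann$annotations, file.path(out, "annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(accession = names(module_of), module = unname(module_of)),
  file.path(out, "module_assignment.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
write_report_json(list(
  generator_seed = SEED,
  expected_filter_report = w$expected_report,
  planted_terms = lapply(ann$ground_truth$enriched_terms, unclass),
  absent_seeds = absent,
  dyad = c("P01236", "P16471"),
  n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net)
), file.path(out, "ground_truth.json"))
message("ground truth written to ", file.path(out, "ground_truth.json"))
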