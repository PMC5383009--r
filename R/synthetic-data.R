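#' Contamination specification for synthetic MITAB files
#'
#' Describes how many removable rows of each curation class to inject into a
#' synthetic MITAB 2.5 export: non-human interactions, interactions with
#' chemical compounds, self-loops and duplicated edges. The classes are
#' constructed to be pairwise disjoint (a non-human row is never also a
#' self-loop), so the expected filter report is exact.
#'
#' @param n_nonhuman_rows,n_chemical_rows,n_selfloop_rows,n_duplicate_rows
#'   non-negative row counts per class
#' @param foreign_taxon_id taxon used for non-human rows (default 10090, mouse)
#' @return a `contamination_spec` list
#' @export
contamination_spec <- function(n_nonhuman_rows = 0L, n_chemical_rows = 0L,
                               n_selfloop_rows = 0L, n_duplicate_rows = 0L,
                               foreign_taxon_id = 10090L) {
  counts <- c(n_nonhuman_rows, n_chemical_rows, n_selfloop_rows, n_duplicate_rows)
  if (any(counts < 0)) stop("contamination counts must be >= 0")
  structure(list(
    n_nonhuman_rows = as.integer(n_nonhuman_rows),
    n_chemical_rows = as.integer(n_chemical_rows),
    n_selfloop_rows = as.integer(n_selfloop_rows),
    n_duplicate_rows = as.integer(n_duplicate_rows),
    foreign_taxon_id = as.integer(foreign_taxon_id)
  ), class = "contamination_spec")
}

# synthetic accessions look like UniProtKB ACs but are clearly fabricated
synthetic_accession <- function(i) sprintf("S%05dX", i)

#' Scale-free network generator
#'
#' Grows a connected simple graph by preferential attachment: `edges_per_node`
#' seed vertices, then each new vertex attaches to `edges_per_node` distinct
#' existing vertices chosen with probability proportional to degree + 1. The
#' +1 smoothing lets the initially isolated seed vertices be chosen and gives
#' exactly (n - m0) * m edges with m0 = m = `edges_per_node`. The resulting
#' degree distribution is heavy-tailed (power-law-like), emulating the
#' scale-free structure of curated interactomes.
#'
#' `method = "configuration"` instead draws a degree sequence from a discrete
#' power law with exponent `gamma` and wires it with the configuration model
#' (simplified; connectivity not guaranteed) — useful for exponent-recovery
#' checks.
#'
#' @param n number of nodes (> `edges_per_node`)
#' @param edges_per_node edges added per new node (>= 1)
#' @param seed RNG seed (required: generation is deterministic)
#' @param method `"pa"` (preferential attachment, default) or
#'   `"configuration"`
#' @param gamma power-law exponent for `method = "configuration"`
#' @return a protein network with synthetic accessions
#' @export
generate_scale_free <- function(n, edges_per_node = 2L, seed,
                                method = c("pa", "configuration"),
                                gamma = 2.5) {
  method <- match.arg(method)
  n <- as.integer(n); m <- as.integer(edges_per_node)
  if (m < 1L || n <= m) stop("invalid-parameters: need n > edges_per_node >= 1")
  set.seed(seed)
  if (method == "configuration") {
    ks <- sample_power_law_degrees(n, gamma, kmin = 1L, kmax = max(2L, floor(sqrt(n))))
    if (sum(ks) %% 2L == 1L) ks[which.max(ks)] <- ks[which.max(ks)] + 1L
    g <- igraph::sample_degseq(ks, method = "configuration")
    g <- igraph::simplify(g)
    igraph::V(g)$name <- synthetic_accession(seq_len(n))
    return(protein_network(igraph::as_edgelist(g), nodes = igraph::V(g)$name))
  }
  acc <- synthetic_accession(seq_len(n))
  deg <- integer(n)
  from <- character((n - m) * m); to <- character((n - m) * m)
  k <- 0L
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    targets <- sample(existing, m, prob = deg[existing] + 1)
    for (t in targets) {
      k <- k + 1L
      from[k] <- acc[v]; to[k] <- acc[t]
      deg[v] <- deg[v] + 1L; deg[t] <- deg[t] + 1L
    }
  }
  protein_network(cbind(from, to), nodes = acc)
}

#' Sample degrees from a discrete power law
#'
#' Inverse-CDF sampling of P(k) proportional to k^-gamma on `kmin..kmax`.
#' Used to plant a known exponent for fit-recovery checks.
#'
#' @param n number of draws
#' @param gamma exponent (> 1)
#' @param kmin,kmax support bounds
#' @return integer vector of degrees
#' @export
sample_power_law_degrees <- function(n, gamma, kmin = 1L, kmax = 1000L) {
  ks <- kmin:kmax
  p <- ks^(-gamma)
  sample(ks, n, replace = TRUE, prob = p / sum(p))
}

#' Planted-partition (stochastic block model) generator
#'
#' Nodes are split into modules of the given sizes; each within-module pair is
#' connected independently with probability `p_in`, each between-module pair
#' with `p_out`. Serves as the ground-truth test bed for cluster recovery.
#'
#' @param module_sizes integer vector of module sizes
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`
#' @param seed RNG seed
#' @return list with `network` and `ground_truth` (a `planted_ground_truth`
#'   list carrying `module_assignment`, a named character vector node ->
#'   module label, and `generator_seed`)
#' @export
generate_planted_partition <- function(module_sizes, p_in, p_out, seed) {
  if (!(p_out >= 0 && p_in <= 1 && p_out < p_in))
    stop("degenerate-planting: need 0 <= p_out < p_in <= 1")
  sizes <- as.integer(module_sizes)
  if (any(sizes < 1L)) stop("module sizes must be >= 1")
  set.seed(seed)
  n <- sum(sizes)
  modules <- rep(paste0("M", seq_along(sizes)), sizes)
  acc <- synthetic_accession(seq_len(n))
  pm <- matrix(p_out, length(sizes), length(sizes))
  diag(pm) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- acc
  net <- protein_network(igraph::as_edgelist(g), nodes = acc)
  gt <- structure(list(
    module_assignment = stats::setNames(modules, acc),
    enriched_terms = list(),
    seed_accessions = character(0),
    generator_seed = seed
  ), class = "planted_ground_truth")
  list(network = net, ground_truth = gt)
}

#' Synthetic protein-to-term annotation table
#'
#' Annotates each protein of the network to each of `n_terms` terms
#' independently at `background_rate`, except for planted (term, module)
#' pairs, where proteins of that module carry the term at `enriched_rate`.
#' Planted pairs are recorded in the returned ground truth so enrichment
#' recovery can be scored exactly.
#'
#' @param network a protein network
#' @param n_terms number of terms (named `T001`, `T002`, ...)
#' @param background_rate per-(protein, term) annotation probability
#' @param ground_truth a `planted_ground_truth` with module assignments (or
#'   `NULL` for a pure-background table)
#' @param planted list of `(term_index, module)` pairs to enrich, e.g.
#'   `list(c(term = 1, module = "M1"))`; term indices refer to `1..n_terms`
#' @param enriched_rate annotation probability on planted pairs
#'   (`background_rate < enriched_rate <= 1`)
#' @param seed RNG seed
#' @return list with `annotations` (data frame: accession, term) and
#'   `ground_truth` (input ground truth with `enriched_terms` filled in)
#' @export
generate_annotations <- function(network, n_terms, background_rate,
                                 ground_truth = NULL, planted = list(),
                                 enriched_rate = 1, seed) {
  if (igraph::vcount(network) == 0L) stop("empty-input: network has no nodes")
  if (!(background_rate >= 0 && background_rate < enriched_rate && enriched_rate <= 1))
    stop("need 0 <= background_rate < enriched_rate <= 1")
  set.seed(seed)
  prots <- sort(node_names(network))
  terms <- sprintf("T%03d", seq_len(n_terms))
  modules <- if (!is.null(ground_truth)) ground_truth$module_assignment[prots]
             else stats::setNames(rep(NA_character_, length(prots)), prots)
  planted_key <- vapply(planted, function(p)
    paste0(terms[as.integer(p[["term"]])], "\r", p[["module"]]), character(1))
  rate <- matrix(background_rate, nrow = length(prots), ncol = n_terms,
                 dimnames = list(prots, terms))
  for (p in planted) {
    term <- terms[as.integer(p[["term"]])]
    rate[!is.na(modules) & modules == p[["module"]], term] <- enriched_rate
  }
  draw <- matrix(stats::runif(length(rate)), nrow = nrow(rate)) < rate
  idx <- which(draw, arr.ind = TRUE)
  ann <- data.frame(accession = prots[idx[, 1L]], term = terms[idx[, 2L]],
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$accession, ann$term), , drop = FALSE]
  rownames(ann) <- NULL
  if (!is.null(ground_truth)) {
    ground_truth$enriched_terms <- lapply(planted, function(p)
      list(term = terms[as.integer(p[["term"]])], module = p[["module"]],
           rate = enriched_rate))
  }
  list(annotations = ann, ground_truth = ground_truth)
}

# one MITAB 2.5 row (15 columns) from namespaced ids and taxa
mitab_row <- function(id_a, id_b, taxon_a, taxon_b,
                      type_a = "psi-mi:\"MI:0326\"(protein)",
                      type_b = "psi-mi:\"MI:0326\"(protein)") {
  paste(
    id_a, id_b, "-", "-", "-", "-",
    "psi-mi:\"MI:0006\"(anti bait coip)",
    "-", "pubmed:00000000",
    if (is.na(taxon_a)) "-" else sprintf("taxid:%d(synthetic)", taxon_a),
    if (is.na(taxon_b)) "-" else sprintf("taxid:%d(synthetic)", taxon_b),
    "psi-mi:\"MI:0915\"(physical association)",
    "psi-mi:\"MI:0469\"(IntAct)", "-", "-",
    sep = "\t"
  )
}

#' Write a synthetic MITAB 2.5 file with known contamination
#'
#' Serializes every edge of `network` as a clean human protein-protein row
#' (`uniprotkb:` accessions, `taxid:9606` on both interactors), injects the
#' contaminant rows described by `contamination` at shuffled positions, and
#' returns the filter report the curation pipeline is expected to produce on
#' this file. Contaminant classes are pairwise disjoint by construction:
#' non-human rows use fabricated foreign accessions, chemical rows use
#' `chebi:` identifiers, self-loop rows repeat a real node against itself
#' (but never an existing edge), and duplicate rows repeat existing clean
#' edges with the interactor columns swapped.
#'
#' @param network a protein network (non-empty)
#' @param contamination a [contamination_spec()]
#' @param seed RNG seed controlling row order and contaminant placement
#' @param path output file path
#' @return invisibly, a list with `path`, the `expected_report` (named counts)
#'   and `clean_edges` (canonical two-column matrix)
#' @export
write_mitab <- function(network, contamination = contamination_spec(),
                        seed = 1L, path) {
  if (igraph::vcount(network) == 0L) stop("empty-input: network has no nodes")
  set.seed(seed)
  el <- igraph::as_edgelist(network)
  if (nrow(el)) {
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  human <- 9606L
  up <- function(acc) paste0("uniprotkb:", acc)
  rows_clean <- if (nrow(el))
    mapply(function(a, b) mitab_row(up(a), up(b), human, human),
           el[, 1L], el[, 2L])
  else character(0)

  con <- contamination
  rows_bad <- character(0)
  if (con$n_nonhuman_rows > 0L) {
    rows_bad <- c(rows_bad, vapply(seq_len(con$n_nonhuman_rows), function(i)
      mitab_row(up(sprintf("F%05dX", i)), up(sprintf("F%05dY", i)),
                con$foreign_taxon_id,
                if (i %% 2L == 0L) human else con$foreign_taxon_id),
      character(1)))
  }
  if (con$n_chemical_rows > 0L) {
    nodes <- sort(node_names(network))
    rows_bad <- c(rows_bad, vapply(seq_len(con$n_chemical_rows), function(i)
      mitab_row(up(nodes[1L + (i - 1L) %% length(nodes)]),
                sprintf("chebi:\"CHEBI:%05d\"", 15000L + i),
                human, human,
                type_b = "psi-mi:\"MI:0328\"(small molecule)"),
      character(1)))
  }
  if (con$n_selfloop_rows > 0L) {
    nodes <- sort(node_names(network))
    rows_bad <- c(rows_bad, vapply(seq_len(con$n_selfloop_rows), function(i) {
      a <- nodes[1L + (i - 1L) %% length(nodes)]
      mitab_row(up(a), up(a), human, human)
    }, character(1)))
  }
  if (con$n_duplicate_rows > 0L) {
    if (nrow(el) == 0L) stop("cannot inject duplicates into an edgeless network")
    rows_bad <- c(rows_bad, vapply(seq_len(con$n_duplicate_rows), function(i) {
      j <- 1L + (i - 1L) %% nrow(el)
      # swapped column order: dedup must canonicalize unordered pairs
      mitab_row(up(el[j, 2L]), up(el[j, 1L]), human, human)
    }, character(1)))
  }

  all_rows <- c(rows_clean, rows_bad)
  all_rows <- all_rows[sample.int(length(all_rows))]
  header <- paste("#ID(s) interactor A", "ID(s) interactor B",
                  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
                  "Alias(es) interactor A", "Alias(es) interactor B",
                  "Interaction detection method(s)", "Publication 1st author(s)",
                  "Publication Identifier(s)", "Taxid interactor A",
                  "Taxid interactor B", "Interaction type(s)",
                  "Source database(s)", "Interaction identifier(s)",
                  "Confidence value(s)", sep = "\t")
  ok <- tryCatch({
    writeLines(c(header, all_rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("io-error: cannot write ", path)

  expected <- list(
    rows_read = length(all_rows),
    rows_nonhuman_removed = con$n_nonhuman_rows,
    rows_nonprotein_removed = con$n_chemical_rows,
    selfloops_removed = con$n_selfloop_rows,
    duplicates_removed = con$n_duplicate_rows,
    clean_edges = nrow(el)
  )
  invisible(list(path = path, expected_report = expected, clean_edges = el))
}
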