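#' Parse a PSI-MITAB 2.5 interaction file
#'
#' Reads a 15-column tab-delimited MITAB 2.5 file into one interaction record
#' per data row. Only the fields the curation filters consume are extracted:
#' the primary identifier of each interactor (the first alternative in the ID
#' column), the taxon of each interactor, and the interactor type when a
#' dialect provides one. Rows with fewer than 15 columns are skipped, counted
#' and reported with a warning rather than aborting the parse.
#'
#' @param path path to a MITAB 2.5 file; a line starting with `#` is treated
#'   as the header
#' @return data frame of class `interaction_records` with columns `id_a`,
#'   `id_b` (namespaced identifier strings), `taxon_a`, `taxon_b` (integer or
#'   `NA`), `type_a`, `type_b` (CV label or `NA`) and `source_line`; the
#'   number of skipped malformed rows is attached as attribute
#'   `malformed_rows`
#' @export
parse_mitab <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "#")
  data_idx <- which(!is_header & nzchar(lines))
  if (length(data_idx) == 0L) {
    warning("empty-input: no data rows in ", path)
    rec <- data.frame(id_a = character(0), id_b = character(0),
                      taxon_a = integer(0), taxon_b = integer(0),
                      type_a = character(0), type_b = character(0),
                      source_line = integer(0), stringsAsFactors = FALSE)
    attr(rec, "malformed_rows") <- 0L
    class(rec) <- c("interaction_records", "data.frame")
    return(rec)
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- nfield < 15L
  if (any(bad))
    warning(sum(bad), " malformed row(s) with < 15 columns skipped")
  fields <- fields[!bad]
  src <- data_idx[!bad]
  first_alt <- function(x) vapply(strsplit(x, "|", fixed = TRUE),
                                  `[`, character(1), 1L)
  col <- function(i) vapply(fields, `[`, character(1), i)
  rec <- data.frame(
    id_a = first_alt(col(1L)),
    id_b = first_alt(col(2L)),
    taxon_a = parse_taxid(col(10L)),
    taxon_b = parse_taxid(col(11L)),
    type_a = NA_character_,
    type_b = NA_character_,
    source_line = src,
    stringsAsFactors = FALSE
  )
  attr(rec, "malformed_rows") <- sum(bad)
  class(rec) <- c("interaction_records", "data.frame")
  rec
}

# "taxid:9606(human)" -> 9606L; "-" or empty -> NA
parse_taxid <- function(x) {
  out <- rep(NA_integer_, length(x))
  hit <- regmatches(x, regexpr("(?<=taxid:)-?[0-9]+", x, perl = TRUE))
  has <- grepl("taxid:", x, fixed = TRUE)
  out[has] <- suppressWarnings(as.integer(hit))
  out
}

id_namespace <- function(id) sub(":.*$", "", id)

# "uniprotkb:P05067-2" -> accession "P05067" (isoform collapsed)
id_accession <- function(id, collapse_isoforms = TRUE) {
  acc <- sub("^[^:]*:", "", id)
  if (collapse_isoforms) acc <- sub("-[0-9]+$", "", acc)
  acc
}

#' Remove non-human and non-protein interaction records
#'
#' Keeps rows where both interactors carry the human taxon and both
#' identifiers live in the `uniprotkb` namespace. Mixed-taxon rows (one human,
#' one not, or missing taxon) count as non-human. A row failing both tests is
#' counted once, in the first class applied: non-human, then non-protein.
#'
#' @param records an `interaction_records` data frame from [parse_mitab()]
#' @param human_taxon taxon identifier to keep (default 9606)
#' @return list with `records` (kept rows) and `report` (named counts:
#'   `rows_read`, `rows_nonhuman_removed`, `rows_nonprotein_removed`)
#' @export
filter_records <- function(records, human_taxon = 9606L) {
  human <- !is.na(records$taxon_a) & records$taxon_a == human_taxon &
           !is.na(records$taxon_b) & records$taxon_b == human_taxon
  protein <- id_namespace(records$id_a) == "uniprotkb" &
             id_namespace(records$id_b) == "uniprotkb"
  nonhuman <- !human
  nonprotein <- human & !protein
  list(
    records = records[human & protein, , drop = FALSE],
    report = list(rows_read = nrow(records),
                  rows_nonhuman_removed = sum(nonhuman),
                  rows_nonprotein_removed = sum(nonprotein))
  )
}

#' Collapse records to a simple edge set
#'
#' Drops self interactions, canonicalizes each remaining pair as a
#' lexicographically sorted unordered accession pair (so `A-B` and `B-A`
#' collapse), and counts removals per class. Isoform suffixes
#' (`P05067-2`) are collapsed to the parent accession by default.
#'
#' @param records filtered `interaction_records`
#' @param collapse_isoforms collapse isoform accessions to the parent?
#' @return list with `edges` (two-column character matrix, canonical order,
#'   unique rows) and `report` (`selfloops_removed`, `duplicates_removed`)
#' @export
dedupe_and_deloop <- function(records, collapse_isoforms = TRUE) {
  a <- id_accession(records$id_a, collapse_isoforms)
  b <- id_accession(records$id_b, collapse_isoforms)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edges <- cbind(lo[!dup], hi[!dup])
  if (nrow(edges)) edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("a", "b")
  list(edges = edges,
       report = list(selfloops_removed = sum(self),
                     duplicates_removed = sum(dup)))
}

#' Assemble the seed-expanded network
#'
#' Two-step expansion around the seed proteins, mirroring how interactome
#' studies grow a network from a curated seed list:
#' \enumerate{
#'   \item keep every edge incident to at least one seed; the retained seeds
#'     and their partners define the node set V1;
#'   \item additionally keep every edge with both endpoints in V1 (the
#'     interactions "between all retained proteins").
#' }
#' A protein whose only records were self interactions never enters V1, which
#' reproduces the exclusion of self-interaction-only nodes.
#'
#' @param edges canonical two-column accession matrix from
#'   [dedupe_and_deloop()]
#' @param seeds character vector of seed accessions (non-empty)
#' @return list with `network` (a protein network) and `report` (counts
#'   `nodes_after_seed_step`, `edges_after_seed_step`, `nodes_final`,
#'   `edges_final`)
#' @export
assemble_network <- function(edges, seeds) {
  if (length(seeds) == 0L) stop("empty-input: no seed accessions")
  edges <- as.matrix(edges)
  touches_seed <- edges[, 1L] %in% seeds | edges[, 2L] %in% seeds
  if (!any(touches_seed)) stop("empty-network: no edge touches any seed")
  e1 <- edges[touches_seed, , drop = FALSE]
  v1 <- sort(unique(as.vector(e1)))
  both_in <- edges[, 1L] %in% v1 & edges[, 2L] %in% v1
  e2 <- edges[both_in, , drop = FALSE]
  net <- protein_network(e2, nodes = v1)
  list(network = net,
       report = list(nodes_after_seed_step = length(v1),
                     edges_after_seed_step = nrow(e1),
                     nodes_final = igraph::vcount(net),
                     edges_final = igraph::ecount(net)))
}

#' Run the full curation pipeline on a MITAB file
#'
#' Convenience wrapper: parse, taxon/molecule filtering, dedup/deloop,
#' seed expansion, with a consolidated filter report.
#'
#' @param path MITAB 2.5 file
#' @param seeds seed accessions; `NULL` assembles over all proteins (every
#'   node treated as a seed)
#' @param human_taxon taxon to keep
#' @param collapse_isoforms see [dedupe_and_deloop()]
#' @return list with `network` and `report` (all counts of the stage reports)
#' @export
curate_mitab <- function(path, seeds = NULL, human_taxon = 9606L,
                         collapse_isoforms = TRUE) {
  rec <- parse_mitab(path)
  f <- filter_records(rec, human_taxon)
  d <- dedupe_and_deloop(f$records, collapse_isoforms)
  if (is.null(seeds)) seeds <- sort(unique(as.vector(d$edges)))
  a <- assemble_network(d$edges, seeds)
  list(network = a$network,
       report = c(f$report, d$report, a$report,
                  list(malformed_rows = attr(rec, "malformed_rows"))))
}

#' Label network nodes with amyloid categories
#'
#' Applies accession -> category tables (in vivo amyloid-forming, in vitro
#' amyloid-forming, amyloid-related); every node absent from all tables is
#' labelled `"other"`. An accession listed under two categories is an error.
#'
#' @param network a protein network
#' @param categories named list of character vectors, names from
#'   `c("in_vivo_amyloid", "in_vitro_amyloid", "amyloid_related")`
#' @param labels optional named character vector accession -> display label
#' @return the network with `category` (and optionally `label`) vertex
#'   attributes set
#' @export
label_nodes <- function(network, categories, labels = NULL) {
  allowed <- c("in_vivo_amyloid", "in_vitro_amyloid", "amyloid_related")
  if (!all(names(categories) %in% allowed))
    stop("unknown category name(s): ",
         paste(setdiff(names(categories), allowed), collapse = ", "))
  all_acc <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(all_acc))
    stop("conflicting-category: ",
         paste(unique(all_acc[duplicated(all_acc)]), collapse = ", "))
  cat_map <- stats::setNames(rep(names(categories), lengths(categories)), all_acc)
  nm <- node_names(network)
  cats <- unname(cat_map[nm])
  cats[is.na(cats)] <- "other"
  igraph::V(network)$category <- cats
  if (!is.null(labels)) {
    lab <- unname(labels[nm])
    igraph::V(network)$label <- ifelse(is.na(lab), nm, lab)
  }
  network
}

#' Packaged amyloid seed protein tables
#'
#' Returns the curated seed tables shipped with the package: 28 precursor
#' proteins documented to form amyloid fibrils in vivo (the seed set used to
#' nucleate the interactome, e.g. amyloid beta A4 protein P05067,
#' transthyretin P02766) and 13 additional proteins — in vitro amyloid
#' formers (e.g. alpha-synuclein P37840) and amyloid-related proteins.
#'
#' @return list of two data frames, `in_vivo` and `related`, each with
#'   columns `protein`, `abbreviation`, `accession`, `category`
#' @export
amyloid_seed_proteins <- function() {
  read1 <- function(f) utils::read.delim(
    system.file("extdata", f, package = "amyloidnet", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(in_vivo = read1("seed_proteins_in_vivo.tsv"),
       related = read1("amyloid_related_proteins.tsv"))
}
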