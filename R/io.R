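#' Export a network to SIF, GraphML or edge-list TSV
#'
#' SIF writes one `A interacts B` line per edge (Cytoscape-compatible);
#' GraphML carries the node attributes (category, roles, cluster id when
#' present) and round-trips through [import_network()]; TSV is a plain
#' two-column edge list with header.
#'
#' @param network a non-empty protein network
#' @param path output file
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`
#' @return `path`, invisibly
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("invalid-format: ", format[1L]))
  if (igraph::vcount(network) == 0L) stop("empty-input: network has no nodes")
  el <- igraph::as_edgelist(network)
  if (format == "sif") {
    writeLines(if (nrow(el)) paste(el[, 1L], "interacts", el[, 2L]) else character(0),
               path)
  } else if (format == "tsv") {
    utils::write.table(data.frame(a = el[, 1L], b = el[, 2L]), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path input file
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`
#' @return a protein network (GraphML retains node attributes)
#' @export
import_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("invalid-format: ", format[1L]))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    # igraph may restore attributes in a different vertex order; names anchor identity
    return(g)
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    el <- cbind(vapply(parts, `[`, character(1), 1L),
                vapply(parts, `[`, character(1), 3L))
    return(protein_network(el))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  protein_network(as.matrix(tab[, 1:2]))
}

#' Write a filter report / summary list as JSON
#'
#' @param x a named list of scalars or simple vectors
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
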