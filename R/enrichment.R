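#' Annotation map
#'
#' Container for a protein-to-term annotation table plus an optional
#' term-to-parent relation (an acyclic is-a hierarchy, GO-style). Works for
#' any namespace — GO-like, pathway-like or disease-like tables go through
#' the same engine.
#'
#' @param annotations data frame with columns `accession`, `term` (one row
#'   per annotation)
#' @param parents optional data frame with columns `term`, `parent`
#' @param namespace free-text label (e.g. `"GO-BP"`, `"pathway"`)
#' @return an `annotation_map` list with `protein_to_terms` (named list of
#'   term character vectors), `term_parents` (named list), `namespace`
#' @export
annotation_map <- function(annotations, parents = NULL, namespace = "generic") {
  stopifnot(all(c("accession", "term") %in% names(annotations)))
  p2t <- lapply(split(annotations$term, annotations$accession), unique)
  tp <- if (is.null(parents) || nrow(parents) == 0L) list()
        else lapply(split(parents$parent, parents$term), unique)
  structure(list(protein_to_terms = p2t, term_parents = tp,
                 namespace = namespace),
            class = "annotation_map")
}

#' Read an annotation map from TSV files
#'
#' @param annotation_path 2+ column TSV with header columns `accession`, `term`
#' @param parent_path optional 2-column TSV with header columns `term`, `parent`
#' @param namespace label for the map
#' @return an [annotation_map()]
#' @export
read_annotation_map <- function(annotation_path, parent_path = NULL,
                                namespace = "generic") {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  par <- if (!is.null(parent_path))
    utils::read.delim(parent_path, stringsAsFactors = FALSE) else NULL
  annotation_map(ann, par, namespace)
}

#' Propagate annotations up the term hierarchy (true-path rule)
#'
#' A protein annotated to a term is implicitly annotated to all of that
#' term's ancestors; this computes the transitive closure over the parent
#' relation. A cycle in the parent relation is an error.
#'
#' @param map an [annotation_map()]
#' @return the map with `protein_to_terms` closed under the parent relation
#' @export
propagate_annotations <- function(map) {
  tp <- map$term_parents
  if (length(tp) == 0L) return(map)
  ancestors_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, trail = character(0)) {
    if (term %in% trail)
      stop("cyclic-ontology: cycle through term ", term)
    cached <- get0(term, envir = ancestors_cache, inherits = FALSE)
    if (!is.null(cached)) return(cached)
    direct <- tp[[term]]
    if (is.null(direct)) {
      ancestors_cache[[term]] <- character(0)
      return(character(0))
    }
    anc <- unique(c(direct, unlist(lapply(direct, ancestors,
                                          trail = c(trail, term)))))
    ancestors_cache[[term]] <- anc
    anc
  }
  for (t in names(tp)) ancestors(t)  # forces cycle detection everywhere
  map$protein_to_terms <- lapply(map$protein_to_terms, function(terms)
    sort(unique(c(terms, unlist(lapply(terms, ancestors))))))
  map
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing a study set of size n
#' from a background of N proteins of which K carry the term, the probability
#' of seeing k or more carriers. This is the over-representation p-value.
#'
#' @param k carriers observed in the study set
#' @param K carriers in the background
#' @param n study-set size
#' @param N background size
#' @return upper-tail probability in \[0, 1\]
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop("invalid-counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply p_(i) by
#' m/i, enforce monotonicity from the largest down, cap at 1, return in input
#' order.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("invalid-pvalue: values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis
#'
#' Hypergeometric test of every term carried by at least one study protein
#' against the chosen background, with Benjamini-Hochberg correction across
#' all tested terms. A term is called significant when its adjusted p-value
#' is below `alpha` AND it is driven by at least `min_drivers` study proteins
#' — terms carried by one or two proteins are flagged but never called, since
#' such calls are dominated by annotation noise. Terms with k = 0 cannot be
#' over-represented and are excluded from the BH family.
#'
#' @param study_set character vector of accessions (non-empty, all present in
#'   the background)
#' @param map an [annotation_map()] (propagate first if a hierarchy applies)
#' @param background character vector of background accessions; defaults to
#'   all annotated proteins in the map (use the analyzed network's proteins
#'   to test a cluster against its interactome context)
#' @param alpha significance level on the adjusted p-value (0.05 by
#'   convention; 0.01 for a stricter profile)
#' @param min_drivers minimum study-set carriers for a significant call
#'   (default 3)
#' @return data frame sorted by adjusted p-value: `term`, `k`, `K`, `n`, `N`,
#'   `frequency` (k/n), `p_raw`, `p_adj`, `significant`
#' @export
enrich <- function(study_set, map, background = NULL, alpha = 0.05,
                   min_drivers = 3L) {
  if (length(study_set) == 0L) stop("empty-input: empty study set")
  if (is.null(background)) background <- names(map$protein_to_terms)
  background <- unique(background)
  study_set <- unique(study_set)
  if (!all(study_set %in% background))
    stop("background-mismatch: study proteins absent from background: ",
         paste(utils::head(setdiff(study_set, background), 5L), collapse = ", "))
  p2t <- map$protein_to_terms
  bg_terms <- p2t[intersect(background, names(p2t))]
  study_terms <- p2t[intersect(study_set, names(p2t))]
  N <- length(background)
  n <- length(study_set)
  K_tab <- table(unlist(bg_terms, use.names = FALSE))
  k_tab <- table(unlist(study_terms, use.names = FALSE))
  terms <- sort(names(k_tab))  # only k >= 1 terms are testable
  if (length(terms) == 0L)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), frequency = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p_raw <- hypergeometric_upper_tail(k, K, n, N)
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    frequency = k / n, p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha & k >= min_drivers,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
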