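# Gene networks are undirected igraph objects whose vertex names are
# canonical gene symbols. Edges may carry a `confidence` attribute (e.g. a
# STRING combined_score); all algorithms here treat the topology as
# unweighted and use confidence only for ingest-time filtering.

#' Build a gene network from an edge table
#'
#' @param edges data frame with columns `gene1`, `gene2` and optionally
#'   `confidence` (non-negative). Symbols are case-normalized, self-loops
#'   dropped, and duplicate / reversed pairs collapsed (keeping the maximum
#'   confidence when present).
#' @return an undirected `igraph` with unique named vertices.
#' @export
gene_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("gene1", "gene2") %in% names(edges)))
  ed <- tibble(
    gene1 = canonical_symbol(edges$gene1),
    gene2 = canonical_symbol(edges$gene2)
  )
  if ("confidence" %in% names(edges)) ed$confidence <- as.numeric(edges$confidence)
  n_self <- sum(ed$gene1 == ed$gene2)
  if (n_self > 0) {
    inform(sprintf("dropping %d self-loop edge(s)", n_self))
    ed <- dplyr::filter(ed, .data$gene1 != .data$gene2)
  }
  # canonical unordered pair: smaller symbol first
  swap <- ed$gene1 > ed$gene2
  tmp <- ed$gene1[swap]
  ed$gene1[swap] <- ed$gene2[swap]
  ed$gene2[swap] <- tmp
  ed <- if ("confidence" %in% names(ed)) {
    dplyr::summarise(dplyr::group_by(ed, .data$gene1, .data$gene2),
                     confidence = max(.data$confidence), .groups = "drop")
  } else {
    dplyr::distinct(ed)
  }
  if (nrow(ed) == 0) abort("no edges remain after cleaning")
  igraph::graph_from_data_frame(ed, directed = FALSE)
}

#' Nodes of a gene network
#' @param net an igraph gene network.
#' @return character vector of gene symbols.
#' @export
network_genes <- function(net) igraph::V(net)$name

#' Induced subnetwork on a gene set
#'
#' @param net igraph gene network.
#' @param genes gene symbols; symbols absent from the network are ignored.
#' @return the induced subgraph (possibly with isolated vertices).
#' @export
induced_subnetwork <- function(net, genes) {
  keep <- intersect(canonical_symbol(genes), network_genes(net))
  igraph::induced_subgraph(net, keep)
}

#' Convert a gene network back to a canonical edge table
#'
#' Pairs are ordered with the lexicographically smaller symbol first and rows
#' sorted, so that write/read round-trips are byte-stable.
#'
#' @param net igraph gene network.
#' @return tibble with columns gene1, gene2 and confidence when present.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  g1 <- pmin(el[, 1], el[, 2])
  g2 <- pmax(el[, 1], el[, 2])
  out <- tibble(gene1 = g1, gene2 = g2)
  if ("confidence" %in% igraph::edge_attr_names(net)) {
    out$confidence <- igraph::E(net)$confidence
  }
  dplyr::arrange(out, .data$gene1, .data$gene2)
}

#' Write a gene network as a TSV edge list
#' @param net igraph gene network.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(network_edges(net), path)
  invisible(path)
}
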