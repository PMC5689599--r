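# Key connector analysis: dynamic neighbourhood search on an undirected
# network. Around a target gene set G, the search first restricts to the
# subnetwork of nodes within L hops of G, then tests each gene's h-hop
# neighbourhoods (h = 1..H) for hypergeometric enrichment in G, takes the
# minimum p across layers and Bonferroni-corrects across genes. On an
# undirected PPI network the hits are "key connectors" (hub-like mediators),
# not directed master regulators.

#' L-hop subnetwork around a gene set
#'
#' @param net igraph gene network.
#' @param G target gene set (must intersect the network).
#' @param L maximum hop distance from G; default 2. `L = 0` gives the
#'   induced subgraph on `G` itself.
#' @return induced subgraph on all nodes within `L` hops of any gene of `G`.
#' @export
build_kca_subnetwork <- function(net, G, L = 2) {
  G <- intersect(canonical_symbol(G), network_genes(net))
  if (length(G) == 0) abort("no target gene maps onto the network")
  d <- igraph::distances(net, v = G, weights = NA)
  keep <- colnames(d)[apply(d, 2, min) <= L]
  igraph::induced_subgraph(net, keep)
}

# Upper-tail hypergeometric enrichment p-value: probability of observing at
# least `overlap` successes when drawing `draws` from a population of size
# `pop` containing `successes` successes.
hypergeom_upper <- function(overlap, successes, pop, draws) {
  phyper(overlap - 1, successes, pop - successes, draws, lower.tail = FALSE)
}

#' Key connector analysis by dynamic neighbourhood search
#'
#' For every gene g in the L-hop subnetwork around `G`, enumerates the genes
#' within h hops of g (h = 1..H, excluding g itself) and computes the
#' upper-tail hypergeometric enrichment of that neighbourhood in `G`, with
#' the subnetwork's genes as background (g excluded from the population, and
#' from the success set if it belongs to `G`, since self-membership is not a
#' connection). The per-gene p-value is the minimum across layers, then
#' Bonferroni-corrected over the number of genes tested; genes at corrected
#' p <= `alpha` are key connectors.
#'
#' @param net igraph gene network.
#' @param G target gene set (e.g. the union of query and disease genes mapped
#'   to a significant module).
#' @param L hop radius of the search subnetwork; default 2.
#' @param H deepest neighbourhood layer tested; default 2.
#' @param alpha Bonferroni significance cutoff; default 0.05.
#' @return tibble sorted by p: gene, min_p, p_bonferroni, is_key, and one
#'   `size_h<h>` column per layer with the neighbourhood size.
#' @export
kca <- function(net, G, L = 2, H = 2, alpha = 0.05) {
  G <- canonical_symbol(G)
  sub <- build_kca_subnetwork(net, G, L = L)
  nodes <- network_genes(sub)
  n_pop_all <- length(nodes)
  g_in <- intersect(G, nodes)
  d <- igraph::distances(sub, weights = NA)
  rows <- lapply(nodes, function(g) {
    succ <- length(setdiff(g_in, g))
    pop <- n_pop_all - 1L
    layer_p <- numeric(H)
    layer_size <- integer(H)
    for (h in seq_len(H)) {
      nbhd <- setdiff(nodes[d[g, ] <= h], g)
      layer_size[h] <- length(nbhd)
      layer_p[h] <- if (length(nbhd) == 0) 1 else {
        hypergeom_upper(length(intersect(nbhd, g_in)), succ, pop, length(nbhd))
      }
    }
    out <- tibble(gene = g, min_p = min(layer_p))
    for (h in seq_len(H)) out[[paste0("size_h", h)]] <- layer_size[h]
    out
  })
  n_tested <- length(nodes)
  dplyr::bind_rows(rows) |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$min_p * n_tested),
                  is_key = .data$p_bonferroni <= alpha) |>
    dplyr::relocate("p_bonferroni", "is_key", .after = "min_p") |>
    dplyr::arrange(.data$min_p, .data$gene)
}
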