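# Functional modules: a GO/KEGG-style gene set mapped onto the reference
# network (the "modularized network"), optionally grown by RWR to 5x its
# mapped size or 500 genes, whichever is smaller (the "expanded modularized
# network").

new_functional_module <- function(module_id, core_genes, expanded_genes,
                                  subnetwork) {
  structure(list(module_id = module_id,
                 core_genes = core_genes,
                 expanded_genes = expanded_genes,
                 subnetwork = subnetwork),
            class = "functional_module")
}

#' Genes of a functional module
#' @param m a `functional_module`.
#' @return the expanded gene set when the module has been expanded, otherwise
#'   the core (mapped) gene set.
#' @export
module_genes <- function(m) {
  if (length(m$expanded_genes) > 0) m$expanded_genes else m$core_genes
}

#' @export
print.functional_module <- function(x, ...) {
  cat(sprintf("<functional_module> %s: %d core gene(s)%s, %d subnetwork edge(s)\n",
              x$module_id, length(x$core_genes),
              if (length(x$expanded_genes) > 0) {
                sprintf(", expanded to %d", length(x$expanded_genes))
              } else "",
              igraph::ecount(x$subnetwork)))
  invisible(x)
}

#' Build modularized networks from a gene-set collection
#'
#' Each gene set with fewer than `max_set_size` genes is mapped onto the
#' reference network: the module's core genes are the set members present on
#' the network and its subnetwork is the induced subgraph. Sets at or above
#' the size cap, or with no gene on the network, are skipped (logged).
#'
#' @param net reference igraph gene network.
#' @param sets a `gene_set_collection` or named list of gene sets.
#' @param max_set_size strict upper bound on the raw set size; default 500.
#' @return named list of `functional_module` objects.
#' @export
build_modules <- function(net, sets, max_set_size = 500) {
  nodes <- network_genes(net)
  skipped <- character()
  mods <- list()
  for (id in names(sets)) {
    genes <- unique(canonical_symbol(sets[[id]]))
    if (length(genes) >= max_set_size) {
      skipped <- c(skipped, sprintf("%s (too large: %d genes)", id, length(genes)))
      next
    }
    core <- sort(intersect(genes, nodes))
    if (length(core) == 0) {
      skipped <- c(skipped, sprintf("%s (no gene on network)", id))
      next
    }
    mods[[id]] <- new_functional_module(id, core, character(),
                                        induced_subnetwork(net, core))
  }
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d gene set(s): %s", length(skipped),
                   paste(head(skipped, 5), collapse = "; ")))
  }
  mods
}

#' Expand a module by random walk with restart
#'
#' The RWR is seeded on the module's core genes and run on the whole
#' reference network, so the expansion can reach genes outside the core. The
#' module grows to `min(factor * |core|, cap)` genes by adding the top-ranked
#' non-core genes (ties broken lexicographically); the subnetwork is
#' re-induced on the expanded gene set. Expanding an already-expanded module
#' with the same parameters is a no-op.
#'
#' @param net reference igraph gene network.
#' @param m a `functional_module` with non-empty core.
#' @param factor growth multiple of the mapped core size; default 5.
#' @param cap absolute size cap; default 500.
#' @param r restart probability for the expansion walk; default 0.5.
#' @return the expanded `functional_module`.
#' @export
expand_module <- function(net, m, factor = 5, cap = 500, r = 0.5) {
  stopifnot(inherits(m, "functional_module"), length(m$core_genes) > 0)
  target <- min(factor * length(m$core_genes), cap)
  if (target <= length(m$core_genes)) {
    m$expanded_genes <- m$core_genes
    return(m)
  }
  tm <- normalize_adjacency(net)
  profile <- rwr(tm, m$core_genes, r = r)
  candidates <- rank_by_probability(profile, exclude = m$core_genes)
  n_add <- min(target - length(m$core_genes), length(candidates))
  expanded <- sort(union(m$core_genes, head(candidates, n_add)))
  m$expanded_genes <- expanded
  m$subnetwork <- induced_subnetwork(net, expanded)
  m
}

#' The whole reference network as a single module
#'
#' Used for the whole-network variant of the scoring methods: a module whose
#' core is every network node; it is never expanded.
#'
#' @param net reference igraph gene network.
#' @return a `functional_module` with id "whole".
#' @export
whole_network_module <- function(net) {
  new_functional_module("whole", sort(network_genes(net)), character(), net)
}

#' Is a module eligible for trait-disease scoring?
#'
#' A module enters scoring only when it carries at least `min_each` trait
#' genes and `min_each` disease genes; with fewer mapped genes the RWR-based
#' reachability statistic is unstable.
#'
#' @param m a `functional_module`.
#' @param trait_genes,disease_genes character gene sets.
#' @param min_each minimum mapped genes on each side; default 5.
#' @return logical scalar.
#' @export
eligible_for_scoring <- function(m, trait_genes, disease_genes, min_each = 5) {
  genes <- module_genes(m)
  length(intersect(canonical_symbol(trait_genes), genes)) >= min_each &&
    length(intersect(canonical_symbol(disease_genes), genes)) >= min_each
}
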