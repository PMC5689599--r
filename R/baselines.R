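# Comparison methods: OBsp (average shortest-path proximity on a module) and
# OBoverlap (direct gene-set Jaccard), plus the literature-Jaccard gold-set
# builder.

#' Average shortest-path distance between two gene sets on a module
#'
#' Unweighted (hop-count) shortest paths are computed between every
#' (disease gene, obesity gene) pair mapped to the module's subnetwork; the
#' distance is the mean over pairs with a finite path. Genes present in both
#' sets contribute distance-0 pairs unless `drop_shared` is set.
#'
#' @param m a `functional_module`.
#' @param obesity_genes,disease_genes character gene sets.
#' @param drop_shared exclude genes in both sets from the pairing.
#' @param min_each eligibility threshold, as in [eligible_for_scoring()].
#' @return one-row tibble: module_id, mean_sp (Inf when no finite pair),
#'   n_pairs_finite, n_pairs_infinite.
#' @export
obsp_module_distance <- function(m, obesity_genes, disease_genes,
                                 drop_shared = FALSE, min_each = 5) {
  if (!eligible_for_scoring(m, obesity_genes, disease_genes, min_each)) {
    abort(sprintf("module %s is not eligible (needs >= %d mapped genes on each side)",
                  m$module_id, min_each))
  }
  genes <- module_genes(m)
  ob <- intersect(canonical_symbol(obesity_genes), genes)
  dis <- intersect(canonical_symbol(disease_genes), genes)
  if (drop_shared) {
    shared <- intersect(ob, dis)
    ob <- setdiff(ob, shared)
    dis <- setdiff(dis, shared)
  }
  if (length(ob) == 0 || length(dis) == 0) {
    return(tibble(module_id = m$module_id, mean_sp = Inf,
                  n_pairs_finite = 0L,
                  n_pairs_infinite = length(ob) * length(dis)))
  }
  d <- igraph::distances(m$subnetwork, v = dis, to = ob, weights = NA)
  finite <- is.finite(d)
  n_inf <- sum(!finite)
  if (n_inf > 0) {
    inform(sprintf("module %s: %d unreachable gene pair(s) excluded from the mean",
                   m$module_id, n_inf))
  }
  tibble(module_id = m$module_id,
         mean_sp = if (any(finite)) mean(d[finite]) else Inf,
         n_pairs_finite = sum(finite),
         n_pairs_infinite = as.integer(n_inf))
}

#' Rank diseases by minimum module shortest-path distance
#'
#' @param per_module tibble with columns `disease_id`, `module_id`,
#'   `mean_sp` (rows from [obsp_module_distance()] over diseases/modules).
#' @return a `disease_ranking` tibble sorted ascending by the minimum
#'   distance across modules (smaller = closer to the query trait).
#' @export
obsp_rank <- function(per_module) {
  stopifnot(all(c("disease_id", "module_id", "mean_sp") %in% names(per_module)))
  ranking <- per_module |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::summarise(
      score = min(.data$mean_sp),
      best_module_id = .data$module_id[which.min(.data$mean_sp)],
      n_modules = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$score, .data$disease_id)
  new_disease_ranking(ranking, direction = "ascending",
                      statistic = "min mean shortest path")
}

#' Jaccard coefficient of two sets
#' @param set_a,set_b character vectors (not both empty).
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) abort("jaccard of two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Rank diseases by direct gene-set overlap with the query trait
#'
#' OBoverlap: the Jaccard coefficient between each disease's gene set and the
#' query trait's gene set, ranked descending.
#'
#' @param traits named list of gene sets (trait_id -> genes).
#' @param query trait id of the query (e.g. "obesity").
#' @return a `disease_ranking` tibble sorted descending by Jaccard.
#' @export
oboverlap_rank <- function(traits, query) {
  if (!query %in% names(traits)) abort(paste0("query trait not found: ", query))
  qg <- canonical_symbol(traits[[query]])
  diseases <- setdiff(names(traits), query)
  ranking <- tibble(
    disease_id = diseases,
    score = vapply(diseases, function(d) jaccard(canonical_symbol(traits[[d]]), qg),
                   numeric(1), USE.NAMES = FALSE),
    best_module_id = NA_character_,
    n_modules = 1L
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$disease_id)
  new_disease_ranking(ranking, direction = "descending",
                      statistic = "gene-set Jaccard")
}

#' Build a gold trait list from literature co-occurrence counts
#'
#' For each disease, the Jaccard coefficient between the abstract-ID set
#' mentioning the disease and the set mentioning the query trait is
#' `n_both / (n_disease + n_query - n_both)`; diseases at or above
#' `threshold` are selected, and curated `manual_additions` are appended.
#'
#' @param per_disease data frame with columns `disease_id`, `n_disease`
#'   (abstracts mentioning the disease) and `n_both` (abstracts mentioning
#'   both the disease and the query trait).
#' @param n_query abstracts mentioning the query trait.
#' @param threshold inclusive Jaccard cutoff; default 0.004.
#' @param manual_additions trait ids always included.
#' @return character vector of gold trait ids (deduplicated, sorted).
#' @export
gold_set_from_counts <- function(per_disease, n_query, threshold = 0.004,
                                 manual_additions = character()) {
  stopifnot(all(c("disease_id", "n_disease", "n_both") %in% names(per_disease)))
  j <- per_disease$n_both /
    (per_disease$n_disease + n_query - per_disease$n_both)
  sort(unique(c(per_disease$disease_id[j >= threshold], manual_additions)))
}
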