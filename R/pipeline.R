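# End-to-end drivers: build (and optionally expand) the module catalogue,
# score every disease against the query trait on every eligible module, and
# rank the diseases.

#' Build the module catalogue for a scoring mode
#'
#' @param net reference igraph gene network.
#' @param sets gene-set collection (ignored for `mode = "whole"`).
#' @param mode "modularized" (gene sets mapped onto the network), "expanded"
#'   (RWR-grown to 5x or 500 genes) or "whole" (one module holding the full
#'   network).
#' @param max_set_size strict raw-size cap on gene sets; default 500.
#' @param factor,cap,r expansion parameters, see [expand_module()].
#' @return named list of `functional_module` objects.
#' @export
prepare_modules <- function(net, sets = NULL,
                            mode = c("expanded", "modularized", "whole"),
                            max_set_size = 500, factor = 5, cap = 500,
                            r = 0.5) {
  mode <- match.arg(mode)
  if (mode == "whole") {
    return(list(whole = whole_network_module(net)))
  }
  mods <- build_modules(net, sets, max_set_size = max_set_size)
  if (mode == "expanded") {
    mods <- lapply(mods, function(m) expand_module(net, m, factor = factor,
                                                   cap = cap, r = r))
  }
  mods
}

#' Score every disease against the query trait on every eligible module
#'
#' For each disease trait (every trait except `query`) and each module
#' carrying at least `min_each` query genes and `min_each` disease genes,
#' computes the OBNet permutation-tested reachability score. Module seeds are
#' derived deterministically from `seed`, so the full table is reproducible.
#'
#' @inheritParams permutation_pvalue
#' @param modules named list of `functional_module`s from
#'   [prepare_modules()].
#' @param traits named list of gene sets including the query trait.
#' @param query trait id of the query (e.g. "obesity").
#' @return tibble with one row per scored (disease, module) pair:
#'   trait_id, disease_id, module_id, es1, es2, es_beta, z, p, ...
#' @export
obnet_score_all <- function(modules, traits, query, n_perm = 100, seed = 1,
                            r = 0.5, beta = 0.1, include_seeds = FALSE,
                            min_each = 5, classic_increments = FALSE) {
  if (!query %in% names(traits)) abort(paste0("query trait not found: ", query))
  qg <- canonical_symbol(traits[[query]])
  diseases <- sort(setdiff(names(traits), query))
  mod_ids <- sort(names(modules))
  idx <- 0L
  rows <- list()
  for (d in diseases) {
    dg <- canonical_symbol(traits[[d]])
    for (mid in mod_ids) {
      idx <- idx + 1L
      m <- modules[[mid]]
      if (!eligible_for_scoring(m, qg, dg, min_each)) next
      res <- permutation_pvalue(m, qg, dg, n_perm = n_perm,
                                seed = child_seed(seed, idx), r = r,
                                beta = beta, include_seeds = include_seeds,
                                min_each = min_each,
                                classic_increments = classic_increments)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(trait_id = query, disease_id = d), res)
    }
  }
  if (length(rows) == 0) {
    warn("no eligible (disease, module) pair to score")
    return(tibble(trait_id = character(), disease_id = character(),
                  module_id = character(), es1 = numeric(), es2 = numeric(),
                  es_beta = numeric(), z = numeric(), p = numeric(),
                  n_permutations = integer(), null_mean = numeric(),
                  null_sd = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' OBNet disease ranking, end to end
#'
#' Convenience wrapper: [prepare_modules()] then [obnet_score_all()] then
#' [rank_diseases()].
#'
#' @inheritParams obnet_score_all
#' @inheritParams prepare_modules
#' @param adjust_method,adjust_scope forwarded to [rank_diseases()].
#' @return list with `scores` (per disease-module tibble, p_adjusted added)
#'   and `ranking` (a `disease_ranking`).
#' @export
obnet_rank <- function(net, sets, traits, query,
                       mode = c("expanded", "modularized", "whole"),
                       n_perm = 100, seed = 1, r = 0.5, beta = 0.1,
                       include_seeds = FALSE, min_each = 5,
                       max_set_size = 500, adjust_method = "BH",
                       adjust_scope = "within_disease") {
  mode <- match.arg(mode)
  modules <- prepare_modules(net, sets, mode = mode,
                             max_set_size = max_set_size, r = r)
  scores <- obnet_score_all(modules, traits, query, n_perm = n_perm,
                            seed = seed, r = r, beta = beta,
                            include_seeds = include_seeds,
                            min_each = min_each)
  ranking <- rank_diseases(scores, method = adjust_method,
                           scope = adjust_scope)
  adj <- if (adjust_scope == "global") {
    dplyr::mutate(scores, p_adjusted = p.adjust(.data$p, method = adjust_method))
  } else {
    dplyr::ungroup(dplyr::mutate(dplyr::group_by(scores, .data$disease_id),
                                 p_adjusted = p.adjust(.data$p, method = adjust_method)))
  }
  list(scores = adj, ranking = ranking)
}

#' OBsp disease ranking, end to end
#'
#' @inheritParams obnet_rank
#' @return list with `scores` (per disease-module distances) and `ranking`.
#' @export
obsp_rank_all <- function(net, sets, traits, query,
                          mode = c("expanded", "modularized", "whole"),
                          min_each = 5, max_set_size = 500, r = 0.5) {
  mode <- match.arg(mode)
  modules <- prepare_modules(net, sets, mode = mode,
                             max_set_size = max_set_size, r = r)
  qg <- canonical_symbol(traits[[query]])
  diseases <- sort(setdiff(names(traits), query))
  rows <- list()
  for (d in diseases) {
    dg <- canonical_symbol(traits[[d]])
    for (mid in sort(names(modules))) {
      m <- modules[[mid]]
      if (!eligible_for_scoring(m, qg, dg, min_each)) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(trait_id = query, disease_id = d),
        obsp_module_distance(m, qg, dg, min_each = min_each))
    }
  }
  if (length(rows) == 0) {
    warn("no eligible (disease, module) pair to score")
    rows <- list(tibble(trait_id = character(), disease_id = character(),
                        module_id = character(), mean_sp = numeric(),
                        n_pairs_finite = integer(), n_pairs_infinite = integer()))
  }
  scores <- dplyr::bind_rows(rows)
  list(scores = scores, ranking = obsp_rank(scores))
}

#' Write a disease ranking (and optional per-module scores) as TSV
#' @param ranking a `disease_ranking`.
#' @param path output TSV for the ranking.
#' @param scores optional per-module score tibble.
#' @param scores_path output TSV for `scores`.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, scores = NULL, scores_path = NULL) {
  readr::write_tsv(as_tibble(ranking), path)
  if (!is.null(scores) && !is.null(scores_path)) {
    readr::write_tsv(scores, scores_path)
  }
  invisible(path)
}
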