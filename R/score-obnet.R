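# OBNet: mutual reachability of two gene sets on a functional module.
#
# Direction 1 seeds the RWR on the disease genes and walks the module's
# RWR-sorted gene list accumulating +(N-G)/G on meeting a trait (obesity)
# gene and -G/(N-G) otherwise; the peak of the running sum is ES1. Direction
# 2 swaps the roles (obesity genes seed, disease genes are the targets) to
# give ES2. The combined score is the convex combination
#   ES_beta = beta * ES1 + (1 - beta) * ES2,   0 < beta < 1.
# Significance comes from re-drawing the obesity genes within the module,
# converting ES_beta to a z-score against the permutation null, and taking
# the upper-tail normal p-value.

#' Running-sum enrichment score over a ranked gene list
#'
#' Walks `ranked_genes` accumulating `(N - G) / G` when the gene is in
#' `targets` and `-G / (N - G)` otherwise; returns the peak (maximum) of the
#' running sum. Note the increments are deliberately not the zero-sum
#' Kolmogorov-Smirnov form: after the full traversal the sum equals
#' `(N - G) - G`, and the peak is read off the same curve. The classic
#' zero-sum increments (`1/G` and `-1/(N - G)`) are available via
#' `classic_increments`.
#'
#' @param ranked_genes character vector, the module's genes in RWR
#'   probability order.
#' @param targets character vector of target genes (subset of the list).
#' @param N list length used in the increments; defaults to
#'   `length(ranked_genes)`.
#' @param G target count used in the increments; defaults to the number of
#'   ranked genes in `targets`.
#' @param classic_increments use the zero-sum KS increments instead.
#' @return the peak running sum (a real number).
#' @export
running_sum_es <- function(ranked_genes, targets, N = length(ranked_genes),
                           G = sum(ranked_genes %in% targets),
                           classic_increments = FALSE) {
  if (G <= 0 || G >= N) {
    abort(sprintf("running-sum increments undefined for G = %d, N = %d", G, N))
  }
  hit <- ranked_genes %in% targets
  if (classic_increments) {
    inc <- ifelse(hit, 1 / G, -1 / (N - G))
  } else {
    inc <- ifelse(hit, (N - G) / G, -G / (N - G))
  }
  max(cumsum(inc))
}

# One direction of the OBNet statistic on a module transition matrix whose
# nodes are exactly the module genes. Seeds drive the RWR; by default the
# seeds are excluded from the traversed list (they trivially rank first and
# are not candidate genes to "meet"). If that exclusion leaves no target (or
# only targets) in the list - e.g. the target set coincides with the seed
# set - we fall back to traversing the full list including seeds.
directional_es <- function(tm, seeds, targets, r = 0.5,
                           include_seeds = FALSE, profile = NULL,
                           classic_increments = FALSE) {
  if (is.null(profile)) profile <- rwr(tm, seeds, r = r)
  seeds <- profile$seeds
  ranked <- rank_by_probability(profile,
                                exclude = if (include_seeds) character() else seeds)
  tin <- intersect(targets, ranked)
  if ((length(tin) == 0 || length(tin) == length(ranked)) && !include_seeds) {
    ranked <- rank_by_probability(profile)
    tin <- intersect(targets, ranked)
  }
  list(es = running_sum_es(ranked, tin, length(ranked), length(tin),
                           classic_increments = classic_increments),
       N = length(ranked), G = length(tin), profile = profile)
}

#' OBNet enrichment score of a trait-disease pair on one module
#'
#' @param m a `functional_module`, eligible per [eligible_for_scoring()].
#' @param obesity_genes query-trait gene set (the set that is permuted for
#'   significance testing).
#' @param disease_genes disease gene set.
#' @param r restart probability; default 0.5.
#' @param beta weight of the disease-seeded direction in the combination;
#'   default 0.1.
#' @param include_seeds traverse the RWR seeds as candidates in the running
#'   sum (default FALSE; see Details in the package vignette).
#' @param min_each eligibility threshold forwarded to
#'   [eligible_for_scoring()].
#' @param classic_increments forwarded to [running_sum_es()].
#' @return an `enrichment_score`: list with es1, es2, es_beta, beta,
#'   module_id, and the (N, G) bookkeeping of each direction.
#' @export
obnet_module_score <- function(m, obesity_genes, disease_genes, r = 0.5,
                               beta = 0.1, include_seeds = FALSE,
                               min_each = 5, classic_increments = FALSE) {
  stopifnot(beta > 0, beta < 1)
  if (!eligible_for_scoring(m, obesity_genes, disease_genes, min_each)) {
    abort(sprintf("module %s is not eligible (needs >= %d mapped genes on each side)",
                  m$module_id, min_each))
  }
  genes <- module_genes(m)
  ob <- intersect(canonical_symbol(obesity_genes), genes)
  dis <- intersect(canonical_symbol(disease_genes), genes)
  tm <- normalize_adjacency(m$subnetwork)
  d1 <- directional_es(tm, seeds = dis, targets = ob, r = r,
                       include_seeds = include_seeds,
                       classic_increments = classic_increments)
  d2 <- directional_es(tm, seeds = ob, targets = dis, r = r,
                       include_seeds = include_seeds,
                       classic_increments = classic_increments)
  structure(list(es1 = d1$es, es2 = d2$es,
                 es_beta = beta * d1$es + (1 - beta) * d2$es,
                 beta = beta, module_id = m$module_id,
                 N1 = d1$N, G1 = d1$G, N2 = d2$N, G2 = d2$G),
            class = "enrichment_score")
}

# Internal scorer shared by the observed statistic and the permutation null:
# scores one (obesity set, disease set) pair on a prebuilt module transition
# matrix, optionally reusing the disease-seeded RWR profile (it does not
# depend on the obesity set).
score_pair <- function(tm, ob, dis, r, beta, include_seeds,
                       disease_profile = NULL, classic_increments = FALSE) {
  d1 <- directional_es(tm, seeds = dis, targets = ob, r = r,
                       include_seeds = include_seeds,
                       profile = disease_profile,
                       classic_increments = classic_increments)
  d2 <- directional_es(tm, seeds = ob, targets = dis, r = r,
                       include_seeds = include_seeds,
                       classic_increments = classic_increments)
  list(es1 = d1$es, es2 = d2$es,
       es_beta = beta * d1$es + (1 - beta) * d2$es,
       disease_profile = d1$profile)
}

#' Permutation significance of the OBNet score on one module
#'
#' The observed `ES_beta` is compared with a null distribution obtained by
#' re-drawing the obesity genes within the module: each permutation draws
#' `|obesity genes in module|` genes uniformly without replacement from the
#' module's gene universe and recomputes both directions of the statistic.
#' The score is converted to a z-statistic against the null mean and standard
#' deviation, and the p-value is the upper-tail normal probability.
#'
#' When `include_seeds = FALSE`, the disease seed genes are excluded both
#' from the observed obesity set and from the permutation universe, so the
#' observed and null statistics are treated symmetrically.
#'
#' @inheritParams obnet_module_score
#' @param n_perm number of permutations; default 100.
#' @param seed integer seed making the null reproducible.
#' @return one-row tibble: module_id, es1, es2, es_beta, z, p,
#'   n_permutations, null_mean, null_sd.
#' @export
permutation_pvalue <- function(m, obesity_genes, disease_genes, n_perm = 100,
                               seed = NULL, r = 0.5, beta = 0.1,
                               include_seeds = FALSE, min_each = 5,
                               classic_increments = FALSE) {
  if (!eligible_for_scoring(m, obesity_genes, disease_genes, min_each)) {
    abort(sprintf("module %s is not eligible (needs >= %d mapped genes on each side)",
                  m$module_id, min_each))
  }
  genes <- module_genes(m)
  ob <- intersect(canonical_symbol(obesity_genes), genes)
  dis <- intersect(canonical_symbol(disease_genes), genes)
  tm <- normalize_adjacency(m$subnetwork)

  universe <- genes
  ob_draw <- ob
  if (!include_seeds) {
    universe <- setdiff(genes, dis)
    ob_draw <- setdiff(ob, dis)
    if (length(ob_draw) == 0) {
      # obesity genes coincide with the disease seeds; fall back to the
      # full universe so the null has the same degenerate geometry as the
      # observed statistic (which includes seeds in this case)
      universe <- genes
      ob_draw <- ob
    }
  }
  k <- length(ob_draw)

  obs <- score_pair(tm, ob, dis, r, beta, include_seeds,
                    classic_increments = classic_increments)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm_ob <- sample(universe, k)
      score_pair(tm, perm_ob, dis, r, beta, include_seeds,
                 disease_profile = obs$disease_profile,
                 classic_increments = classic_increments)$es_beta
    }, numeric(1))
  })
  mu <- mean(null_scores)
  sigma <- sd(null_scores)
  if (!is.finite(sigma) || sigma == 0) {
    inform(sprintf("degenerate permutation null on module %s (sd = 0)",
                   m$module_id))
    z <- 0
    p <- if (obs$es_beta <= mu) 1 else .Machine$double.xmin
  } else {
    z <- (obs$es_beta - mu) / sigma
    p <- pnorm(z, lower.tail = FALSE)
  }
  tibble(module_id = m$module_id, es1 = obs$es1, es2 = obs$es2,
         es_beta = obs$es_beta, z = z, p = p,
         n_permutations = as.integer(n_perm), null_mean = mu, null_sd = sigma)
}

#' Rank diseases by their minimum adjusted module p-value
#'
#' P-values are adjusted for multiple testing (Benjamini-Hochberg by
#' default) across the modules scored for each disease (`scope =
#' "within_disease"`) or across all disease-module pairs at once (`scope =
#' "global"`); each disease then receives the minimum adjusted p over its
#' modules and diseases are sorted ascending (ties broken on the id).
#'
#' @param results tibble with columns `disease_id`, `module_id`, `p` (e.g.
#'   rows from [permutation_pvalue()] bound together by [obnet_rank()]).
#' @param method adjustment method passed to [stats::p.adjust()]; default
#'   "BH".
#' @param scope adjustment scope, see above.
#' @return a `disease_ranking` tibble: disease_id, score (min adjusted p;
#'   smaller = more obesity-related), best_module_id, n_modules.
#' @export
rank_diseases <- function(results, method = "BH",
                          scope = c("within_disease", "global")) {
  scope <- match.arg(scope)
  stopifnot(all(c("disease_id", "module_id", "p") %in% names(results)))
  adj <- if (scope == "global") {
    dplyr::mutate(results, p_adjusted = p.adjust(.data$p, method = method))
  } else {
    dplyr::mutate(dplyr::group_by(results, .data$disease_id),
                  p_adjusted = p.adjust(.data$p, method = method))
  }
  ranking <- adj |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::summarise(
      score = min(.data$p_adjusted),
      best_module_id = .data$module_id[which.min(.data$p_adjusted)],
      n_modules = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$score, .data$disease_id)
  new_disease_ranking(ranking, direction = "ascending",
                      statistic = "min adjusted p")
}

new_disease_ranking <- function(tb, direction, statistic) {
  structure(tb, direction = direction, statistic = statistic,
            class = c("disease_ranking", class(tb)))
}
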