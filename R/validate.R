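# Expression-based validation statistics: module differential connectivity
# (MDC), pairwise module-overlap Fisher tests with BH adjustment, and the
# size-preserving module-label permutation study.

#' Module differential connectivity (MDC)
#'
#' Connectivity of a gene pair within a condition is the absolute Pearson
#' correlation of the two genes across that condition's samples (optionally
#' soft-thresholded, `|r|^power`, WGCNA-style). MDC is the ratio of the mean
#' pairwise connectivity over all module gene pairs in `cond_a` to that in
#' `cond_b`; a value above 1 means the module gains connectivity in
#' `cond_a`.
#'
#' @param expr an `expression_matrix`.
#' @param module_genes character gene set (>= 2 genes on the matrix).
#' @param cond_a,cond_b condition labels (each with >= 3 samples).
#' @param power soft-threshold exponent on `|r|`; default 1.
#' @return the MDC ratio (positive real).
#' @export
mdc <- function(expr, module_genes, cond_a, cond_b, power = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- intersect(canonical_symbol(module_genes), rownames(expr$values))
  if (length(genes) < 2) abort("need at least 2 module genes on the matrix")
  conn <- function(cond) {
    cols <- expr$condition == cond
    if (sum(cols) < 3) abort(paste0("condition ", cond, " has < 3 samples"))
    r <- cor(t(expr$values[genes, cols, drop = FALSE]))
    mean(abs(r[upper.tri(r)])^power)
  }
  denom <- conn(cond_b)
  if (denom == 0) abort("zero mean connectivity in the denominator condition")
  conn(cond_a) / denom
}

#' Permutation significance of MDC across modules
#'
#' Null MDC values come from shuffling the condition labels over samples;
#' the two-sided empirical p-value (with add-one correction) compares
#' `|log MDC|` of the observed ratio with the null, and p-values are
#' BH-adjusted across modules.
#'
#' @param expr an `expression_matrix`.
#' @param modules named list of gene sets (module label -> genes).
#' @param cond_a,cond_b condition labels.
#' @param n_perm number of label shuffles; default 100.
#' @param seed integer seed.
#' @param power soft-threshold exponent, see [mdc()].
#' @return tibble: module, n_genes, mdc, p, fdr.
#' @export
mdc_significance <- function(expr, modules, cond_a, cond_b, n_perm = 100,
                             seed = NULL, power = 1) {
  labels <- expr$condition
  observed <- vapply(modules, function(g) mdc(expr, g, cond_a, cond_b, power),
                     numeric(1))
  pvals <- with_seed(seed, {
    vapply(seq_along(modules), function(i) {
      obs_stat <- abs(log(observed[i]))
      hits <- 0L
      for (k in seq_len(n_perm)) {
        shuffled <- sample(labels)
        perm_expr <- expression_matrix(expr$values, shuffled)
        null_mdc <- mdc(perm_expr, modules[[i]], cond_a, cond_b, power)
        if (abs(log(null_mdc)) >= obs_stat) hits <- hits + 1L
      }
      (hits + 1) / (n_perm + 1)
    }, numeric(1))
  })
  tibble(module = names(modules),
         n_genes = lengths(modules),
         mdc = unname(observed),
         p = pvals,
         fdr = p.adjust(pvals, method = "BH"))
}

#' Pairwise module-overlap Fisher tests
#'
#' For every pair of modules (one from each collection), a one-sided
#' (enrichment) Fisher's exact test on the 2x2 membership table over the
#' gene universe, BH-adjusted across all pairs. The one-sided p equals the
#' upper-tail hypergeometric probability of the observed overlap.
#'
#' @param modules_a,modules_b named lists of gene sets.
#' @param universe gene universe; defaults to the union of all module genes.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return tibble: module_a, module_b, n_a, n_b, overlap, p, p_adjusted.
#' @export
overlap_fisher <- function(modules_a, modules_b, universe = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(universe)) {
    universe <- union(unlist(modules_a, use.names = FALSE),
                      unlist(modules_b, use.names = FALSE))
  }
  universe <- unique(canonical_symbol(universe))
  if (length(universe) == 0) abort("empty gene universe")
  grid <- tidyr::expand_grid(module_a = names(modules_a),
                             module_b = names(modules_b))
  res <- purrr::pmap_dfr(grid, function(module_a, module_b) {
    a <- intersect(canonical_symbol(modules_a[[module_a]]), universe)
    b <- intersect(canonical_symbol(modules_b[[module_b]]), universe)
    k <- length(intersect(a, b))
    p <- if (alternative == "greater") {
      hypergeom_upper(k, length(a), length(universe), length(b))
    } else {
      tab <- matrix(c(k, length(a) - k, length(b) - k,
                      length(universe) - length(a) - length(b) + k), 2, 2)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    tibble(module_a = module_a, module_b = module_b,
           n_a = length(a), n_b = length(b), overlap = k, p = p)
  })
  dplyr::mutate(res, p_adjusted = p.adjust(.data$p, method = "BH"))
}

#' Upper-tail normal p-value of an observed count against a permutation null
#'
#' The final step of [overlap_permutation_study()]: given the permutation
#' mean and standard deviation of the overlap count, the significance of the
#' observed count is the upper-tail probability of the normal z-score
#' `(observed - mean) / sd`.
#'
#' @param observed observed count.
#' @param null_mean,null_sd permutation mean and standard deviation.
#' @return list with `z` and `p`.
#' @export
normal_tail_p <- function(observed, null_mean, null_sd) {
  z <- (observed - null_mean) / null_sd
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Size-preserving module-label permutation study of overlap counts
#'
#' Assesses whether the number of `modules_a` members significantly
#' overlapping the selected top modules of `modules_b` exceeds chance.
#' Each permutation reassigns the genes of `modules_b` to module labels
#' uniformly at random, preserving every module's size, re-applies
#' `selector` to pick the top `top_k` modules, and counts the `modules_a`
#' members whose Fisher overlap with any selected module reaches
#' `fdr_cutoff` after BH. The observed count is compared with the
#' permutation null via an upper-tail normal p-value.
#'
#' @param modules_a named list of gene sets (held fixed).
#' @param modules_b named list of gene sets whose labels are shuffled.
#' @param selector function(modules) -> character vector of selected module
#'   labels (e.g. top modules by MDC); defaults to selecting all of
#'   `modules_b`.
#' @param n_perm number of permutations; default 1000.
#' @param top_k number of modules the selector should return; selections are
#'   truncated to this length. Default 10.
#' @param seed integer seed.
#' @param universe gene universe for the Fisher tests.
#' @param fdr_cutoff BH-adjusted significance rule for "significant
#'   overlap"; default 0.05.
#' @return list: observed (count), mean_hits, sd_hits, z, p_observed, and
#'   `null_counts` (length `n_perm` integer vector).
#' @export
overlap_permutation_study <- function(modules_a, modules_b, selector = NULL,
                                      n_perm = 1000, top_k = 10, seed = NULL,
                                      universe = NULL, fdr_cutoff = 0.05) {
  if (is.null(selector)) selector <- function(mods) names(mods)
  if (is.null(universe)) {
    universe <- union(unlist(modules_a, use.names = FALSE),
                      unlist(modules_b, use.names = FALSE))
  }
  count_hits <- function(mods_b) {
    sel <- head(selector(mods_b), top_k)
    ft <- overlap_fisher(modules_a, mods_b[sel], universe = universe)
    sig <- dplyr::filter(ft, .data$p_adjusted < fdr_cutoff)
    length(unique(sig$module_a))
  }
  observed <- count_hits(modules_b)
  sizes <- lengths(modules_b)
  pool <- unlist(modules_b, use.names = FALSE)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- sample(pool)
      perm <- split(shuffled, rep(names(sizes), sizes))[names(sizes)]
      stopifnot(identical(lengths(perm), sizes))
      count_hits(perm)
    }, integer(1))
  })
  mu <- mean(null_counts)
  sigma <- sd(null_counts)
  tail <- normal_tail_p(observed, mu, sigma)
  list(observed = observed, mean_hits = mu, sd_hits = sigma,
       z = tail$z, p_observed = tail$p, null_counts = null_counts)
}
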