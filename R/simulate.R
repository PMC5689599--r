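# Synthetic benchmark generator. Emulates the external inputs (reference
# interactome, functional gene-set catalogue, trait-gene catalogue, gold
# list, expression matrix) with planted, parameterized signal so that every
# analysis in the package can be exercised and calibrated without downloads.
#
# The default network is a stochastic block model: blocks play the role of
# biological processes, so the "functional modules" sampled from them induce
# internally dense subnetworks, as GO/KEGG sets do on a real interactome.
# Query-trait (obesity) genes are seeded inside a few chosen blocks; each
# planted disease draws its genes from the 2-hop network neighbourhood of
# the query genes inside those blocks with probability `proximity_effect`,
# and uniformly otherwise, so `proximity_effect` dials the network proximity
# signal from exchangeable-with-background (0) to fully planted (1).

sample_network <- function(n_genes, model, p_er, m_ba, n_blocks, p_in, p_out) {
  g <- switch(model,
    erdos_renyi = igraph::sample_gnp(n_genes, p_er),
    barabasi_albert = igraph::sample_pa(n_genes, m = m_ba, directed = FALSE),
    stochastic_block = {
      sizes <- rep(n_genes %/% n_blocks, n_blocks)
      sizes[seq_len(n_genes %% n_blocks)] <- sizes[seq_len(n_genes %% n_blocks)] + 1L
      pm <- matrix(p_out, n_blocks, n_blocks)
      diag(pm) <- p_in
      igraph::sample_sbm(n_genes, pref.matrix = pm, block.sizes = sizes)
    },
    abort(paste0("unknown network model: ", model))
  )
  igraph::V(g)$name <- sprintf("G%05d", seq_len(n_genes))
  igraph::simplify(g)
}

#' Generate a planted-signal benchmark
#'
#' @param n_genes network size; default 3000 (large relative to the module
#'   sizes, so RWR expansion keeps modules local as it does on a real
#'   interactome).
#' @param network_model "stochastic_block" (default), "erdos_renyi" or
#'   "barabasi_albert".
#' @param p_er edge probability for the Erdos-Renyi model.
#' @param m_ba edges per step for the Barabasi-Albert model.
#' @param n_modules number of functional gene sets (= SBM blocks); default 20.
#' @param module_size_range inclusive range of gene-set sizes; default
#'   c(30, 60). Each set draws 90% of its genes from its own block and 10%
#'   from the rest of the network, emulating imperfect annotation.
#' @param n_diseases total diseases in the trait catalogue; default 20.
#' @param n_planted_ord diseases planted as obesity-related; default 4.
#' @param proximity_effect probability that a planted disease gene is drawn
#'   from the 2-hop neighbourhood of the query genes inside the shared
#'   blocks (vs uniformly); default 0.8.
#' @param n_query_genes query-trait gene-set size; default 25.
#' @param disease_size_range inclusive range of disease gene-set sizes;
#'   default c(15, 25).
#' @param n_shared_modules blocks in which the query genes are seeded;
#'   default 2.
#' @param p_in,p_out SBM within/between-block edge probabilities; defaults
#'   0.15 and 0.005.
#' @param query trait id of the query; default "obesity".
#' @param seed integer seed; the whole benchmark is reproducible from it.
#' @return list with `network` (igraph), `gene_sets`
#'   (`gene_set_collection`), `traits` (named list incl. the query), `gold`
#'   (planted disease ids) and `truth` (generator bookkeeping: block
#'   assignment, shared modules, per-disease planted-gene counts).
#' @export
generate_benchmark <- function(n_genes = 3000,
                               network_model = "stochastic_block",
                               p_er = 0.05, m_ba = 3,
                               n_modules = 20,
                               module_size_range = c(30, 60),
                               n_diseases = 20, n_planted_ord = 4,
                               proximity_effect = 0.8,
                               n_query_genes = 25,
                               disease_size_range = c(15, 25),
                               n_shared_modules = 2,
                               p_in = 0.15, p_out = 0.005,
                               query = "obesity", seed = 1) {
  stopifnot(n_planted_ord <= n_diseases,
            proximity_effect >= 0, proximity_effect <= 1,
            max(module_size_range) <= n_genes)
  with_seed(seed, {
    net <- sample_network(n_genes, network_model, p_er, m_ba,
                          n_modules, p_in, p_out)
    genes <- network_genes(net)
    sizes <- rep(n_genes %/% n_modules, n_modules)
    sizes[seq_len(n_genes %% n_modules)] <- sizes[seq_len(n_genes %% n_modules)] + 1L
    block <- rep(seq_len(n_modules), times = sizes)  # matches sample_network order

    sets <- lapply(seq_len(n_modules), function(b) {
      size <- sample(seq(module_size_range[1], module_size_range[2]), 1)
      own <- genes[block == b]
      n_own <- min(length(own), round(0.9 * size))
      c(sample(own, n_own), sample(genes[block != b], size - n_own))
    })
    names(sets) <- sprintf("M%02d", seq_len(n_modules))
    collection <- gene_set_collection(sets, source_tag = "synthetic")

    shared_idx <- sample(seq_len(n_modules), n_shared_modules)
    shared <- names(sets)[shared_idx]
    shared_pool <- unique(unlist(sets[shared], use.names = FALSE))
    query_genes <- sample(shared_pool, min(n_query_genes, length(shared_pool)))

    # Planted pool: 2-hop neighbours of the query genes within the shared
    # blocks but outside the core gene sets - the zone RWR expansion grows
    # into. Planted diseases are therefore invisible to the unexpanded
    # modules and recovered by the expanded ones.
    d <- igraph::distances(net, v = query_genes, weights = NA)
    near <- colnames(d)[apply(d, 2, min) <= 2]
    planted_pool <- setdiff(intersect(near, genes[block %in% shared_idx]),
                            c(query_genes, shared_pool))
    if (length(planted_pool) == 0) planted_pool <- setdiff(near, query_genes)

    disease_ids <- sprintf("D%03d", seq_len(n_diseases))
    planted <- disease_ids[seq_len(n_planted_ord)]
    traits <- list()
    planted_counts <- integer(n_diseases)
    for (i in seq_len(n_diseases)) {
      size <- sample(seq(disease_size_range[1], disease_size_range[2]), 1)
      if (disease_ids[i] %in% planted) {
        n_near <- stats::rbinom(1, size, proximity_effect)
        n_near <- min(n_near, length(planted_pool))
        g <- c(sample(planted_pool, n_near),
               sample(setdiff(genes, planted_pool), size - n_near))
      } else {
        g <- sample(genes, size)
      }
      planted_counts[i] <- length(intersect(g, planted_pool))
      traits[[disease_ids[i]]] <- g
    }
    traits[[query]] <- query_genes

    list(network = net,
         gene_sets = collection,
         traits = traits,
         gold = planted,
         truth = list(block = setNames(block, genes),
                      shared_modules = shared,
                      planted_pool = planted_pool,
                      planted = planted,
                      planted_gene_counts = setNames(planted_counts, disease_ids),
                      seed = seed))
  })
}

#' Generate a module-structured expression matrix
#'
#' Within each module, gene expression in a condition follows an
#' equicorrelated multivariate normal: gene g in sample s is
#' `sqrt(rho) * f_s + sqrt(1 - rho) * e_gs` with standard-normal factor and
#' noise, giving pairwise correlation `rho`. Background genes (outside every
#' module) are independent noise in both conditions.
#'
#' @param modules named list of gene sets.
#' @param n_samples_a,n_samples_b samples per condition; defaults 50.
#' @param rho_in_a,rho_in_b within-module correlation per condition (in
#'   `[0, 1)`).
#' @param n_background independent background genes appended; default 0.
#' @param conditions labels of the two conditions; default c("A", "B").
#' @param seed integer seed.
#' @return an `expression_matrix`.
#' @export
generate_expression <- function(modules, n_samples_a = 50, n_samples_b = 50,
                                rho_in_a = 0.5, rho_in_b = 0.5,
                                n_background = 0,
                                conditions = c("A", "B"), seed = 1) {
  stopifnot(rho_in_a >= 0, rho_in_a < 1, rho_in_b >= 0, rho_in_b < 1)
  with_seed(seed, {
    genes <- unique(unlist(modules, use.names = FALSE))
    if (n_background > 0) {
      genes <- c(genes, sprintf("BG%05d", seq_len(n_background)))
    }
    n <- n_samples_a + n_samples_b
    values <- matrix(rnorm(length(genes) * n), length(genes), n,
                     dimnames = list(canonical_symbol(genes),
                                     sprintf("S%04d", seq_len(n))))
    cols_a <- seq_len(n_samples_a)
    cols_b <- n_samples_a + seq_len(n_samples_b)
    add_factor <- function(vals, gset, cols, rho) {
      g <- intersect(canonical_symbol(gset), rownames(vals))
      f <- rnorm(length(cols))
      vals[g, cols] <- sqrt(rho) * matrix(f, length(g), length(cols),
                                          byrow = TRUE) +
        sqrt(1 - rho) * vals[g, cols]
      vals
    }
    for (gset in modules) {
      values <- add_factor(values, gset, cols_a, rho_in_a)
      values <- add_factor(values, gset, cols_b, rho_in_b)
    }
    expression_matrix(values, rep(conditions, c(n_samples_a, n_samples_b)))
  })
}
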