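# Shared fixtures and independent oracles used across the suite.

# --- tiny graphs -----------------------------------------------------------

path_net <- function(genes = c("A", "B", "C")) {
  gene_network(data.frame(gene1 = genes[-length(genes)], gene2 = genes[-1]))
}

star_net <- function(hub = "HUB", n_leaves = 6) {
  gene_network(data.frame(gene1 = hub,
                          gene2 = sprintf("L%02d", seq_len(n_leaves))))
}

random_net <- function(n, p = 0.2, seed = 1) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  # ensure no isolated-only graph pathologies: add a spanning path
  extra <- data.frame(gene1 = sprintf("N%03d", seq_len(n - 1)),
                      gene2 = sprintf("N%03d", 2:n))
  el <- igraph::as_edgelist(g)
  edges <- rbind(data.frame(gene1 = el[, 1], gene2 = el[, 2]), extra)
  gene_network(edges)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- independent oracles ---------------------------------------------------

# Prefix-max running sum in exact integer arithmetic: increments scaled by
# G * (N - G) so hits add (N - G)^2 and misses subtract G^2.
es_prefix_oracle <- function(hits, N, G) {
  inc <- ifelse(hits, (N - G)^2, -G^2)
  best <- -Inf
  run <- 0
  for (x in inc) {
    run <- run + x
    if (run > best) best <- run
  }
  best / (G * (N - G))
}

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
floyd_warshall <- function(net) {
  nodes <- network_genes(net)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  el <- igraph::as_edgelist(net)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1
    d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Upper-tail hypergeometric probability by explicit summation of the pmf:
# P(X >= k) with `succ` successes in a population of `pop`, drawing `draws`.
hyper_tail_oracle <- function(k, succ, pop, draws) {
  kk <- seq(max(k, 0), min(succ, draws))
  if (length(kk) == 0) return(0)
  sum(choose(succ, kk) * choose(pop - succ, draws - kk) / choose(pop, draws))
}

# AUC as the normalized Mann-Whitney U statistic with 0.5 credit for ties.
auc_rank_oracle <- function(score_pos, score_neg) {
  wins <- 0
  for (a in score_pos) {
    for (b in score_neg) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
  }
  wins / (length(score_pos) * length(score_neg))
}

# Direct linear solve of the RWR fixed point (I - (1 - r) A') p = r P0.
rwr_solve_oracle <- function(tm, seeds, r) {
  nodes <- tm$node_order
  p0 <- numeric(length(nodes))
  p0[match(seeds, nodes)] <- 1 / length(seeds)
  A <- as.matrix(tm$matrix)
  p <- solve(diag(length(nodes)) - (1 - r) * A, r * p0)
  p <- p / sum(p)
  setNames(p, nodes)
}
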