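# The OBNet running-sum statistic, its permutation test and disease ranking.

test_that("hand-computed running sums match", {
  # N = 4, G = 2: hit +1, miss -1
  expect_equal(running_sum_es(c("t1", "t2", "m1", "m2"), c("t1", "t2")), 2)
  expect_equal(running_sum_es(c("m1", "m2", "t1", "t2"), c("t1", "t2")), 0)
  expect_equal(running_sum_es(c("m1", "t1", "m2", "t2"), c("t1", "t2")), 0)
})

test_that("degenerate target counts are rejected", {
  expect_error(running_sum_es(c("a", "b"), character()), "undefined")
  expect_error(running_sum_es(c("a", "b"), c("a", "b")), "undefined")
})

test_that("the peak equals the exhaustive prefix-max oracle on random orderings", {
  set.seed(123)
  for (rep in 1:200) {
    N <- sample(3:12, 1)
    G <- sample(seq_len(N - 1), 1)
    genes <- sprintf("g%02d", seq_len(N))
    targets <- sample(genes, G)
    ord <- sample(genes)
    expect_equal(running_sum_es(ord, targets, N, G),
                 es_prefix_oracle(ord %in% targets, N, G),
                 tolerance = 1e-12)
  }
})

test_that("the full traversal lands on (N - G) - G: the increments are not zero-sum", {
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(4:15, 1)
    G <- sample(seq_len(N - 1), 1)
    genes <- sprintf("g%02d", seq_len(N))
    targets <- sample(genes, G)
    ord <- sample(genes)
    hit <- ord %in% targets
    endpoint <- sum(ifelse(hit, (N - G) / G, -G / (N - G)))
    expect_equal(endpoint, (N - G) - G, tolerance = 1e-9)
    # classic increments do telescope to zero
    endpoint_classic <- sum(ifelse(hit, 1 / G, -1 / (N - G)))
    expect_equal(endpoint_classic, 0, tolerance = 1e-9)
  }
})

make_planted_module <- function() {
  # two dense cliques bridged by one edge; obesity in clique 1, disease
  # either in clique 1 (planted, proximal) or clique 2 (control, distal)
  c1 <- sprintf("A%02d", 1:12)
  c2 <- sprintf("B%02d", 1:12)
  clique_edges <- function(v) t(utils::combn(v, 2))
  edges <- rbind(clique_edges(c1), clique_edges(c2), c("A01", "B01"))
  net <- gene_network(data.frame(gene1 = edges[, 1], gene2 = edges[, 2]))
  build_modules(net, list(m = c(c1, c2)))$m
}

test_that("es_beta is the stated convex combination and symmetric cases collapse", {
  m <- make_planted_module()
  ob <- sprintf("A%02d", 1:5)
  dis <- sprintf("A%02d", 8:12)
  for (beta in c(0.1, 0.5, 0.9)) {
    sc <- obnet_module_score(m, ob, dis, beta = beta)
    expect_equal(sc$es_beta, beta * sc$es1 + (1 - beta) * sc$es2)
  }
  # identical seed and target sets: both directions coincide by symmetry
  sym <- obnet_module_score(m, ob, ob, beta = 0.3)
  expect_equal(sym$es1, sym$es2)
  expect_equal(sym$es_beta, sym$es1)
})

test_that("a proximal gene set outscores a distal one on the same module", {
  m <- make_planted_module()
  ob <- sprintf("A%02d", 1:5)
  planted <- obnet_module_score(m, ob, sprintf("A%02d", 8:12))
  control <- obnet_module_score(m, ob, sprintf("B%02d", 8:12))
  expect_gt(planted$es_beta, control$es_beta)
})

test_that("permutation p-values are deterministic given a seed and track the z-score", {
  m <- make_planted_module()
  ob <- sprintf("A%02d", 1:5)
  dis <- sprintf("A%02d", 8:12)
  r1 <- permutation_pvalue(m, ob, dis, n_perm = 50, seed = 99)
  r2 <- permutation_pvalue(m, ob, dis, n_perm = 50, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$p, pnorm(r1$z, lower.tail = FALSE))
  expect_gt(r1$z, 0)  # planted proximity shows up as enrichment
  r3 <- permutation_pvalue(m, ob, dis, n_perm = 50, seed = 100)
  expect_false(identical(r1$p, r3$p))
})

test_that("ranking adjusts within disease and sorts by the minimum adjusted p", {
  results <- tibble::tibble(
    disease_id = c("d1", "d1", "d2"),
    module_id = c("m1", "m2", "m1"),
    p = c(0.5, 0.01, 0.01)
  )
  rk <- rank_diseases(results)
  # BH over {0.5, 0.01}: adjusted {0.5, 0.02}; d2 has a single test
  expect_identical(rk$disease_id, c("d2", "d1"))
  expect_equal(rk$score[rk$disease_id == "d1"], 0.02)
  expect_equal(rk$score[rk$disease_id == "d2"], 0.01)
  expect_identical(rk$best_module_id[rk$disease_id == "d1"], "m2")
})
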