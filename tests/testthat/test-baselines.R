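# OBsp shortest-path proximity, OBoverlap Jaccard, and the gold-set builder.

test_that("path-graph distances come out by hand", {
  net <- path_net(sprintf("P%02d", 1:12))
  m <- build_modules(net, list(m = sprintf("P%02d", 1:12)))$m
  ob <- sprintf("P%02d", 1:5)
  dis <- sprintf("P%02d", 8:12)
  res <- obsp_module_distance(m, ob, dis)
  # mean over the 25 pairs |i - j| for i in 1:5, j in 8:12
  expected <- mean(abs(outer(1:5, 8:12, "-")))
  expect_equal(res$mean_sp, expected)
  expect_equal(res$n_pairs_finite, 25L)
})

test_that("shared genes contribute distance-zero pairs unless dropped", {
  net <- path_net(c("A", "B", "C", "D", "E"))
  m <- build_modules(net, list(m = c("A", "B", "C", "D", "E")))$m
  res <- obsp_module_distance(m, c("A", "B"), "A", min_each = 1)
  expect_equal(res$mean_sp, 0.5)  # pairs (A,A)=0 and (A,B)=1
  # dropping the shared gene A leaves pairs (D,B)=2 only
  res2 <- obsp_module_distance(m, c("A", "B"), c("A", "D"),
                               drop_shared = TRUE, min_each = 1)
  expect_equal(res2$mean_sp, 2)
  # a fully shared disease set degenerates to no pairs at all
  res3 <- obsp_module_distance(m, c("A", "B"), "A", drop_shared = TRUE,
                               min_each = 1)
  expect_equal(res3$mean_sp, Inf)
})

test_that("unreachable pairs are excluded from the mean and counted", {
  # two components: A-B and C-D
  net <- gene_network(data.frame(gene1 = c("A", "C"), gene2 = c("B", "D")))
  m <- build_modules(net, list(m = c("A", "B", "C", "D")))$m
  res <- suppressMessages(obsp_module_distance(m, c("A", "C"), c("B", "D"),
                                               min_each = 1))
  expect_equal(res$mean_sp, 1)       # finite pairs: (A,B), (C,D)
  expect_equal(res$n_pairs_infinite, 2L)
})

test_that("module distances match the Floyd-Warshall oracle on random graphs", {
  for (s in 1:5) {
    net <- suppressMessages(random_net(30, 0.08, seed = s))
    m <- build_modules(net, list(m = network_genes(net)))$m
    ob <- sample(network_genes(net), 6)
    dis <- sample(network_genes(net), 6)
    res <- suppressMessages(obsp_module_distance(m, ob, dis))
    d <- floyd_warshall(net)[dis, ob]
    expect_equal(res$mean_sp, mean(d[is.finite(d)]))
    expect_equal(res$n_pairs_finite, sum(is.finite(d)))
  }
})

test_that("the distance is symmetric in the two gene-set arguments", {
  net <- suppressMessages(random_net(25, 0.12, seed = 17))
  m <- build_modules(net, list(m = network_genes(net)))$m
  a <- sprintf("N%03d", 1:6)
  b <- sprintf("N%03d", 15:20)
  expect_equal(obsp_module_distance(m, a, b)$mean_sp,
               obsp_module_distance(m, b, a)$mean_sp)
})

test_that("disease ranking takes the minimum distance across modules", {
  per_module <- tibble::tibble(
    disease_id = c("d1", "d1", "d2"),
    module_id = c("m1", "m2", "m1"),
    mean_sp = c(3.0, 1.5, 2.0)
  )
  rk <- obsp_rank(per_module)
  expect_identical(rk$disease_id, c("d1", "d2"))
  expect_equal(rk$score, c(1.5, 2.0))
  expect_identical(attr(rk, "direction"), "ascending")
})

test_that("jaccard satisfies its identities", {
  expect_equal(jaccard(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B"), c("B", "C")),
               jaccard(c("B", "C"), c("A", "B")))
  expect_error(jaccard(character(), character()), "empty")
})

test_that("oboverlap ranks diseases by gene-set Jaccard, descending", {
  traits <- list(obesity = c("A", "B", "C", "D"),
                 d1 = c("A", "B", "C", "E"),   # J = 3/5
                 d2 = c("A", "X", "Y", "Z"),   # J = 1/7
                 d3 = c("P", "Q"))             # J = 0
  rk <- oboverlap_rank(traits, "obesity")
  expect_identical(rk$disease_id, c("d1", "d2", "d3"))
  expect_equal(rk$score, c(3 / 5, 1 / 7, 0))
})

test_that("the literature gold set applies the Jaccard threshold and manual additions", {
  counts <- tibble::tibble(
    disease_id = c("included", "borderline_out", "far_out"),
    n_disease = c(100, 100, 100),
    n_both = c(5, 4, 1)
  )
  # J(included) = 5 / (100 + 1000 - 5) = 0.00457 >= 0.004
  # J(borderline_out) = 4 / 1096 = 0.00365 < 0.004
  gold <- gold_set_from_counts(counts, n_query = 1000, threshold = 0.004,
                               manual_additions = "curated_extra")
  expect_setequal(gold, c("included", "curated_extra"))

  # generator-known membership on a random fixture
  set.seed(21)
  n_q <- 2000
  tb <- tibble::tibble(disease_id = sprintf("d%02d", 1:20),
                       n_disease = sample(50:500, 20),
                       n_both = sample(0:12, 20, TRUE))
  truth <- tb$disease_id[tb$n_both / (tb$n_disease + n_q - tb$n_both) >= 0.004]
  expect_setequal(gold_set_from_counts(tb, n_q), truth)
})
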