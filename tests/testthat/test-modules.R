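# Module construction, RWR expansion and scoring eligibility.

test_that("module building enforces the size cap and network mapping", {
  net <- suppressMessages(random_net(30, 0.15, seed = 2))
  big <- sprintf("X%03d", 1:500)        # exactly at the cap -> skipped
  sets <- list(big_set = big,
               partial = c("N001", "N002", "OFFNET"),
               absent = c("Z1", "Z2"))
  mods <- suppressMessages(build_modules(net, sets, max_set_size = 500))
  expect_named(mods, "partial")
  expect_setequal(mods$partial$core_genes, c("N001", "N002"))
})

test_that("module count equals the number of eligible sets on a fixture", {
  net <- suppressMessages(random_net(50, 0.1, seed = 9))
  set.seed(31)
  sets <- lapply(setNames(nm = sprintf("S%02d", 1:10)), function(i) {
    sample(sprintf("N%03d", 1:50), sample(4:12, 1))
  })
  sets$too_big <- sprintf("Y%03d", 1:600)
  sets$off_net <- c("QQ1", "QQ2")
  mods <- suppressMessages(build_modules(net, sets))
  expect_length(mods, 10)
})

test_that("star-graph expansion adds the highest-probability leaves", {
  net <- star_net(n_leaves = 8)
  # make two leaves better connected so they outrank the rest
  net <- igraph::add_edges(net, c("L01", "L02"))
  mods <- build_modules(net, list(m = "HUB"))
  ex <- expand_module(net, mods$m, factor = 3)
  expect_length(ex$expanded_genes, 3)
  expect_true(all(c("L01", "L02") %in% ex$expanded_genes))
  # agrees with the full RWR ranking
  prof <- rwr(normalize_adjacency(net), "HUB", r = 0.5)
  top2 <- head(rank_by_probability(prof, exclude = "HUB"), 2)
  expect_setequal(setdiff(ex$expanded_genes, "HUB"), top2)
})

test_that("expansion respects the cap, the network size, and is idempotent and monotone", {
  net <- suppressMessages(random_net(12, 0.3, seed = 4))
  mods <- build_modules(net, list(m = c("N001", "N002", "N003", "N004")))
  ex <- expand_module(net, mods$m, factor = 5, cap = 500)
  expect_lte(length(ex$expanded_genes), 12)
  expect_true(all(mods$m$core_genes %in% ex$expanded_genes))
  again <- expand_module(net, ex, factor = 5, cap = 500)
  expect_identical(again$expanded_genes, ex$expanded_genes)

  capped <- expand_module(net, mods$m, factor = 5, cap = 6)
  expect_lte(length(capped$expanded_genes), 6)
})

test_that("module subnetwork edges all come from the reference network", {
  net <- suppressMessages(random_net(40, 0.15, seed = 6))
  mods <- build_modules(net, list(m = sprintf("N%03d", seq(1, 40, by = 3))))
  ex <- expand_module(net, mods$m, factor = 2)
  ref_keys <- with(network_edges(net), paste(gene1, gene2))
  sub_edges <- network_edges(ex$subnetwork)
  expect_true(all(paste(sub_edges$gene1, sub_edges$gene2) %in% ref_keys))
  expect_true(all(c(sub_edges$gene1, sub_edges$gene2) %in% ex$expanded_genes))
})

test_that("eligibility needs five mapped genes on each side and expansion can rescue it", {
  net <- path_net(sprintf("P%02d", 1:20))
  core <- sprintf("P%02d", 3:12)
  mods <- build_modules(net, list(m = core))
  ob <- sprintf("P%02d", 3:7)      # 5 obesity genes in core
  dis_in <- sprintf("P%02d", 8:12) # 5 disease genes in core
  expect_true(eligible_for_scoring(mods$m, ob, dis_in))
  expect_false(eligible_for_scoring(mods$m, ob[1:4], dis_in))

  # disease genes placed just outside the core: ineligible until expansion
  dis_out <- sprintf("P%02d", 13:17)
  expect_false(eligible_for_scoring(mods$m, ob, dis_out))
  ex <- expand_module(net, mods$m, factor = 2)
  expect_true(eligible_for_scoring(ex, ob, dis_out))
})

test_that("the whole-network module covers every node and is never expanded", {
  net <- suppressMessages(random_net(15, 0.2, seed = 8))
  wm <- whole_network_module(net)
  expect_setequal(module_genes(wm), network_genes(net))
  expect_identical(wm$module_id, "whole")
})
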