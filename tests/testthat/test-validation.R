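# MDC, module-overlap Fisher tests, and the label-shuffle permutation study.

test_that("identical submatrices give MDC 1 and swapping conditions inverts it", {
  set.seed(1)
  vals <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  same <- expression_matrix(cbind(vals, vals),
                            rep(c("A", "B"), each = 12))
  colnames(same$values) <- sprintf("s%02d", 1:24)
  expect_equal(mdc(same, sprintf("g%02d", 1:10), "A", "B"), 1)

  expr <- generate_expression(list(m = sprintf("g%02d", 1:10)),
                              n_samples_a = 30, n_samples_b = 30,
                              rho_in_a = 0.7, rho_in_b = 0.1, seed = 5)
  ab <- mdc(expr, sprintf("g%02d", 1:10), "A", "B")
  ba <- mdc(expr, sprintf("g%02d", 1:10), "B", "A")
  expect_equal(ab, 1 / ba)
  expect_gt(ab, 1)
})

test_that("a two-gene module reduces to the single-pair correlation ratio", {
  expr <- generate_expression(list(m = c("g1", "g2")), 40, 40,
                              rho_in_a = 0.8, rho_in_b = 0.3, seed = 9)
  va <- expr$values[, expr$condition == "A"]
  vb <- expr$values[, expr$condition == "B"]
  direct <- abs(cor(va["G1", ], va["G2", ])) / abs(cor(vb["G1", ], vb["G2", ]))
  expect_equal(mdc(expr, c("g1", "g2"), "A", "B"), direct)
})

test_that("a strong planted effect pins the empirical p at its floor", {
  mods <- list(m1 = sprintf("g%02d", 1:15))
  expr <- generate_expression(mods, 40, 40, rho_in_a = 0.9, rho_in_b = 0.05,
                              seed = 3)
  res <- mdc_significance(expr, mods, "A", "B", n_perm = 49, seed = 21)
  expect_equal(res$p, 1 / 50)
  expect_true(all(res$fdr >= res$p))
})

test_that("label-shuffled data yields unremarkable MDC p-values", {
  mods <- list(m1 = sprintf("g%02d", 1:10), m2 = sprintf("h%02d", 1:10))
  expr <- generate_expression(mods, 30, 30, rho_in_a = 0.5, rho_in_b = 0.5,
                              seed = 17)
  res <- mdc_significance(expr, mods, "A", "B", n_perm = 39, seed = 23)
  expect_true(all(res$p > 0.025))  # no condition effect to find
})

test_that("overlap Fisher p-values match the hypergeometric tail-sum oracle", {
  set.seed(11)
  universe <- sprintf("u%02d", 1:40)
  mods_a <- list(a1 = sample(universe, 12), a2 = sample(universe, 8))
  mods_b <- list(b1 = sample(universe, 15), b2 = sample(universe, 6))
  res <- overlap_fisher(mods_a, mods_b, universe = universe)
  for (i in seq_len(nrow(res))) {
    a <- mods_a[[res$module_a[i]]]
    b <- mods_b[[res$module_b[i]]]
    k <- length(intersect(a, b))
    expect_equal(res$p[i],
                 hyper_tail_oracle(k, length(a), 40, length(b)),
                 tolerance = 1e-12)
  }
  expect_equal(res$p_adjusted, p.adjust(res$p, "BH"))
})

test_that("disjoint modules covering the universe are maximally unenriched", {
  universe <- sprintf("u%02d", 1:20)
  res <- overlap_fisher(list(a = universe[1:10]), list(b = universe[11:20]),
                        universe = universe)
  expect_equal(res$overlap, 0L)
  expect_equal(res$p, 1)
})

test_that("BH adjustment on a four-pair table matches the hand computation", {
  res <- tibble::tibble(p = c(0.01, 0.02, 0.04, 0.8))
  # BH: p * n / rank, cummin from the largest
  expect_equal(p.adjust(res$p, "BH"), c(0.04, 0.04, 16 / 300, 0.8))
})

test_that("the permutation study's normal tail matches direct arithmetic", {
  # observed equal to the null mean sits exactly at p = 0.5
  expect_equal(normal_tail_p(3, 3, 1.5)$p, 0.5)
  out <- normal_tail_p(6, 0.67, 1.22)
  expect_equal(out$z, (6 - 0.67) / 1.22)
  expect_equal(out$p, pnorm(out$z, lower.tail = FALSE))
})

test_that("label shuffles preserve module sizes and a null study is unremarkable", {
  set.seed(31)
  universe <- sprintf("u%03d", 1:120)
  mods_b <- split(sample(universe, 60), rep(1:6, each = 10))
  names(mods_b) <- sprintf("w%d", 1:6)
  mods_a <- lapply(setNames(nm = sprintf("a%d", 1:4)),
                   function(i) sample(universe, 12))
  study <- overlap_permutation_study(mods_a, mods_b, n_perm = 60, top_k = 3,
                                     seed = 42, universe = universe,
                                     selector = function(m) names(m)[1:3])
  expect_length(study$null_counts, 60)
  expect_true(study$observed <= length(mods_a))
  # observed count from random modules stays within 2 null sd of the mean
  expect_lte(abs(study$observed - study$mean_hits),
             2 * max(study$sd_hits, 1))
})
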