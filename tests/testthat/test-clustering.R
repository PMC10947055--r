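test_that("the nearest pair merges first and duplicates merge at zero cost", {
  t1 <- hierarchical_merge_tree(c(0, 1, 10))
  expect_equal(sort(t1$merge[1, ]), c(-2, -1))
  expect_equal(t1$height[1], 1)  # squared distance between 0 and 1

  t2 <- hierarchical_merge_tree(c(3, 7, 3, 9))
  expect_equal(sort(t2$merge[1, ]), c(-3, -1))
  expect_equal(t2$height[1], 0)

  expect_error(hierarchical_merge_tree(5), "2 items")
})

test_that("within-groups linkage reproduces the brute-force oracle", {
  set.seed(101)
  for (r in 1:5) {
    x <- runif(40)
    fast <- hierarchical_merge_tree(x)
    slow <- oracle_merge_tree(x)
    expect_equal(t(apply(fast$merge, 1, sort)), t(apply(slow$merge, 1, sort)))
    expect_equal(fast$height, slow$height, tolerance = 1e-9)
  }
})

test_that("tree cuts partition the items consistently with the merge order", {
  set.seed(5)
  x <- rnorm(30)
  tr <- hierarchical_merge_tree(x)
  expect_equal(cut_merge_tree(tr, 30), 1:30)
  expect_true(all(cut_merge_tree(tr, 1) == 1))
  for (k in c(2, 5, 10)) {
    lab <- cut_merge_tree(tr, k)
    expect_equal(length(unique(lab)), k)
  }
})

test_that("BIC selects one cluster for degenerate data and two for two Gaussians", {
  same <- rep(4, 25)
  expect_equal(select_initial_k_bic(same, hierarchical_merge_tree(same), 10), 1L)

  set.seed(33)
  y <- c(rnorm(100, -10), rnorm(100, 10))
  tr <- hierarchical_merge_tree(y)
  expect_equal(select_initial_k_bic(y, tr, 1), 1L)
  k0 <- select_initial_k_bic(y, tr, 10)
  expect_equal(k0, 2L)

  # independent direct evaluation of the stated score at every cut
  direct <- sapply(1:10, function(k) {
    lab <- cut_merge_tree(tr, k)
    nk <- table(lab)
    s2 <- sum((y - ave(y, lab))^2) / length(y)
    logl <- sum(nk * log(nk / length(y))) -
      length(y) / 2 * (log(2 * pi * s2) + 1)
    -2 * logl + 2 * k * log(length(y))
  })
  expect_equal(k0, which.min(direct))
})

test_that("d-prime follows its closed form and edge conventions", {
  expect_equal(dprime(list(mean = -10, sd = 3), list(mean = -4, sd = 5)),
               6 / sqrt(0.5 * (9 + 25)))
  expect_equal(dprime(list(mean = 2, sd = 1), list(mean = 2, sd = 4)), 0)
  expect_equal(dprime(list(mean = 1, sd = 0), list(mean = 1, sd = 0)), 0)
  expect_equal(dprime(list(mean = 1, sd = 0), list(mean = 2, sd = 0)), Inf)
  a <- list(mean = -3, sd = 2); b <- list(mean = 1, sd = 1)
  expect_equal(dprime(a, b), dprime(b, a))
})

test_that("d-prime refinement merges below-criterion pairs smallest-first", {
  # two groups separated by d' = 0.5 collapse to one cluster
  g1 <- exact_sample(20, 0, 2); g2 <- exact_sample(20, 1, 2)
  tr <- manual_tree(c(20, 20))
  sol <- refine_by_dprime(c(g1, g2), tr, k0 = 2)
  expect_equal(sol$k, 1)

  # two groups at d' = 2 stay separate
  g3 <- exact_sample(20, 4, 2)
  sol2 <- refine_by_dprime(c(g1, g3), tr, k0 = 2)
  expect_equal(sol2$k, 2)
  expect_gte(min(sol2$dprime_matrix, na.rm = TRUE), 1)

  # three groups with pairwise d' {0.6, 1.8, 2.4}: the 0.6 pair merges
  # first, then the loop continues until all survivors are >= 1
  h1 <- exact_sample(20, 0, 2)
  h2 <- exact_sample(20, 1.2, 2)   # d(h1,h2) = 0.6
  h3 <- exact_sample(20, 4.8, 2)   # d(h1,h3) = 2.4, d(h2,h3) = 1.8
  tr3 <- manual_tree(c(20, 20, 20))
  sol3 <- refine_by_dprime(c(h1, h2, h3), tr3, k0 = 3)
  merged <- c(h1, h2)
  d_rem <- abs(mean(merged) - 4.8) /
    sqrt(0.5 * (stats::var(merged) + 4))
  if (d_rem >= 1) {
    expect_equal(sol3$k, 2)
    expect_equal(sort(sol3$clusters$n), c(20, 40))
    expect_equal(min(sol3$clusters$mean), mean(merged), tolerance = 1e-9)
  } else {
    expect_equal(sol3$k, 1)
  }
  expect_true(sol3$k == 1 || min(sol3$dprime_matrix, na.rm = TRUE) >= 1)
})

test_that("labels are ordinal by descending cluster mean", {
  g1 <- exact_sample(10, -8, 0.5); g2 <- exact_sample(10, 0, 0.5)
  g3 <- exact_sample(10, 6, 0.5)
  sol <- refine_by_dprime(c(g1, g2, g3), manual_tree(c(10, 10, 10)), k0 = 3)
  expect_equal(sol$k, 3)
  expect_equal(sol$clusters$mean, sort(sol$clusters$mean, decreasing = TRUE))
  expect_true(all(sol$labels[1:10] == 3))   # most negative group -> last label
  expect_true(all(sol$labels[21:30] == 1))  # most positive -> label 1
})

test_that("d-prime solutions are invariant to shift and positive scaling", {
  set.seed(8)
  x <- rnorm(80)
  tr <- hierarchical_merge_tree(x)
  k0 <- select_initial_k_bic(x, tr, 6)
  s1 <- refine_by_dprime(x, tr, k0)
  y <- 3 + 2 * x
  tr2 <- hierarchical_merge_tree(y)
  s2 <- refine_by_dprime(y, tr2, select_initial_k_bic(y, tr2, 6))
  expect_equal(s1$labels, s2$labels)
  expect_equal(s1$dprime_matrix, s2$dprime_matrix, tolerance = 1e-9)
})

test_that("grid clustering recovers a planted arcuate defect", {
  dr <- run_defect_recovery_replicate(n_glaucoma = 8, n_healthy = 8, seed = 3)
  expect_true(dr$all_S)
  expect_gte(dr$dice, 0.6)
  expect_gte(dr$k_gcipl, 2)
})

test_that("refinement never increases k and respects k0 <= k_max", {
  set.seed(19)
  for (r in 1:5) {
    x <- rnorm(60, sd = sample(1:3, 1)) + sample(0:6, 1) * rbinom(60, 1, 0.4)
    tr <- hierarchical_merge_tree(x)
    k0 <- select_initial_k_bic(x, tr, 8)
    expect_lte(k0, 8)
    sol <- refine_by_dprime(x, tr, k0)
    expect_lte(sol$k, k0)
    expect_true(sol$k == 1 || min(sol$dprime_matrix, na.rm = TRUE) >= 1)
  }
})
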