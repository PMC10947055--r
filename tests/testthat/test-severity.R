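test_that("within/outside differences follow their arithmetic", {
  v <- matrix(0, 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[1:10, ] <- TRUE
  v[mask] <- -8; v[!mask] <- -2
  expect_equal(within_outside_difference(as_grid(v), mask), -6)

  expect_equal(within_outside_difference(as_grid(matrix(3, 64, 64)), mask), 0)

  # empty class among the valid cells -> undefined
  all_mask <- matrix(TRUE, 64, 64)
  expect_true(is.na(within_outside_difference(as_grid(v), all_mask)))
})

test_that("a perfectly recovered 10 um defect yields a -10 um difference", {
  d <- defect_spec(hemifields = "superior_retina", gcipl_depth = 10,
                   vf_depth = 8)
  m <- quiet_model("GCIPL")
  rec <- flat_record(age = 60)
  g_map <- standardise_map(synth_thickness_map(rec, m, defect = d, seed = 1))
  h_map <- standardise_map(synth_thickness_map(flat_record(age = 60), m, seed = 2))
  dev <- compute_deviation_map(g_map, normative_mean_map(list(h_map)))
  grid <- grid_average(dev)
  planted <- defect_grid_mask(d)
  # use the defect interior (fully covered cells) as the mask
  interior <- planted & grid$values < -9.99
  # inside the interior the deviation is exactly -10; the outside mean is
  # pulled slightly negative by partially covered border cells
  expect_equal(within_outside_difference(grid, interior), -10, tolerance = 0.2)
})

test_that("spearman_r handles monotone data and mid-rank ties", {
  x <- 1:10
  expect_equal(spearman_r(x, 2 * x + 3)$r, 1)
  expect_equal(spearman_r(x, exp(-x))$r, -1)
  r <- spearman_r(c(1, 2, 2, 3, 5), c(10, 20, 20, 40, 80))
  expect_equal(r$r, 1)
  expect_true(is.na(spearman_r(rep(1, 6), rnorm(6))$r))
  expect_error(spearman_r(1:3, 1:3), "5")
})

test_that("spearman_r equals the explicit rank-transform oracle", {
  set.seed(14)
  for (r in 1:100) {
    n <- sample(8:40, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01 * rbinom(1, 1, 0.5))
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_r(x, y)$r, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  r0 <- spearman_r(x, y)$r
  expect_equal(spearman_r(exp(x), y)$r, r0)
  expect_equal(spearman_r(x, y^3 + 5 * y)$r, r0)
})

test_that("cross-layer correlations respond to planted coupling", {
  set.seed(6)
  g <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(cross_layer_r(as_grid(g), as_grid(0.3 * g))$r, 1)
  expect_equal(cross_layer_r(as_grid(g), as_grid(-0.2 * g))$r, -1)
  ind <- cross_layer_r(as_grid(g), as_grid(matrix(rnorm(64 * 64), 64, 64)))
  expect_lt(abs(ind$r), qnorm(0.995) / sqrt(64 * 64 - 1))
})

test_that("the per-participant severity table assembles all six quantities", {
  set.seed(9)
  mask_sol <- list(GCIPL = structure(list(
    labels = integer(0),
    clusters = data.frame(label = 1:2, mean = c(1, -6), sd = 1, n = c(100, 50)),
    dprime_matrix = matrix(NA, 2, 2), k = 2, grid_mean = -1,
    label_map = matrix(rep(1:2, c(64 * 64 - 600, 600)), 64, 64)),
    class = "cluster_solution"))
  grids <- list(P1 = list(GCIPL = as_grid(matrix(rnorm(4096, -2), 64, 64)),
                          INL = as_grid(matrix(rnorm(4096), 64, 64)),
                          ORC = as_grid(matrix(rnorm(4096), 64, 64))))
  vfs <- list(P1 = synth_vf(defect_spec(vf_depth = 8), seed = 1))
  tab <- participant_severity_table(grids, c(P1 = "S.bin1"),
                                    list(S.bin1 = mask_sol), vfs)
  expect_equal(nrow(tab), 1)
  expect_false(anyNA(tab[, c("GCIPL_diff", "INL_diff", "ORC_diff",
                             "r_GCIPL_INL", "r_GCIPL_ORC", "r_INL_ORC")]))
  expect_equal(tab$MD, vfs$P1$md)

  # a stratum without a defective GCIPL cluster contributes NA differences
  tab2 <- participant_severity_table(grids, c(P1 = "C.bin1"),
                                     list(C.bin1 = NULL), vfs)
  expect_true(all(is.na(tab2[, c("GCIPL_diff", "INL_diff", "ORC_diff")])))
  expect_false(anyNA(tab2[, c("r_GCIPL_INL", "r_GCIPL_ORC", "r_INL_ORC")]))
})

test_that("global severity correlations cover 6 quantities x 2 indices", {
  set.seed(10)
  n <- 30
  tab <- data.frame(id = sprintf("P%02d", 1:n), stratum = "S.bin1",
                    GCIPL_diff = -seq_len(n) + rnorm(n, 0, 0.1),
                    INL_diff = rnorm(n), ORC_diff = rnorm(n),
                    r_GCIPL_INL = runif(n), r_GCIPL_ORC = runif(n),
                    r_INL_ORC = runif(n),
                    MD = -seq_len(n) * 0.3, PSD = seq_len(n) * 0.2)
  res <- global_severity_correlations(tab)
  expect_equal(nrow(res), 12)
  g_md <- res[res$quantity == "GCIPL_diff" & res$versus == "MD", ]
  expect_gt(g_md$r_g, 0.95)   # loss grows with worsening MD by construction
  g_psd <- res[res$quantity == "GCIPL_diff" & res$versus == "PSD", ]
  expect_lt(g_psd$r_g, -0.95)
  expect_true(all(res$n == n))
})
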