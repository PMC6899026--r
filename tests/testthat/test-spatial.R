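test_that("pearson_r reproduces hand-computed correlations", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 2)), sqrt(3) / 2,
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-10)
  }
})

test_that("correlation is symmetric, bounded and positive-affine invariant", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- pearson_r(x, y)
    expect_lte(abs(r), 1)
    expect_equal(r, pearson_r(y, x), tolerance = 1e-12)
    expect_equal(r, pearson_r(2.5 * x + 7, 0.3 * y - 4), tolerance = 1e-10)
  }
})

test_that("the null draws two distinct cells per pair and is seed-deterministic", {
  # two-point score distribution: half the cells at +v, half at -v
  v <- c(1, 2, 4)
  feats <- rbind(matrix(v, 10, 3, byrow = TRUE),
                 matrix(-v, 10, 3, byrow = TRUE))
  colnames(feats) <- paste0("F", 1:3)
  tab <- make_table(feats)
  null <- build_null(tab, n_draws = 500, seed = 5)
  expect_true(all(abs(abs(null$draws) - 1) < 1e-12))
  expect_equal(null$q95, 1)
  expect_identical(build_null(tab, n_draws = 500, seed = 5), null)
  expect_false(identical(build_null(tab, n_draws = 500, seed = 6)$draws,
                         null$draws))
  expect_error(build_null(tab[1, ], n_draws = 10, seed = 1), "fewer than 2")
})

test_that("null q95 and median agree with hand percentile oracles", {
  sim <- small_sim(seed = 13, n_fovs = 1, cells_per_fov = 100, n_features = 10)
  null <- build_null(sim$table, n_draws = 501, seed = 2)
  expect_true(all(null$draws >= -1 & null$draws <= 1))
  expect_equal(null$q95, oracle_quantile_linear(null$draws, 0.95),
               tolerance = 1e-10)
  expect_equal(null$median_r, oracle_quantile_linear(null$draws, 0.5),
               tolerance = 1e-10)
  nearest <- build_null(sim$table, n_draws = 501, seed = 2,
                        percentile = "nearest")
  expect_equal(nearest$q95, sort(nearest$draws)[ceiling(0.95 * 501)])
})

test_that("doubling the draw count moves q95 by less than Monte-Carlo error", {
  sim <- small_sim(seed = 14, n_fovs = 1, cells_per_fov = 200, n_features = 20)
  q1 <- build_null(sim$table, n_draws = 2000, seed = 3)$q95
  q2 <- build_null(sim$table, n_draws = 4000, seed = 4)$q95
  # SE of the 95th percentile ~ sqrt(p(1-p)/n) / f(q); bound generously
  expect_lt(abs(q1 - q2), 5 * sqrt(0.05 * 0.95 / 2000) / 1.0)
})

test_that("neighbor lists match geometry on hand-laid-out cells", {
  tab <- make_table(data.frame(F1 = c(1, 2, 3)), x = c(0, 1, 3), y = c(0, 0, 0))
  nb <- find_neighbors(tab, k = 1)
  expect_identical(nb[["cell001"]], "cell002")
  expect_identical(nb[["cell002"]], "cell001")
  expect_identical(nb[["cell003"]], "cell002")
  # k >= n - 1: everyone else, nearest first
  nb_all <- find_neighbors(tab, k = 10)
  expect_identical(nb_all[["cell001"]], c("cell002", "cell003"))
})

test_that("distance ties break by ascending cell_id", {
  tab <- make_table(data.frame(F1 = 1:4),
                    x = c(0, 1, -1, 0), y = c(0, 0, 0, 1))
  nb <- find_neighbors(tab, k = 2)
  # cells 2, 3, 4 are all at distance 1 from cell 1
  expect_identical(nb[["cell001"]], c("cell002", "cell003"))
})

test_that("neighbors never cross FOVs and match the brute-force oracle", {
  sim <- small_sim(seed = 17, n_fovs = 2, cells_per_fov = 100, n_features = 3)
  nb <- find_neighbors(sim$table, k = 20)
  fov_of <- setNames(sim$table$fov_id, sim$table$cell_id)
  expect_true(all(vapply(names(nb), function(id) {
    all(fov_of[nb[[id]]] == fov_of[id]) && !(id %in% nb[[id]])
  }, logical(1))))
  for (fov in unique(sim$table$fov_id)) {
    sub <- sim$table[sim$table$fov_id == fov, ]
    oracle <- oracle_knn(sub$cell_id, sub$centroid_x, sub$centroid_y, 20)
    expect_identical(nb[sub$cell_id], oracle[sub$cell_id])
  }
})

test_that("median neighbor correlations match brute-force recomputation", {
  sim <- small_sim(seed = 19, n_fovs = 1, cells_per_fov = 200, n_features = 8)
  nb <- find_neighbors(sim$table, k = 20)
  scored <- score_cells(sim$table, nb)
  oracle <- oracle_median_neighbor(sim$table, nb)
  expect_equal(scored$median_neighbor_r, unname(oracle[scored$cell_id]),
               tolerance = 1e-10)
  expect_true(all(scored$n_neighbors_used == 20))
})

test_that("degenerate score vectors are handled as documented", {
  feats <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, paste0("F", 1:4)))
  feats[3, ] <- 5  # zero-variance cell
  tab <- make_table(feats, x = 1:8)
  nb <- find_neighbors(tab, k = 3)
  expect_message(scored <- score_cells(tab, nb, min_neighbors = 2), "skipped")
  expect_true(is.na(scored$median_neighbor_r[3]))
  # a cell whose neighbors are all copies of itself correlates at exactly 1
  same <- matrix(rep(c(1, 3, 2, 5), each = 5), 5, 4,
                 dimnames = list(NULL, paste0("F", 1:4)))
  tab2 <- make_table(same, x = 1:5)
  s2 <- score_cells(tab2, find_neighbors(tab2, k = 4), min_neighbors = 1)
  expect_equal(s2$median_neighbor_r, rep(1, 5))
  # two neighbors at r = +1 and -1: even-n median is 0
  tri <- make_table(rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)),
                    x = c(0, 1, 2))
  s3 <- score_cells(tri, find_neighbors(tri, k = 2), min_neighbors = 1)
  expect_equal(s3$median_neighbor_r[1], 0)
})

test_that("cells below the usable-neighbor minimum stay unscored", {
  sim <- small_sim(seed = 23, n_fovs = 1, cells_per_fov = 4, n_features = 5)
  nb <- find_neighbors(sim$table, k = 20)
  expect_message(scored <- score_cells(sim$table, nb, min_neighbors = 5),
                 "unscored")
  expect_true(all(is.na(scored$median_neighbor_r)))
})

test_that("classification is strict at the threshold and condition-checked", {
  sim <- small_sim(seed = 29, n_fovs = 1, cells_per_fov = 50, n_features = 6)
  null <- build_null(sim$table, n_draws = 200, seed = 1)
  scored <- score_cells(sim$table, find_neighbors(sim$table, k = 10))
  scored$median_neighbor_r[1] <- null$q95        # exact tie -> uncorrelated
  scored$median_neighbor_r[2] <- null$q95 + 1e-9 # just above -> correlated
  flagged <- classify_cells(scored, null)
  expect_false(flagged$correlated_flag[1])
  expect_true(flagged$correlated_flag[2])

  other <- small_sim(seed = 29, n_fovs = 1, cells_per_fov = 50, n_features = 6)
  other$table$treatment <- "IGF-1"
  scored_other <- score_cells(other$table, find_neighbors(other$table, k = 10))
  expect_error(classify_cells(scored_other, null), "condition")
})

test_that("identical profiles up to positive scaling all classify as correlated", {
  base <- c(1, 4, 2, 6, 3)
  feats <- outer(seq(0.5, 2.5, length.out = 30), base)
  colnames(feats) <- paste0("F", 1:5)
  tab <- make_table(feats, x = runif(30), y = runif(30))
  null <- build_null(tab, n_draws = 100, seed = 1)
  scored <- score_cells(tab, find_neighbors(tab, k = 5))
  flagged <- classify_cells(scored, null)
  expect_equal(null$q95, 1) # all pairwise correlations are exactly 1...
  expect_false(any(flagged$correlated_flag)) # ...so nothing exceeds it strictly
  # against a sub-unity threshold the same cells all flag
  null$q95 <- 0.9
  expect_true(all(classify_cells(scored, null)$correlated_flag))
})

test_that("percent_correlated summarizes flagged fractions per group", {
  scored <- data.frame(
    cell_type = "normal", treatment = rep(c("vehicle", "IGF-1"), c(50, 40)),
    time_point = 60, replicate = "r1",
    correlated_flag = c(rep(c(TRUE, FALSE), c(5, 45)),
                        rep(c(TRUE, FALSE), c(0, 40)))
  )
  out <- percent_correlated(scored)
  expect_equal(out$percent_correlated[out$treatment == "vehicle"], 10)
  expect_equal(out$percent_correlated[out$treatment == "IGF-1"], 0)
  expect_equal(out$n_scored, c(40, 50))

  scored$correlated_flag[scored$treatment == "IGF-1"] <- NA
  expect_warning(out2 <- percent_correlated(scored), "no scored cells")
  expect_equal(nrow(out2), 1L)
})

test_that("spatial_analysis is reproducible and splits conditions correctly", {
  params <- generator_params(n_fovs = 1, cells_per_fov = 60, n_features = 8,
                             responder_fraction = 0, seed = 1)
  sim <- generate_experiment(
    list(
      list(cell_type = "normal", treatment = "vehicle", time_point = 0,
           replicate = "r1"),
      list(cell_type = "normal", treatment = "IGF-1", time_point = 60,
           replicate = "r1")
    ),
    params, seed = 2
  )
  r1 <- spatial_analysis(sim$table, k = 10, n_draws = 300, seed = 5)
  r2 <- spatial_analysis(sim$table, k = 10, n_draws = 300, seed = 5)
  expect_identical(r1, r2)
  expect_length(r1$nulls, 2L)
  expect_equal(nrow(r1$scores), nrow(sim$table))
})
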