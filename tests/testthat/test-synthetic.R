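test_that("generation is fully reproducible from the seed", {
  a <- small_sim(seed = 11, responder_fraction = 0.3)
  b <- small_sim(seed = 11, responder_fraction = 0.3)
  expect_identical(a, b)
  c <- small_sim(seed = 12, responder_fraction = 0.3)
  expect_false(identical(a$table, c$table))
})

test_that("responder_fraction = 0 yields no responder labels", {
  sim <- small_sim(seed = 2, responder_fraction = 0)
  expect_false(any(sim$truth$responder))
  expect_true(all(is.na(sim$truth$cluster_id)))
})

test_that("centroids lie inside the FOV and tables validate", {
  sim <- small_sim(seed = 3, responder_fraction = 0.4, fov_size = 500)
  expect_true(all(sim$table$centroid_x >= 0 & sim$table$centroid_x <= 500))
  expect_true(all(sim$table$centroid_y >= 0 & sim$table$centroid_y <= 500))
  expect_silent(validate_feature_table(sim$table))
})

test_that("responder counts follow the binomial law", {
  # 100 FOVs x 500 cells at fraction 0.2: expect 10000 +/- 3 binomial SDs
  params <- generator_params(n_fovs = 100, cells_per_fov = 500,
                             n_features = 2, responder_fraction = 0.2,
                             seed = 21)
  sim <- generate_experiment(
    list(list(cell_type = "normal", treatment = "IGF-1", time_point = 60,
              replicate = "r1")),
    params, seed = 21
  )
  n <- 100 * 500
  sd3 <- 3 * sqrt(n * 0.2 * 0.8)
  expect_lt(abs(sum(sim$truth$responder) - n * 0.2), sd3)
})

test_that("conditions get disjoint cell ids and duplicate conditions fail", {
  params <- generator_params(n_fovs = 1, cells_per_fov = 30, n_features = 3,
                             seed = 1)
  conds <- list(
    list(cell_type = "normal", treatment = "vehicle", time_point = 0,
         replicate = "r1", responder_fraction = 0),
    list(cell_type = "normal", treatment = "IGF-1", time_point = 60,
         replicate = "r1")
  )
  sim <- generate_experiment(conds, params, seed = 4)
  expect_false(anyDuplicated(sim$table$cell_id) > 0)
  expect_error(generate_experiment(c(conds, conds[1]), params, seed = 4),
               "duplicate condition")
})

test_that("treated-vs-vehicle mean shift matches the law of total expectation", {
  # fraction f of cells shifted by effect * sd => mean difference f * effect * sd
  params <- generator_params(n_fovs = 20, cells_per_fov = 400, n_features = 5,
                             n_shifted_features = 2, effect_size = 2,
                             baseline_noise_sd = 1, seed = 31)
  sim <- generate_experiment(
    list(
      list(cell_type = "normal", treatment = "vehicle", time_point = 0,
           replicate = "r1", responder_fraction = 0),
      list(cell_type = "normal", treatment = "IGF-1", time_point = 60,
           replicate = "r1", responder_fraction = 0.2)
    ),
    params, seed = 31
  )
  veh <- sim$table[sim$table$treatment == "vehicle", ]
  trt <- sim$table[sim$table$treatment == "IGF-1", ]
  diff_shifted <- mean(trt$Feature_001) - mean(veh$Feature_001)
  diff_unshifted <- mean(trt$Feature_003) - mean(veh$Feature_003)
  n <- nrow(trt)
  # expected 0.2 * 2 * 1 = 0.4; MC tolerance ~ 4 * sd(mean diff)
  tol <- 4 * sqrt(2 / n + 0.16 * 4 / n)
  expect_lt(abs(diff_shifted - 0.4), tol)
  expect_lt(abs(diff_unshifted), tol)
})

test_that("hard-core spacing is honored and infeasible densities error out", {
  params <- generator_params(n_fovs = 1, cells_per_fov = 40, n_features = 2,
                             responder_fraction = 0, fov_size = 200,
                             min_cell_spacing = 10, seed = 7)
  fov <- generate_fov(params, 1)
  d <- as.matrix(dist(fov$table[, c("centroid_x", "centroid_y")]))
  diag(d) <- Inf
  expect_gte(min(d), 10)

  bad <- generator_params(n_fovs = 1, cells_per_fov = 200, n_features = 2,
                          responder_fraction = 0, fov_size = 50,
                          min_cell_spacing = 20, seed = 7)
  expect_error(generate_fov(bad, 1), "min_cell_spacing")
})

test_that("under the null, features carry no positional signal", {
  sim <- small_sim(seed = 41, n_fovs = 1, cells_per_fov = 400,
                   n_features = 4, responder_fraction = 0)
  # permutation test of the feature/x-coordinate correlation
  obs <- cor(sim$table$Feature_001, sim$table$centroid_x)
  set.seed(1)
  perm <- replicate(500, cor(sample(sim$table$Feature_001),
                             sim$table$centroid_x))
  p <- mean(abs(perm) >= abs(obs))
  expect_gt(p, 0.001)
})
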