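# Fixture builders shared across tests. Everything is generated in code.

# Minimal valid feature table with hand-set feature values.
make_table <- function(features,
                       cell_type = "normal", treatment = "vehicle",
                       time_point = 0, replicate = "r1", fov_id = "f1",
                       x = NULL, y = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    cell_type = rep(cell_type, n), treatment = rep(treatment, n),
    time_point = rep(time_point, n),
    replicate = rep(replicate, n), fov_id = rep(fov_id, n),
    centroid_x = if (is.null(x)) as.numeric(seq_len(n)) else x,
    centroid_y = if (is.null(y)) rep(0, n) else y,
    cell_area = rep(100, n),
    features,
    stringsAsFactors = FALSE
  )
}

# One small simulated FOV table, deterministic.
small_sim <- function(seed = 1, n_fovs = 2, cells_per_fov = 60,
                      n_features = 12, responder_fraction = 0, ...) {
  params <- generator_params(n_fovs = n_fovs, cells_per_fov = cells_per_fov,
                             n_features = n_features,
                             responder_fraction = responder_fraction,
                             seed = seed, ...)
  generate_experiment(
    list(list(cell_type = "normal", treatment = "vehicle", time_point = 0,
              replicate = "r1")),
    params, seed = seed
  )
}
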