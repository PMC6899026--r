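# Synthetic multi-FOV feature tables with a spatially clustered responder
# sub-population and ground-truth labels.
#
# The spatial model is a Thomas-like cluster process: non-responders are
# placed uniformly in the FOV (optionally with a hard-core minimum spacing),
# responders around uniformly drawn cluster centers with isotropic Gaussian
# dispersion. Features are baseline mean + iid Gaussian noise; responders get
# an additive mean shift (in baseline-SD units) on a fixed leading subset of
# features. Everything is reproducible from a single seed.

#' Parameters of the synthetic-data generator
#'
#' Defaults emulate the acquisition layout and responder scenario the
#' analysis is designed for: a slide imaged as a 10x10 grid of non-overlapping
#' fields of view (FOVs), ~250 segmented cells per 2048 px FOV, 300 numeric
#' features, and a clustered responder sub-population (20\% of cells, mean
#' shift of 2 baseline SD on the first 30 features, cluster dispersion 5\% of
#' the FOV side).
#'
#' @param n_fovs number of FOVs per condition (default 100, a 10x10 grid).
#' @param fov_size FOV side length in pixels; centroids lie in
#'   `[0, fov_size]^2`.
#' @param cells_per_fov number of cells generated per FOV.
#' @param n_features number of numeric feature columns.
#' @param responder_fraction expected fraction of responder cells in `[0,1]`;
#'   the realized count per FOV is binomial.
#' @param n_clusters_per_fov number of responder cluster centers per FOV.
#' @param cluster_sigma isotropic Gaussian dispersion (pixels) of responders
#'   around their cluster center.
#' @param effect_size responder mean shift on each shifted feature, in units
#'   of `baseline_noise_sd`.
#' @param n_shifted_features number of shifted features; always the first
#'   `n_shifted_features` columns by index, for reproducibility.
#' @param baseline_noise_sd SD of the iid Gaussian feature noise (> 0).
#' @param baseline_mean baseline feature mean; scalar or length-`n_features`
#'   vector.
#' @param min_cell_spacing hard-core minimum distance (pixels) between
#'   non-responder cells, enforced by rejection; 0 disables it.
#' @param seed integer master seed for the generator.
#' @return a `generator_params` list, validated.
#' @export
generator_params <- function(n_fovs = 100L,
                             fov_size = 2048,
                             cells_per_fov = 250L,
                             n_features = 300L,
                             responder_fraction = 0.2,
                             n_clusters_per_fov = 3L,
                             cluster_sigma = 0.05 * fov_size,
                             effect_size = 2,
                             n_shifted_features = min(30L, n_features),
                             baseline_noise_sd = 1,
                             baseline_mean = 0,
                             min_cell_spacing = 0,
                             seed = 1L) {
  p <- list(
    n_fovs = as.integer(n_fovs), fov_size = fov_size,
    cells_per_fov = as.integer(cells_per_fov),
    n_features = as.integer(n_features),
    responder_fraction = responder_fraction,
    n_clusters_per_fov = as.integer(n_clusters_per_fov),
    cluster_sigma = cluster_sigma, effect_size = effect_size,
    n_shifted_features = as.integer(n_shifted_features),
    baseline_noise_sd = baseline_noise_sd,
    baseline_mean = baseline_mean,
    min_cell_spacing = min_cell_spacing,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_fovs >= 1L, p$fov_size > 0, p$cells_per_fov >= 1L, p$n_features >= 1L,
    p$responder_fraction >= 0, p$responder_fraction <= 1,
    p$n_clusters_per_fov >= 1L, p$cluster_sigma >= 0, p$effect_size >= 0,
    p$n_shifted_features >= 0L, p$n_shifted_features <= p$n_features,
    p$baseline_noise_sd > 0, p$min_cell_spacing >= 0,
    length(p$baseline_mean) %in% c(1L, p$n_features)
  )
  class(p) <- "generator_params"
  p
}

# Uniform positions with optional hard-core rejection. Errors when the
# requested density is infeasible under min_cell_spacing.
.place_uniform <- function(n, fov_size, min_spacing, max_attempts = 200L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  if (min_spacing <= 0) {
    return(cbind(stats::runif(n, 0, fov_size), stats::runif(n, 0, fov_size)))
  }
  pts <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    cand <- c(stats::runif(1, 0, fov_size), stats::runif(1, 0, fov_size))
    ok <- placed == 0L ||
      min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_spacing
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      attempts <- 0L
    } else {
      attempts <- attempts + 1L
      if (attempts >= max_attempts) {
        stop("cannot place ", n, " cells with min_cell_spacing = ",
             min_spacing, " in a ", fov_size, " px FOV (rejection limit hit)")
      }
    }
  }
  pts
}

# Gaussian offspring around a center, truncated to the FOV by redrawing
# (falls back to clamping after bounded attempts, which only matters for
# centers essentially on the border with large sigma).
.place_clustered <- function(centers, assignment, sigma, fov_size,
                             max_attempts = 100L) {
  n <- length(assignment)
  pts <- matrix(NA_real_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    ctr <- centers[assignment[i], ]
    for (a in seq_len(max_attempts)) {
      cand <- ctr + stats::rnorm(2, 0, sigma)
      if (all(cand >= 0 & cand <= fov_size)) break
    }
    pts[i, ] <- pmin(pmax(cand, 0), fov_size)
  }
  pts
}

#' Generate one synthetic field of view
#'
#' @param params a [generator_params()] object; its `seed` (combined with
#'   `fov_index`) determines the output completely.
#' @param fov_index 1-based FOV index, used for the FOV id and sub-seed.
#' @param condition named list with `cell_type`, `treatment`, `time_point`,
#'   `replicate`.
#' @param id_prefix prefix for `cell_id` / `fov_id` uniqueness across
#'   conditions.
#' @return list with `table` (a feature table) and `truth` (one row per cell:
#'   `cell_id`, `responder`, `cluster_id`, cluster center coordinates).
#' @export
generate_fov <- function(params, fov_index = 1L,
                         condition = list(cell_type = "normal",
                                          treatment = "vehicle",
                                          time_point = 0, replicate = "r1"),
                         id_prefix = "c1") {
  stopifnot(inherits(params, "generator_params"))
  set.seed(derive_seed(params$seed, fov_index))
  n <- params$cells_per_fov
  p <- params$n_features

  n_resp <- stats::rbinom(1L, n, params$responder_fraction)
  n_base <- n - n_resp

  base_xy <- .place_uniform(n_base, params$fov_size, params$min_cell_spacing)
  if (n_resp > 0L) {
    centers <- cbind(stats::runif(params$n_clusters_per_fov, 0, params$fov_size),
                     stats::runif(params$n_clusters_per_fov, 0, params$fov_size))
    assignment <- sample.int(params$n_clusters_per_fov, n_resp, replace = TRUE)
    resp_xy <- .place_clustered(centers, assignment, params$cluster_sigma,
                                params$fov_size)
  } else {
    centers <- matrix(numeric(0), ncol = 2)
    assignment <- integer(0)
    resp_xy <- matrix(numeric(0), ncol = 2)
  }

  responder <- c(rep(FALSE, n_base), rep(TRUE, n_resp))
  xy <- rbind(base_xy, resp_xy)

  feats <- matrix(stats::rnorm(n * p, mean = 0, sd = params$baseline_noise_sd),
                  nrow = n, ncol = p)
  feats <- sweep(feats, 2L, rep_len(params$baseline_mean, p), "+")
  if (n_resp > 0L && params$n_shifted_features > 0L) {
    shift <- params$effect_size * params$baseline_noise_sd
    sel <- seq_len(params$n_shifted_features)
    feats[responder, sel] <- feats[responder, sel] + shift
  }
  colnames(feats) <- sprintf("Feature_%03d", seq_len(p))

  fov_id <- sprintf("%s_f%03d", id_prefix, fov_index)
  cell_id <- sprintf("%s_c%04d", fov_id, seq_len(n))
  table <- data.frame(
    cell_id = cell_id,
    cell_type = condition$cell_type,
    treatment = condition$treatment,
    time_point = condition$time_point,
    replicate = condition$replicate,
    fov_id = fov_id,
    centroid_x = xy[, 1], centroid_y = xy[, 2],
    cell_area = stats::rlnorm(n, meanlog = log(5000), sdlog = 0.3),
    feats,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    cell_id = cell_id,
    responder = responder,
    cluster_id = c(rep(NA_character_, n_base),
                   if (n_resp) sprintf("%s_k%02d", fov_id, assignment)),
    cluster_x = c(rep(NA_real_, n_base),
                  if (n_resp) centers[assignment, 1]),
    cluster_y = c(rep(NA_real_, n_base),
                  if (n_resp) centers[assignment, 2]),
    stringsAsFactors = FALSE
  )
  list(table = table, truth = truth)
}

#' Generate a synthetic multi-condition experiment
#'
#' Concatenates FOVs over a list of conditions, with unique `fov_id`s and
#' `cell_id`s and per-condition sub-seeds derived deterministically from the
#' master seed. Each condition may override any generator parameter (most
#' usefully `responder_fraction`, e.g. 0 for a vehicle condition).
#'
#' @param conditions list of named lists; each must contain `cell_type`,
#'   `treatment`, `time_point`, `replicate` and may contain generator
#'   parameter overrides (e.g. `responder_fraction = 0`).
#' @param params shared [generator_params()] defaults.
#' @param seed master seed; overrides `params$seed`.
#' @return list with `table` (all conditions stacked) and `truth`.
#' @export
#' @examples
#' params <- generator_params(n_fovs = 2, cells_per_fov = 50, n_features = 10)
#' sim <- generate_experiment(
#'   list(
#'     list(cell_type = "normal", treatment = "vehicle", time_point = 0,
#'          replicate = "r1", responder_fraction = 0),
#'     list(cell_type = "normal", treatment = "IGF-1", time_point = 1440,
#'          replicate = "r1")
#'   ),
#'   params = params, seed = 7
#' )
#' table(sim$truth$responder)
generate_experiment <- function(conditions, params = generator_params(),
                                seed = params$seed) {
  stopifnot(length(conditions) >= 1L)
  keys <- vapply(conditions, function(cn) {
    condition_label(cn)
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate condition tuples: ", paste(keys[duplicated(keys)], collapse = ", "))
  }
  tables <- vector("list", length(conditions))
  truths <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    overrides <- cond[setdiff(names(cond), .condition_cols)]
    p_ci <- params
    if (length(overrides)) {
      p_list <- unclass(params)
      p_list[names(overrides)] <- overrides
      p_ci <- do.call(generator_params, p_list)
    }
    p_ci$seed <- derive_seed(seed, ci)
    fovs <- lapply(seq_len(p_ci$n_fovs), function(fi) {
      generate_fov(p_ci, fi, condition = cond,
                   id_prefix = sprintf("c%02d", ci))
    })
    tables[[ci]] <- do.call(rbind, lapply(fovs, `[[`, "table"))
    truths[[ci]] <- do.call(rbind, lapply(fovs, `[[`, "truth"))
  }
  table <- do.call(rbind, tables)
  rownames(table) <- NULL
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  validate_feature_table(table)
  list(table = table, truth = truth)
}
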