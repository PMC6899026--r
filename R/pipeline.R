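# Pipeline orchestration from a single config with one master seed.
#
# run_pipeline() drives: simulate (or ingest) -> per-cell-type median/MAD
# normalization -> per-cell-type PCA -> per-condition null + kNN scoring +
# classification -> summaries -> figures, writing every intermediate table,
# a machine-readable manifest and a log of every filter count and decision.

#' Default pipeline configuration
#'
#' The defaults are the procedure's stated parameters: k = 20 nearest
#' neighbors, 2000 null draws, 99\% PCA variance threshold, classification at
#' the null's 95th percentile, MAD scale constant 1.4826, correlations
#' computed on PC scores.
#'
#' @param ... named overrides of any top-level entry.
#' @return a validated config list.
#' @export
default_config <- function(...) {
  config <- list(
    seed = 1L,
    k = 20L,
    n_draws = 2000L,
    variance_threshold = 0.99,
    classification_quantile = 0.95,
    mad_constant = 1.4826,
    percentile_method = "linear",      # or "nearest"
    correlation_space = "pcs",         # or "features"
    min_neighbors = 5L,
    exclude_features = character(0),
    input = NULL,                      # CSV path; NULL -> simulate
    schema = list(),                   # cellprofiler_schema() overrides
    simulate = list(
      params = list(),                 # generator_params() overrides
      conditions = list(
        list(cell_type = "normal", treatment = "vehicle", time_point = 0,
             replicate = "r1", responder_fraction = 0),
        list(cell_type = "normal", treatment = "IGF-1", time_point = 1440,
             replicate = "r1")
      )
    ),
    figures = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(config))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    config[names(dots)] <- dots
  }
  validate_config(config)
}

#' Validate a pipeline configuration
#'
#' All schema problems are raised here, before any computation.
#'
#' @param config a config list (e.g. from [default_config()] or
#'   [yaml::read_yaml()]).
#' @return the config, normalized (integer counts coerced), invisibly usable.
#' @export
validate_config <- function(config) {
  need <- c("seed", "k", "n_draws", "variance_threshold",
            "classification_quantile", "mad_constant", "percentile_method",
            "correlation_space", "min_neighbors")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(config$seed)) stop("config$seed must be a single integer")
  if (!num1(config$k) || config$k < 1) stop("config$k must be >= 1")
  if (!num1(config$n_draws) || config$n_draws < 1) stop("config$n_draws must be >= 1")
  if (!num1(config$variance_threshold) || config$variance_threshold <= 0 ||
      config$variance_threshold > 1) {
    stop("config$variance_threshold must be in (0, 1]")
  }
  if (!num1(config$classification_quantile) ||
      config$classification_quantile <= 0 || config$classification_quantile >= 1) {
    stop("config$classification_quantile must be in (0, 1)")
  }
  if (!num1(config$mad_constant) || config$mad_constant <= 0) {
    stop("config$mad_constant must be positive")
  }
  if (!config$percentile_method %in% c("linear", "nearest")) {
    stop("config$percentile_method must be 'linear' or 'nearest'")
  }
  if (!config$correlation_space %in% c("pcs", "features")) {
    stop("config$correlation_space must be 'pcs' or 'features'")
  }
  if (!num1(config$min_neighbors) || config$min_neighbors < 1) {
    stop("config$min_neighbors must be >= 1")
  }
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("config needs either an input path or a simulate block")
  }
  for (f in c("seed", "k", "n_draws", "min_neighbors")) {
    config[[f]] <- as.integer(config[[f]])
  }
  config
}

# Tiny FNV-1a hash of the canonical YAML text of the config, for the manifest.
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Sensitivity and specificity against ground truth
#'
#' Compares the flagged-cell set with the generator's responder labels, over
#' scored cells only.
#'
#' @param scored classified score table.
#' @param truth ground-truth table from [generate_experiment()].
#' @return one-row data.frame: `n_scored`, `sensitivity`, `specificity`,
#'   `flagged_fraction`, `responder_fraction` (among scored cells). Entries
#'   are `NA` when a class is absent.
#' @export
recovery_stats <- function(scored, truth) {
  m <- merge(scored[, c("cell_id", "correlated_flag")],
             truth[, c("cell_id", "responder")], by = "cell_id")
  m <- m[!is.na(m$correlated_flag), , drop = FALSE]
  pos <- m$responder
  data.frame(
    n_scored = nrow(m),
    sensitivity = if (any(pos)) mean(m$correlated_flag[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!m$correlated_flag[!pos]) else NA_real_,
    flagged_fraction = mean(m$correlated_flag),
    responder_fraction = mean(pos)
  )
}

#' Run the full pipeline from a config
#'
#' @param config a config list, or the path to a YAML file with one; see
#'   [default_config()] for entries and defaults.
#' @param output_dir directory for all results (created; existing files are
#'   overwritten).
#' @return invisibly, a list with `scores`, `summary`, `nulls`, `manifest`
#'   and (for synthetic runs) `truth` and `recovery`.
#' @export
run_pipeline <- function(config = default_config(), output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(percentile_method = "linear", correlation_space = "pcs",
                   min_neighbors = 5L, mad_constant = 1.4826,
                   exclude_features = character(0), figures = TRUE)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  config <- validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "log.txt")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log_msg("run started ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  truth <- NULL
  n_rejected <- 0L
  if (!is.null(config$input)) {
    schema <- do.call(cellprofiler_schema, config$schema %||% list())
    table <- read_feature_table(config$input, schema)
    n_rejected <- attr(table, "n_rejected") %||% 0L
    log_msg("ingested ", nrow(table), " cells from ", config$input,
            " (", n_rejected, " rejected)")
  } else {
    params <- do.call(generator_params, config$simulate$params %||% list())
    conditions <- lapply(config$simulate$conditions, as.list)
    sim <- generate_experiment(conditions, params,
                               seed = derive_seed(config$seed, 1))
    table <- sim$table
    truth <- sim$truth
    write_feature_table(table, file.path(output_dir, "simulated_cells.csv"))
    write_table(truth, file.path(output_dir, "ground_truth.csv"))
    log_msg("simulated ", nrow(table), " cells over ",
            length(conditions), " condition(s)")
  }

  # per-cell-type normalization + embedding; cell types analyzed separately
  types <- unique(table$cell_type)
  score_tables <- vector("list", length(types))
  n_components <- stats::setNames(rep(NA_integer_, length(types)), types)
  features_dropped <- stats::setNames(integer(length(types)), types)
  for (ti in seq_along(types)) {
    ty <- types[ti]
    sub <- table[table$cell_type == ty, , drop = FALSE]
    ref_rows <- sub[sub$time_point == 0, , drop = FALSE]
    if (nrow(ref_rows) == 0L) {
      stop("cell type '", ty, "' has no time_point == 0 cells for the reference")
    }
    ref <- compute_reference(ref_rows, scale_constant = config$mad_constant,
                             exclude_features = config$exclude_features)
    features_dropped[ty] <- length(ref$median) - length(ref$retained_features)
    log_msg("cell type ", ty, ": ", length(ref$retained_features),
            " feature(s) retained, ", features_dropped[ty],
            " dropped (MAD = 0)")
    norm <- apply_normalization(sub, ref)
    if (config$correlation_space == "pcs") {
      model <- fit_embedding(norm, config$variance_threshold)
      n_components[ty] <- model$n_components
      log_msg("cell type ", ty, ": ", model$n_components,
              " principal component(s) reach ",
              100 * config$variance_threshold, "% of variance")
      score_tables[[ti]] <- embed_cells(norm, model)
    } else {
      score_tables[[ti]] <- norm
    }
  }

  nulls <- list()
  scores <- vector("list", length(types))
  for (ti in seq_along(types)) {
    res <- spatial_analysis(
      score_tables[[ti]], k = config$k, n_draws = config$n_draws,
      seed = derive_seed(config$seed, 2, ti),
      q = config$classification_quantile,
      percentile = config$percentile_method,
      min_neighbors = config$min_neighbors
    )
    scores[[ti]] <- res$scores
    nulls <- c(nulls, res$nulls)
  }
  scored <- do.call(rbind, scores)
  rownames(scored) <- NULL
  n_unscored <- sum(is.na(scored$correlated_flag))
  log_msg(nrow(scored), " cell(s) scored; ", n_unscored, " unscored")

  write_table(scored, file.path(output_dir, "cell_scores.csv"))
  for (lab in names(nulls)) {
    nd <- nulls[[lab]]
    write_table(
      data.frame(draw = seq_along(nd$draws), r = nd$draws,
                 q95 = nd$q95, median_r = nd$median_r),
      file.path(output_dir,
                paste0("null_", gsub("[^A-Za-z0-9.-]+", "_", lab), ".csv"))
    )
  }
  summary <- percent_correlated(scored,
                                by = c("cell_type", "treatment", "time_point"))
  summary_rep <- percent_correlated(
    scored, by = c("cell_type", "treatment", "time_point", "replicate"))
  write_table(summary, file.path(output_dir, "percent_correlated.csv"))
  write_table(summary_rep,
              file.path(output_dir, "percent_correlated_by_replicate.csv"))
  for (i in seq_len(nrow(summary))) {
    log_msg("flagged fraction ", summary$cell_type[i], "/",
            summary$treatment[i], "/t", summary$time_point[i], ": ",
            sprintf("%.2f%%", summary$percent_correlated[i]))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_stats(scored, truth)
    write_table(recovery, file.path(output_dir, "recovery_stats.csv"))
    log_msg(sprintf("recovery vs ground truth: sensitivity %.3f, specificity %.3f",
                    recovery$sensitivity, recovery$specificity))
  }

  if (isTRUE(config$figures)) {
    summary_report(summary, output_dir)
    spatial_map_report(scored, output_dir)
  }

  manifest <- list(
    package = "spatcorr",
    version = as.character(utils::packageVersion("spatcorr")),
    config = config,
    config_hash = config_hash(config),
    seeds = list(master = config$seed,
                 simulate = derive_seed(config$seed, 1)),
    counts = list(
      cells = nrow(table), rows_rejected = n_rejected,
      features_dropped_mad0 = as.list(features_dropped),
      n_components = as.list(n_components),
      cells_unscored = n_unscored
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(c(log_lines,
               paste0("run finished ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             log_path)
  invisible(list(scores = scored, summary = summary, nulls = nulls,
                 manifest = manifest, truth = truth, recovery = recovery))
}
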