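# Internal helpers shared across modules.

# Canonical metadata columns of a feature table, in fixed order.
.metadata_cols <- c(
  "cell_id", "cell_type", "treatment", "time_point", "replicate",
  "fov_id", "centroid_x", "centroid_y", "cell_area"
)

# Columns added by downstream steps / ground truth; never treated as features.
.derived_cols <- c(
  "median_neighbor_r", "n_neighbors_used", "correlated_flag",
  "responder", "cluster_id", "cluster_x", "cluster_y"
)

# Condition keys: the unit within which cells are exchangeable under the null.
.condition_cols <- c("cell_type", "treatment", "time_point", "replicate")

#' Feature column names of a cell table
#'
#' Every column that is not a canonical metadata column
#' (`cell_id`, `cell_type`, `treatment`, `time_point`, `replicate`, `fov_id`,
#' `centroid_x`, `centroid_y`, `cell_area`) and not a pipeline result column
#' is a feature. After [embed_cells()] the "features" are the principal
#' component scores.
#'
#' @param table a feature table (`data.frame`).
#' @return character vector of feature column names, in table order.
#' @export
feature_names <- function(table) {
  setdiff(colnames(table), c(.metadata_cols, .derived_cols))
}

#' Numeric feature matrix of a cell table
#'
#' @inheritParams feature_names
#' @return numeric matrix (cells x features) with `cell_id` rownames.
#' @export
feature_matrix <- function(table) {
  fn <- feature_names(table)
  if (length(fn) == 0L) stop("table has no feature columns")
  m <- as.matrix(table[, fn, drop = FALSE])
  if (!is.numeric(m)) stop("feature columns must all be numeric")
  rownames(m) <- table$cell_id
  m
}

# Deterministic sub-seed derivation from a master seed (Lehmer-style walk over
# the given index path). Keeps every derived seed in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (i in as.numeric(c(...))) {
    s <- (s * 48271 + i + 1) %% m
  }
  as.integer(s)
}

# Unique condition tuples present in a table, as a data.frame (one row each).
condition_table <- function(table) {
  unique(table[, .condition_cols, drop = FALSE])
}

# Single condition tuple of a table; error if the table mixes conditions.
condition_of <- function(table) {
  ct <- condition_table(table)
  if (nrow(ct) != 1L) {
    stop("table spans ", nrow(ct), " conditions; expected exactly one")
  }
  as.list(ct[1L, , drop = FALSE])
}

# Compact "type/treatment/time/rep" label for messages and file names.
condition_label <- function(cond) {
  paste(cond$cell_type, cond$treatment, cond$time_point, cond$replicate,
        sep = "/")
}

# Row-standardize a matrix so that the Pearson correlation between two rows is
# the plain dot product of their standardized versions. Rows with zero
# variance become all-NA (correlation undefined).
row_standardize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 columns to correlate rows")
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  z <- ctr / ss
  z[ss == 0, ] <- NA_real_
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
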