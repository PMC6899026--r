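# The core spatial statistic: per-condition resampling null of pairwise
# Pearson correlations, k-nearest-neighbor median-correlation scoring, and
# classification against the null's 95th percentile.
#
# All correlations are Pearson product-moment correlations between two cells'
# score vectors (PC scores by default, normalized features if preferred).
# Scoring is vectorized through row-standardized matrices: after
# standardizing each cell's vector to zero mean and unit sum of squares, the
# correlation between two cells is the dot product of their rows.

#' Pearson correlation between two cell vectors
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return the sample Pearson product-moment correlation, in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))  # exactly 1
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero-variance vector")
  }
  stats::cor(x, y)
}

#' Resampling null distribution of pairwise correlations
#'
#' Draws `n_draws` pairs of distinct cells uniformly at random (pairs with
#' replacement across draws) from one condition, ignoring spatial position,
#' and records the Pearson correlation of each pair's score vectors. The
#' distribution's 95th percentile is the classification threshold for that
#' condition; its median is kept as a location summary.
#'
#' @param table score table (or normalized feature table) for a single
#'   condition, with >= 2 cells.
#' @param n_draws number of random pairs (default 2000).
#' @param seed integer seed; identical seeds give identical draws.
#' @param q percentile used as the classification threshold (default 0.95).
#' @param percentile `"linear"` for interpolation between order statistics
#'   (default) or `"nearest"` for the nearest-rank convention.
#' @return an object of class `null_distribution`: `condition`, `draws`,
#'   `n_draws`, `q95` (the `q` percentile of the draws), `median_r`, `seed`,
#'   and the conventions used.
#' @export
build_null <- function(table, n_draws = 2000L, seed = 1L, q = 0.95,
                       percentile = c("linear", "nearest")) {
  percentile <- match.arg(percentile)
  cond <- condition_of(table)
  z <- row_standardize(feature_matrix(table))
  usable <- !is.na(z[, 1L])
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message(n_dropped, " cell(s) excluded from null (zero-variance vectors)")
    z <- z[usable, , drop = FALSE]
  }
  n <- nrow(z)
  if (n < 2L) stop("condition has fewer than 2 usable cells")
  set.seed(seed)
  i <- sample.int(n, n_draws, replace = TRUE)
  j <- sample.int(n, n_draws, replace = TRUE)
  while (any(clash <- i == j)) {
    j[clash] <- sample.int(n, sum(clash), replace = TRUE)
  }
  draws <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
  draws <- pmin(1, pmax(-1, draws))  # guard rounding at the boundary
  q95 <- stats::quantile(draws, q, names = FALSE,
                         type = if (percentile == "linear") 7L else 1L)
  structure(
    list(condition = cond, draws = draws, n_draws = as.integer(n_draws),
         q95 = q95, median_r = stats::median(draws), seed = as.integer(seed),
         q = q, percentile = percentile, n_cells = n),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null distribution of pairwise correlations\n")
  cat("  condition:", condition_label(x$condition), "\n")
  cat(sprintf("  %d draws from %d cells; q%g = %.4f; median r = %.4f\n",
              x$n_draws, x$n_cells, 100 * x$q, x$q95, x$median_r))
  invisible(x)
}

#' k-nearest-neighbor lists by centroid distance
#'
#' For each cell, the `k` nearest other cells of the same FOV by Euclidean
#' centroid distance (FOVs do not overlap, so cross-FOV adjacency is
#' undefined). If a FOV holds fewer than `k + 1` cells, all other cells are
#' returned. Distance ties are broken by ascending `cell_id`.
#'
#' @param table feature or score table with `fov_id`, `centroid_x`,
#'   `centroid_y`; every FOV must hold >= 2 cells.
#' @param k neighbors per cell (default 20).
#' @return named list: for each `cell_id`, a character vector of neighbor
#'   `cell_id`s ordered by increasing distance.
#' @export
find_neighbors <- function(table, k = 20L) {
  stopifnot(k >= 1L)
  out <- vector("list", nrow(table))
  names(out) <- table$cell_id
  for (fov in unique(table$fov_id)) {
    idx <- which(table$fov_id == fov)
    n <- length(idx)
    if (n < 2L) stop("FOV '", fov, "' has fewer than 2 cells")
    ids <- table$cell_id[idx]
    d <- as.matrix(stats::dist(cbind(table$centroid_x[idx],
                                     table$centroid_y[idx])))
    kk <- min(k, n - 1L)
    for (a in seq_len(n)) {
      da <- d[a, ]
      da[a] <- Inf
      ord <- order(da, ids)  # ties by ascending cell_id
      out[[idx[a]]] <- ids[ord[seq_len(kk)]]
    }
  }
  out
}

#' Median neighbor correlation per cell
#'
#' For each cell, the median of the Pearson correlations between its score
#' vector and each of its neighbors' score vectors. Neighbors with
#' zero-variance vectors are skipped (their count is reported); a cell with a
#' zero-variance vector of its own, or with fewer than `min_neighbors` usable
#' neighbors, is left unscored (`NA`) and excluded from downstream summaries.
#'
#' @param table score table covering all cells named in `neighbors`.
#' @param neighbors neighbor lists from [find_neighbors()].
#' @param min_neighbors minimum usable neighbors required to score a cell
#'   (default 5).
#' @return the table with feature/score columns replaced by
#'   `median_neighbor_r` and `n_neighbors_used`.
#' @export
score_cells <- function(table, neighbors, min_neighbors = 5L) {
  z <- row_standardize(feature_matrix(table))
  rownames(z) <- table$cell_id
  med <- rep(NA_real_, nrow(table))
  nused <- integer(nrow(table))
  skipped <- 0L
  for (fov in unique(table$fov_id)) {
    idx <- which(table$fov_id == fov)
    zf <- z[idx, , drop = FALSE]
    cmat <- tcrossprod(zf)  # cells x cells Pearson correlations
    ids <- table$cell_id[idx]
    pos <- stats::setNames(seq_along(ids), ids)
    for (a in seq_along(idx)) {
      nb <- neighbors[[ids[a]]]
      if (is.null(nb)) stop("no neighbor list for cell ", ids[a])
      rs <- cmat[a, pos[nb]]
      ok <- !is.na(rs)
      skipped <- skipped + sum(!ok)
      if (is.na(zf[a, 1L]) || sum(ok) < min_neighbors) next
      med[idx[a]] <- stats::median(rs[ok])
      nused[idx[a]] <- sum(ok)
    }
  }
  if (skipped > 0L) {
    message(skipped, " neighbor correlation(s) skipped (zero-variance vectors)")
  }
  n_unscored <- sum(is.na(med))
  if (n_unscored > 0L) {
    message(n_unscored, " cell(s) left unscored")
  }
  meta <- table[, intersect(.metadata_cols, colnames(table)), drop = FALSE]
  out <- cbind(meta,
               data.frame(median_neighbor_r = pmin(1, pmax(-1, med)),
                          n_neighbors_used = nused))
  rownames(out) <- NULL
  out
}

#' Classify cells against the null threshold
#'
#' A cell is flagged as spatially correlated when its median neighbor
#' correlation strictly exceeds the null's 95th percentile; equality counts
#' as uncorrelated. Unscored cells keep `NA`.
#'
#' @param scored output of [score_cells()] for one condition.
#' @param null the same condition's [build_null()] result.
#' @return `scored` with a logical `correlated_flag` column added.
#' @export
classify_cells <- function(scored, null) {
  stopifnot(inherits(null, "null_distribution"))
  cond <- condition_of(scored)
  if (!identical(lapply(cond, as.character), lapply(null$condition, as.character))) {
    stop("null was built for condition ", condition_label(null$condition),
         ", not ", condition_label(cond))
  }
  scored$correlated_flag <- scored$median_neighbor_r > null$q95
  scored
}

#' Percent of spatially correlated cells per condition group
#'
#' @param scored a classified score table (any number of conditions).
#' @param by grouping columns (default cell type, treatment and time point;
#'   add `"replicate"` for per-replicate summaries).
#' @return data.frame with one row per group: the grouping columns,
#'   `n_scored`, `n_correlated` and `percent_correlated`
#'   (`100 * n_correlated / n_scored`). Groups with no scored cells are
#'   omitted with a warning.
#' @export
percent_correlated <- function(scored,
                               by = c("cell_type", "treatment", "time_point")) {
  stopifnot(all(by %in% colnames(scored)),
            "correlated_flag" %in% colnames(scored))
  key <- interaction(scored[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    sub <- scored[key == lv, , drop = FALSE]
    flags <- sub$correlated_flag[!is.na(sub$correlated_flag)]
    if (length(flags) == 0L) {
      warning("group ", lv, " has no scored cells; omitted")
      return(NULL)
    }
    cbind(sub[1L, by, drop = FALSE],
          data.frame(n_scored = length(flags),
                     n_correlated = sum(flags),
                     percent_correlated = 100 * mean(flags)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full spatial statistic over all conditions of a table
#'
#' Splits the score table by condition (cell type, treatment, time point,
#' replicate), builds each condition's resampling null, finds within-FOV
#' nearest neighbors, scores every cell by its median neighbor correlation
#' and classifies it against the condition's null threshold.
#'
#' @param table score table (PC scores) or normalized feature table covering
#'   one or more conditions.
#' @param k neighbors per cell (default 20).
#' @param n_draws null draws per condition (default 2000).
#' @param seed master seed; per-condition sub-seeds are derived from it
#'   deterministically (conditions ordered by their label).
#' @param q classification percentile (default 0.95).
#' @param percentile percentile convention, see [build_null()].
#' @param min_neighbors see [score_cells()].
#' @return list with `scores` (classified per-cell table across conditions)
#'   and `nulls` (named list of `null_distribution` objects).
#' @export
spatial_analysis <- function(table, k = 20L, n_draws = 2000L, seed = 1L,
                             q = 0.95, percentile = c("linear", "nearest"),
                             min_neighbors = 5L) {
  percentile <- match.arg(percentile)
  ct <- condition_table(table)
  labels <- vapply(seq_len(nrow(ct)), function(i) {
    condition_label(as.list(ct[i, , drop = FALSE]))
  }, character(1))
  ord <- order(labels)
  scores <- vector("list", nrow(ct))
  nulls <- vector("list", nrow(ct))
  names(nulls) <- labels[ord]
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    sel <- rep(TRUE, nrow(table))
    for (cc in .condition_cols) sel <- sel & table[[cc]] == ct[[cc]][i]
    sub <- table[sel, , drop = FALSE]
    null <- build_null(sub, n_draws = n_draws,
                       seed = derive_seed(seed, pos), q = q,
                       percentile = percentile)
    nb <- find_neighbors(sub, k = k)
    sc <- score_cells(sub, nb, min_neighbors = min_neighbors)
    scores[[pos]] <- classify_cells(sc, null)
    nulls[[pos]] <- null
  }
  out <- do.call(rbind, scores)
  rownames(out) <- NULL
  list(scores = out, nulls = nulls)
}
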