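# PCA embedding with explained-variance component selection.
#
# Fit on the pooled normalized data of one cell type (all its conditions);
# keep the smallest number of leading components whose cumulative explained
# variance reaches the threshold (default 99%). Component signs are fixed by
# making each loading vector's largest-magnitude entry positive, so repeated
# fits on identical data are bit-identical.

#' Fit a PCA embedding with a cumulative-variance component rule
#'
#' @param table a normalized feature table (typically pooled across all
#'   conditions of one cell type), or a numeric matrix (cells x features).
#' @param variance_threshold proportion of total variance the selected
#'   components must explain (default 0.99).
#' @return an object of class `cell_embedding`: `loadings` (features x all
#'   components, orthonormal columns, sign-fixed), `center` (fit-population
#'   feature means), `explained_variance_ratio`, `n_components` (smallest k
#'   whose cumulative ratio reaches the threshold), `variance_threshold`,
#'   `feature_names` and `fit_n` (number of cells used).
#' @export
fit_embedding <- function(table, variance_threshold = 0.99) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  x <- if (is.matrix(table)) table else feature_matrix(table)
  if (nrow(x) < 2L) stop("need at least 2 cells to fit an embedding")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  var_j <- pc$sdev^2
  evr <- var_j / sum(var_j)
  ncomp <- which(cumsum(evr) >= variance_threshold - 1e-12)[1L]
  structure(
    list(
      loadings = rot,
      center = pc$center,
      explained_variance_ratio = evr,
      n_components = as.integer(ncomp),
      variance_threshold = variance_threshold,
      feature_names = colnames(x),
      fit_n = nrow(x)
    ),
    class = "cell_embedding"
  )
}

#' Project cells into a fitted embedding
#'
#' Scores are the centered feature vectors (centering by the fit population's
#' means) projected onto the selected loading vectors. Metadata and
#' coordinates are carried through; the score columns are named `PC1` ...
#' `PCk` and act as the table's "features" for all downstream steps.
#'
#' @param table a normalized feature table whose features match the model's.
#' @param model a `cell_embedding` from [fit_embedding()].
#' @param n_components number of components to keep; defaults to the model's
#'   variance-rule selection. Pass `ncol(model$loadings)` for the full basis.
#' @return a score table (`data.frame`): metadata columns + `PC1..PCk`.
#' @export
embed_cells <- function(table, model, n_components = model$n_components) {
  stopifnot(inherits(model, "cell_embedding"))
  missing <- setdiff(model$feature_names, colnames(table))
  if (length(missing)) {
    stop("table lacks model feature(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  k <- as.integer(n_components)
  stopifnot(k >= 1L, k <= ncol(model$loadings))
  x <- as.matrix(table[, model$feature_names, drop = FALSE])
  scores <- sweep(x, 2L, model$center, "-") %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  meta <- table[, intersect(c(.metadata_cols, .derived_cols), colnames(table)),
                drop = FALSE]
  out <- cbind(meta, as.data.frame(scores))
  rownames(out) <- NULL
  out
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat("PCA cell embedding\n")
  cat("  features:", length(x$feature_names), " cells fitted:", x$fit_n, "\n")
  cat(sprintf("  %d component(s) reach %.4g%% of variance (threshold %g%%)\n",
              x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)]),
              100 * x$variance_threshold))
  invisible(x)
}
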