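# Robust per-feature normalization against a reference population.
#
# The reference is one cell type at time 0 (treatment cannot yet have acted,
# so vehicle and treated rows at t = 0 are pooled). Each feature is centered
# by the reference median and scaled by 1.4826 * MAD, the consistent robust
# SD estimate for Gaussian data; features whose reference MAD is exactly 0
# carry no usable information at this scale and are dropped.

#' Compute a median/MAD normalization reference
#'
#' @param table a feature table restricted to a single cell type at
#'   `time_point == 0` (checked).
#' @param scale_constant multiplier applied to the MAD; 1.4826 makes
#'   `scale_constant * MAD` estimate the SD for Gaussian features.
#' @param exclude_features optional character vector of feature names to drop
#'   by hand (e.g. known-uninformative bookkeeping measurements), applied
#'   before the MAD = 0 rule.
#' @return an object of class `mad_reference`: per-feature `median` and `mad`
#'   (median of absolute deviations from the median, no small-sample
#'   correction), `retained_features` (MAD > 0 only, input order preserved),
#'   `scale_constant` and the `reference_condition`.
#' @export
#' @examples
#' tab <- data.frame(
#'   cell_id = as.character(1:5), cell_type = "normal", treatment = "vehicle",
#'   time_point = 0, replicate = "r1", fov_id = "f1",
#'   centroid_x = 1:5, centroid_y = 1:5, cell_area = 10,
#'   F1 = c(1, 2, 3, 4, 5), F2 = 2
#' )
#' ref <- compute_reference(tab)
#' ref$retained_features  # F2 has MAD 0 and is dropped
compute_reference <- function(table, scale_constant = 1.4826,
                              exclude_features = character(0)) {
  if (nrow(table) == 0L) stop("reference table is empty")
  if (length(unique(table$cell_type)) != 1L) {
    stop("reference must contain a single cell_type")
  }
  if (any(table$time_point != 0)) {
    stop("reference must be restricted to time_point == 0")
  }
  fn <- setdiff(feature_names(table), exclude_features)
  if (length(fn) == 0L) stop("no feature columns in reference table")
  x <- as.matrix(table[, fn, drop = FALSE])
  med <- apply(x, 2L, stats::median)
  mad0 <- apply(x, 2L, function(v) stats::median(abs(v - stats::median(v))))
  retained <- fn[mad0 > 0]
  if (length(retained) == 0L) stop("all features have MAD = 0; no usable features")
  n_dropped <- length(fn) - length(retained)
  if (n_dropped > 0L) {
    message(n_dropped, " feature(s) dropped (MAD = 0 in reference)")
  }
  structure(
    list(
      reference_condition = list(cell_type = table$cell_type[1L], time_point = 0),
      median = med, mad = mad0,
      retained_features = retained,
      scale_constant = scale_constant
    ),
    class = "mad_reference"
  )
}

#' Apply a normalization reference to a feature table
#'
#' Each retained feature value `x` becomes
#' `(x - median_f) / (scale_constant * MAD_f)` with the reference's
#' per-feature statistics. Features not retained by the reference are
#' removed; metadata and coordinates pass through unchanged.
#'
#' @param table a feature table whose features include all of the reference's
#'   `retained_features`.
#' @param ref a `mad_reference` from [compute_reference()].
#' @return the normalized feature table (metadata + retained features only).
#' @export
apply_normalization <- function(table, ref) {
  stopifnot(inherits(ref, "mad_reference"))
  missing <- setdiff(ref$retained_features, colnames(table))
  if (length(missing)) {
    stop("table lacks retained feature(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  keep <- ref$retained_features
  x <- as.matrix(table[, keep, drop = FALSE])
  scale <- ref$scale_constant * ref$mad[keep]
  z <- sweep(sweep(x, 2L, ref$median[keep], "-"), 2L, scale, "/")
  meta <- table[, intersect(c(.metadata_cols, .derived_cols), colnames(table)),
                drop = FALSE]
  out <- cbind(meta, as.data.frame(z))
  rownames(out) <- NULL
  out
}

#' @export
print.mad_reference <- function(x, ...) {
  cat("median/MAD normalization reference\n")
  cat("  cell type:", x$reference_condition$cell_type, "at t = 0\n")
  cat("  features retained:", length(x$retained_features),
      "of", length(x$median), "\n")
  cat("  scale constant:", x$scale_constant, "\n")
  invisible(x)
}
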