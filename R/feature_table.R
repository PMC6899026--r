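# Ingest and serialization of per-cell feature tables.
#
# The on-disk dialect follows CellProfiler per-object exports: one row per
# cell, metadata columns prefixed "Metadata_", centroids in
# Location_Center_X/Y, any number of numeric feature columns. Internally the
# table uses canonical column names (see `feature_names()`); a schema map
# translates between the two.

#' Default CellProfiler-style column schema
#'
#' Maps canonical column names used throughout the package to the column
#' names found in a CellProfiler per-object export. Override individual
#' entries to ingest other dialects.
#'
#' @param ... named overrides, e.g. `fov_id = "Metadata_Site"`.
#' @return named list mapping canonical names to file column names.
#' @export
#' @examples
#' cellprofiler_schema(cell_type = "Metadata_Line")
cellprofiler_schema <- function(...) {
  schema <- list(
    cell_id    = "ObjectNumber",
    cell_type  = "Metadata_CellType",
    treatment  = "Metadata_Treatment",
    time_point = "Metadata_TimePoint",
    replicate  = "Metadata_Replicate",
    fov_id     = "Metadata_FOV",
    centroid_x = "Location_Center_X",
    centroid_y = "Location_Center_Y",
    cell_area  = "AreaShape_Area"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) stop("unknown schema entries: ", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

#' Read a per-cell feature table
#'
#' Reads a CellProfiler-export-style CSV, renames columns to the canonical
#' schema, coerces feature columns to numeric and validates the result. Rows
#' containing any non-numeric or missing feature value are rejected (their
#' count is reported with a message): downstream statistics assume complete
#' feature vectors.
#'
#' @param path CSV file with a header row.
#' @param schema_map named list from [cellprofiler_schema()] identifying the
#'   metadata, coordinate and area columns; all remaining columns are
#'   features.
#' @return a validated feature table (`data.frame`) with canonical metadata
#'   columns followed by the feature columns in file order.
#' @export
read_feature_table <- function(path, schema_map = cellprofiler_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- vapply(schema_map, function(col) !(col %in% colnames(raw)),
                    logical(1))
  if (any(missing)) {
    stop("missing mandatory column(s): ",
         paste(unlist(schema_map[missing]), collapse = ", "))
  }
  feat_cols <- setdiff(colnames(raw), unlist(schema_map))
  table <- raw[, unlist(schema_map), drop = FALSE]
  colnames(table) <- names(schema_map)

  feats <- raw[, feat_cols, drop = FALSE]
  for (j in seq_along(feats)) {
    feats[[j]] <- suppressWarnings(as.numeric(feats[[j]]))
  }
  bad_row <- if (ncol(feats)) rowSums(is.na(feats)) > 0 else rep(FALSE, nrow(feats))
  if (any(bad_row)) {
    message(sum(bad_row), " row(s) rejected: non-numeric or missing feature values")
    table <- table[!bad_row, , drop = FALSE]
    feats <- feats[!bad_row, , drop = FALSE]
  }
  out <- cbind(table, feats)
  rownames(out) <- NULL
  out$cell_id <- as.character(out$cell_id)
  out$fov_id <- as.character(out$fov_id)
  for (col in c("time_point", "centroid_x", "centroid_y", "cell_area")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  attr(out, "n_rejected") <- sum(bad_row)
  validate_feature_table(out)
  out
}

#' Validate a feature table
#'
#' Checks the structural invariants every downstream step relies on:
#' unique `cell_id`; numeric, finite, non-negative coordinates and time
#' points; positive cell areas; a single condition tuple per FOV; complete
#' numeric feature columns.
#'
#' @param table a feature table.
#' @return the table, invisibly; errors describe the first violated invariant.
#' @export
validate_feature_table <- function(table) {
  miss <- setdiff(.metadata_cols, colnames(table))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(table$cell_id)) {
    stop("duplicate cell_id values: ",
         paste(utils::head(unique(table$cell_id[duplicated(table$cell_id)]), 3),
               collapse = ", "))
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(table$time_point) || any(table$time_point < 0)) {
    stop("time_point must be a non-negative number")
  }
  if (!num_ok(table$centroid_x) || !num_ok(table$centroid_y) ||
      any(table$centroid_x < 0) || any(table$centroid_y < 0)) {
    stop("centroid coordinates must be non-negative numbers")
  }
  if (!num_ok(table$cell_area) || any(table$cell_area <= 0)) {
    stop("cell_area must be positive")
  }
  # one condition per FOV
  if (nrow(table)) {
    per_fov <- unique(table[, c("fov_id", .condition_cols)])
    if (anyDuplicated(per_fov$fov_id)) {
      stop("FOV(s) with mixed conditions: ",
           paste(unique(per_fov$fov_id[duplicated(per_fov$fov_id)]), collapse = ", "))
    }
  }
  fn <- feature_names(table)
  for (f in fn) {
    if (!is.numeric(table[[f]]) || anyNA(table[[f]])) {
      stop("feature column '", f, "' contains non-numeric or missing values")
    }
  }
  invisible(table)
}

# Format a data.frame for lossless CSV text: doubles at 17 significant digits
# (round-trip stable), logicals as 0/1 integers.
.format_for_csv <- function(table) {
  out <- table
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.logical(x)) {
      out[[j]] <- as.integer(x)
    } else if (is.double(x)) {
      s <- vapply(x, function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
      out[[j]] <- s
    }
  }
  out
}

#' Write a result table to CSV
#'
#' Writes any pipeline table (feature table, spatial score table, summary
#' rows) with a deterministic column order, logical flags encoded as 0/1 and
#' doubles printed with 17 significant digits so that re-reading reproduces
#' every value exactly.
#'
#' @param table a `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  ok <- tryCatch({
    utils::write.csv(.format_for_csv(table), path, row.names = FALSE,
                     quote = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Write a feature table in the CellProfiler-style dialect
#'
#' The inverse of [read_feature_table()]: canonical metadata columns are
#' renamed through `schema_map`, so `read_feature_table(write_feature_table(x))`
#' reproduces `x` exactly.
#'
#' @inheritParams read_feature_table
#' @param table a validated feature table.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                schema_map = cellprofiler_schema()) {
  validate_feature_table(table)
  out <- table
  idx <- match(names(schema_map), colnames(out))
  colnames(out)[idx] <- unlist(schema_map)
  write_table(out, path)
}
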