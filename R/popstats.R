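# Non-spatial population readouts: area-normalized marginal distributions,
# rank-based k-sample tests, percent-change summaries.

#' Area-normalized intensity
#'
#' Per-cell total intensity divided by cell area, the standard way to compare
#' expression between cells of very different sizes.
#'
#' @param total_intensity non-negative numeric vector (or scalar).
#' @param cell_area positive numeric vector (pixels^2), recycled against
#'   `total_intensity`.
#' @return `total_intensity / cell_area`, element-wise.
#' @export
area_normalize <- function(total_intensity, cell_area) {
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  if (any(total_intensity < 0)) stop("total_intensity must be non-negative")
  total_intensity / cell_area
}

#' Kruskal-Wallis rank test across k samples
#'
#' Non-parametric k-sample location test on ranks, with tie correction; the
#' p-value uses the chi-square approximation with k - 1 degrees of freedom.
#' A degenerate input in which every pooled value is identical returns
#' `H = 0, p = 1` (no evidence of any difference).
#'
#' @param groups list of >= 2 numeric vectors (each non-empty, pooled
#'   n >= 3).
#' @return list with `H` (the test statistic), `p`, `df`, and `n` per group.
#' @export
#' @examples
#' k_sample_rank_test(list(c(1, 2, 3), c(4, 5, 6)))$H  # 27/7
k_sample_rank_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n < 1L) || sum(n) < 3L) {
    stop("each group needs >= 1 value and pooled n >= 3")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = n))
  }
  g <- factor(rep.int(seq_along(groups), n))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = n)
}

#' Significance tier of a p-value
#'
#' Star coding used in the figure annotations: `*` for P < 0.01, `**` for
#' P < 0.001, `***` for P < 0.0001; non-significant results (P > 0.05) get
#' an empty string, and `"ns"` marks 0.01 <= P <= 0.05.
#'
#' @param p p-value(s).
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "***"
    else if (pi < 1e-3) "**"
    else if (pi < 1e-2) "*"
    else if (pi <= 0.05) "ns"
    else ""
  }, character(1))
}

#' Percent change of a treated value against a reference
#'
#' @param reference positive baseline value(s).
#' @param treated value(s) to compare.
#' @return `100 * (treated - reference) / reference`.
#' @export
#' @examples
#' percent_change(100, 132)  # +32
#' percent_change(100, 53)   # -47
percent_change <- function(reference, treated) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (treated - reference) / reference
}

#' Compare marginal distributions across conditions
#'
#' Summarizes per-cell values (e.g. area-normalized intensities) for each
#' group as empirical quantiles and histogram counts over bin edges shared
#' across all groups, and tests the groups with the Kruskal-Wallis rank test.
#'
#' @param values numeric vector of per-cell values.
#' @param group factor/character vector of the same length (e.g. treatment).
#' @param n_bins number of shared histogram bins (default 50).
#' @param probs quantiles reported per group.
#' @return list with `test` (from [k_sample_rank_test()]), `quantiles`
#'   (groups x probs matrix), `breaks` (shared bin edges) and `counts`
#'   (groups x bins matrix).
#' @export
compare_marginals <- function(values, group, n_bins = 50L,
                              probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  split_vals <- split(values, group)
  breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
  counts <- t(vapply(split_vals, function(v) {
    graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  }, numeric(n_bins)))
  quantiles <- t(vapply(split_vals, stats::quantile, numeric(length(probs)),
                        probs = probs, names = FALSE))
  colnames(quantiles) <- sprintf("q%g", 100 * probs)
  list(test = k_sample_rank_test(split_vals),
       quantiles = quantiles, breaks = breaks, counts = counts)
}
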