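# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths (row-standardized dot products, stats::kruskal.test,
# quantile types): correlations from the covariance/SD definition, kNN from a
# full all-pairs sort, percentiles by hand interpolation, Kruskal-Wallis from
# the rank-sum formula with explicit tie correction.

oracle_pearson <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Linear-interpolation percentile between order statistics (quantile type 7).
oracle_quantile_linear <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# All-pairs kNN with distance ties broken by ascending cell_id.
oracle_knn <- function(ids, x, y, k) {
  out <- list()
  for (a in seq_along(ids)) {
    d <- sqrt((x - x[a])^2 + (y - y[a])^2)
    others <- setdiff(seq_along(ids), a)
    ord <- others[order(d[others], ids[others])]
    out[[ids[a]]] <- ids[ord[seq_len(min(k, length(ord)))]]
  }
  out
}

# Per-cell median neighbor correlation via plain stats::cor calls.
oracle_median_neighbor <- function(table, neighbors) {
  m <- feature_matrix(table)
  vapply(table$cell_id, function(id) {
    nb <- neighbors[[id]]
    stats::median(vapply(nb, function(j) {
      stats::cor(m[id, ], m[j, ])
    }, numeric(1)))
  }, numeric(1))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction.
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(x)
  rbar <- vapply(split(r, rep(seq_along(groups), n)), mean, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Exhaustive permutation distribution of a k-sample statistic over all
# reassignments of pooled values to the given group sizes.
oracle_perm_p <- function(groups, stat) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  obs <- stat(groups)
  combos <- utils::combn(length(x), n[1])
  count <- 0L
  total <- 0L
  for (j in seq_len(ncol(combos))) {
    g1 <- combos[, j]
    rest <- setdiff(seq_along(x), g1)
    if (length(n) == 2L) {
      s <- stat(list(x[g1], x[rest]))
      total <- total + 1L
      if (s >= obs - 1e-12) count <- count + 1L
    } else {
      inner <- utils::combn(length(rest), n[2])
      for (jj in seq_len(ncol(inner))) {
        g2 <- rest[inner[, jj]]
        g3 <- setdiff(rest, g2)
        s <- stat(list(x[g1], x[g2], x[g3]))
        total <- total + 1L
        if (s >= obs - 1e-12) count <- count + 1L
      }
    }
  }
  count / total
}
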