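# Residual spatial-autocorrelation diagnostics. A well-specified spatial
# model should leave residuals with no detectable autocorrelation at any
# distance; the correlogram (Moran's I per distance bin, with permutation
# significance) makes that comparable between the global and the
# geographically weighted fit.

#' Moran's I for one distance bin
#'
#' Binary-weight Moran's I: `w_ij = 1` iff the great-circle distance between
#' stations i and j falls in `[bin[1], bin[2])` (the final bin of a
#' correlogram closes the right edge), zero otherwise, `w_ii = 0`. With
#' centred values z, `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2`.
#'
#' @param values one value per station (e.g. fit residuals).
#' @param table a [station_table()] supplying coordinates.
#' @param bin length-2 numeric, distance interval in km.
#' @param dist_matrix optional precomputed [station_distance_matrix()].
#' @param right_closed include pairs exactly at `bin[2]`.
#' @return list with `i` (the statistic, `NA` if the bin is empty or the
#'   values have zero variance), `n_pairs` (unordered pairs in the bin) and
#'   `flag` (`"ok"`, `"empty_bin"` or `"zero_variance"`).
#' @export
morans_i <- function(values, table, bin, dist_matrix = NULL,
                     right_closed = FALSE) {
  n <- length(values)
  stopifnot(n == nrow(table), length(bin) == 2L, bin[1] < bin[2])
  if (is.null(dist_matrix)) dist_matrix <- station_distance_matrix(table)
  A <- dist_matrix >= bin[1] &
    (if (right_closed) dist_matrix <= bin[2] else dist_matrix < bin[2])
  diag(A) <- FALSE
  W <- sum(A)
  if (W == 0) return(list(i = NA_real_, n_pairs = 0L, flag = "empty_bin"))
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) return(list(i = NA_real_, n_pairs = as.integer(W / 2),
                           flag = "zero_variance"))
  list(i = (n / W) * sum(A * outer(z, z)) / s2,
       n_pairs = as.integer(W / 2), flag = "ok")
}

#' Equal-count distance bin edges for a station table
#'
#' Quantile edges of the pairwise-distance distribution, so each bin holds
#' roughly the same number of station pairs — appropriate when station
#' density is very uneven across basins.
#'
#' @param table a [station_table()].
#' @param n_bins number of bins.
#' @param dist_matrix optional precomputed distance matrix.
#' @return numeric vector of `n_bins + 1` edges, km.
#' @export
quantile_bin_edges <- function(table, n_bins = 10L, dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- station_distance_matrix(table)
  d <- dist_matrix[upper.tri(dist_matrix)]
  edges <- unname(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  if (anyDuplicated(edges)) edges <- unique(edges)
  edges
}

#' Residual correlogram with permutation significance
#'
#' Moran's I of the residuals in each distance bin, with a two-sided
#' permutation p-value: the residuals are randomly relabelled across stations
#' `n_perm` times and, per bin, p is the fraction of permutations (plus the
#' observation) whose statistic lies at least as far from the permutation
#' mean as the observed one.
#'
#' @param residuals per-station residuals, aligned with `table`.
#' @param table a [station_table()].
#' @param bins either an integer bin count (quantile edges are derived) or a
#'   numeric vector of edges in km covering the observed distance range.
#' @param n_perm number of permutations; fewer than 99 limits the p-value
#'   resolution and draws a warning.
#' @param seed integer seed recorded in the output.
#' @return object of class `ballast_correlogram`: a data frame with one row
#'   per bin (`bin_lo`, `bin_hi`, `n_pairs`, `morans_i`, `p_perm`, `flag`)
#'   and attributes `seed`, `n_perm`.
#' @export
residual_correlogram <- function(residuals, table, bins = 10L, n_perm = 999L,
                                 seed = 1L) {
  stopifnot(length(residuals) == nrow(table))
  if (n_perm < 99L) warning("n_perm < 99: permutation p-values are coarse")
  D <- station_distance_matrix(table)
  edges <- if (length(bins) == 1L) quantile_bin_edges(table, bins, D) else
    as.numeric(bins)
  n_bins <- length(edges) - 1L
  n <- length(residuals)
  z <- residuals - mean(residuals)
  s2 <- sum(z^2)

  # per-bin unordered pair index lists (upper triangle)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  dvec <- D[upper.tri(D)]
  bin_of <- findInterval(dvec, edges, rightmost.closed = TRUE)
  bin_of[bin_of < 1L | bin_of > n_bins] <- NA_integer_
  pairs <- lapply(seq_len(n_bins), function(b) ut[which(bin_of == b), , drop = FALSE])
  n_pairs <- vapply(pairs, nrow, integer(1))
  W <- 2 * n_pairs

  stat <- function(zz) {
    vapply(seq_len(n_bins), function(b) {
      if (n_pairs[b] == 0L) return(NA_real_)
      pp <- pairs[[b]]
      (n / W[b]) * 2 * sum(zz[pp[, 1]] * zz[pp[, 2]]) / sum(zz^2)
    }, numeric(1))
  }
  i_obs <- stat(z)

  set.seed(seed)
  perm_mat <- matrix(NA_real_, n_perm, n_bins)
  for (r in seq_len(n_perm)) perm_mat[r, ] <- stat(z[sample.int(n)])
  perm_mean <- colMeans(perm_mat)
  p_perm <- vapply(seq_len(n_bins), function(b) {
    if (is.na(i_obs[b]) || s2 == 0) return(NA_real_)
    dev_obs <- abs(i_obs[b] - perm_mean[b])
    (1 + sum(abs(perm_mat[, b] - perm_mean[b]) >= dev_obs - 1e-15)) / (n_perm + 1)
  }, numeric(1))

  flag <- ifelse(n_pairs == 0L, "empty_bin",
                 ifelse(s2 == 0, "zero_variance", "ok"))
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       n_pairs = n_pairs, morans_i = i_obs, p_perm = p_perm,
                       flag = flag, stringsAsFactors = FALSE),
            seed = seed, n_perm = n_perm,
            class = c("ballast_correlogram", "data.frame"))
}

#' @export
print.ballast_correlogram <- function(x, ...) {
  cat("Residual Moran's I correlogram (", attr(x, "n_perm"),
      " permutations, seed ", attr(x, "seed"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$bin_lo <- round(df$bin_lo); df$bin_hi <- round(df$bin_hi)
  df$morans_i <- sprintf("%.3f", df$morans_i)
  print(df, row.names = FALSE)
  invisible(x)
}
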