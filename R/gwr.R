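# Geographically weighted regression (GWR) for the ballast model, built from
# first principles: great-circle distances, an adaptive Gaussian kernel whose
# local bandwidth is the distance to the Nth nearest neighbour, weighted
# least squares at every station, hat-matrix-based effective degrees of
# freedom, and AICc bandwidth selection.

.earth_radius_km <- 6371.0

#' Great-circle (haversine) distance
#'
#' Distance on a sphere of radius 6371 km. Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @param radius_km sphere radius, km.
#' @return distance in km.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2,
                                  radius_km = .earth_radius_km) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 360, na.rm = TRUE)) {
    stop("coordinates out of range")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix of a station table
#'
#' @param table a [station_table()] (or data frame with `lat`, `lon`).
#' @param radius_km sphere radius, km.
#' @return symmetric n x n matrix of distances, km.
#' @export
station_distance_matrix <- function(table, radius_km = .earth_radius_km) {
  n <- nrow(table)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- great_circle_distance(table$lat[i], table$lon[i],
                                    table$lat, table$lon, radius_km)
  }
  (D + t(D)) / 2  # enforce exact symmetry
}

#' Adaptive Gaussian kernel specification
#'
#' The kernel's bandwidth adapts to the sampling density: at each regression
#' point the local bandwidth `h_i` is the distance to its `n_neighbors`-th
#' nearest neighbour (the point itself counts as neighbour 1), and
#' observation j receives weight `exp(-0.5 (d_ij / h_i)^2)`.
#'
#' @param n_neighbors integer neighbour count (the "bandwidth"); must be at
#'   least p + 2 = 6 for the four-parameter ballast model.
#' @return object of class `kernel_spec`.
#' @export
adaptive_gaussian_kernel <- function(n_neighbors) {
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 6L) stop("n_neighbors must be >= 6 (p + 2)")
  structure(list(family = "adaptive_gaussian", n_neighbors = n_neighbors),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Adaptive Gaussian kernel, bandwidth =", x$n_neighbors, "neighbours\n")
  invisible(x)
}

#' Adaptive Gaussian weights for one regression point
#'
#' @param target_index row index of the regression point.
#' @param table a [station_table()].
#' @param kernel an [adaptive_gaussian_kernel()].
#' @param dist_matrix optional precomputed [station_distance_matrix()].
#' @return numeric vector of weights in (0, 1], one per station; the target's
#'   own weight is 1.
#' @export
adaptive_gaussian_weights <- function(target_index, table, kernel,
                                      dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- station_distance_matrix(table)
  n <- nrow(dist_matrix)
  if (kernel$n_neighbors > n) stop("n_neighbors exceeds the station count")
  d <- dist_matrix[target_index, ]
  h <- sort(d, partial = kernel$n_neighbors)[kernel$n_neighbors]
  if (h <= 0) {
    stop("degenerate bandwidth at station index ", target_index,
         ": the ", kernel$n_neighbors, " nearest neighbours are co-located; ",
         "jitter the coordinates or raise n_neighbors")
  }
  exp(-0.5 * (d / h)^2)
}

# design matrix [f_pic, f_bsi, f_lith, 1] for the complete rows of a table
.ballast_design <- function(d) {
  cbind(f_pic = d$f_pic, f_bsi = d$f_bsi, f_lith = d$f_lith, intercept = 1)
}

#' Local weighted least-squares fit at one station
#'
#' Solves `beta_i = (X' W X)^-1 X' W y` and returns the hat-matrix row
#' `x_i' (X' W X)^-1 X' W`, whose inner product with `y` is the locally
#' fitted value at the target.
#'
#' @param target_index row index of the regression point.
#' @param table a [station_table()] (complete rows only; see [fit_gwr()]).
#' @param weights per-station weights, e.g. [adaptive_gaussian_weights()].
#' @return list with `coefficients` (named a, b, c, d), `hat_row`, `fitted`
#'   (at the target) and `residual`.
#' @export
fit_local <- function(target_index, table, weights) {
  d <- as.data.frame(table)
  X <- .ballast_design(d)
  y <- d$f_poc
  XtW <- t(X * weights)               # X' W
  XtWX <- XtW %*% X
  ok <- TRUE
  beta <- tryCatch(solve(XtWX, XtW %*% y), error = function(e) {ok <<- FALSE; NULL})
  if (!ok || any(!is.finite(beta))) {
    stop("singular local fit at station '", d$station_id[target_index],
         "' (index ", target_index, "): weighted design is rank deficient")
  }
  hat_row <- drop(X[target_index, ] %*% solve(XtWX, XtW))
  fitted_i <- drop(X[target_index, ] %*% beta)
  list(coefficients = stats::setNames(drop(beta), c("a", "b", "c", "d")),
       hat_row = hat_row,
       fitted = fitted_i,
       residual = y[target_index] - fitted_i)
}

#' Fit the geographically weighted ballast regression
#'
#' Performs a local weighted least-squares fit of the ballast model at every
#' station, giving spatially varying carrying coefficients. The effective
#' number of parameters is the hat-matrix trace `tr(S)` (`S` rows from
#' [fit_local()]); AICc uses [aicc_gaussian()] with `k_eff = tr(S)`, and the
#' global R^2 pools the local residuals. Each station's local R^2 is the
#' weighted R^2 of its local model over all observations under its own
#' kernel weights.
#'
#' @param table a [station_table()]; stations with incomplete fluxes are
#'   excluded as in [fit_mlra()].
#' @param kernel an [adaptive_gaussian_kernel()], e.g. from
#'   [select_bandwidth()].
#' @param dist_matrix optional precomputed distance matrix for the complete
#'   rows.
#' @param force_uniform if `TRUE` every observation gets weight 1 (the
#'   ordinary-least-squares limit; for checking against [fit_mlra()]).
#' @return object of class `ballast_gwr`: `stations` (data frame of
#'   station_id, lat, lon, local a/b/c/d, fitted, residual, local_r2,
#'   hat_diag), `kernel`, `trace_s`, `aicc`, `r2`, `rss`, `tss`, `n`, `p`.
#' @examples
#' tab <- generate_table(default_paperlike_config(n_stations = 30L))$table
#' sel <- select_bandwidth(tab)
#' fit_gwr(tab, sel$kernel)
#' @export
fit_gwr <- function(table, kernel, dist_matrix = NULL, force_uniform = FALSE) {
  stopifnot(inherits(table, "station_table"), inherits(kernel, "kernel_spec"))
  rows <- complete_flux_rows(table)
  d <- as.data.frame(table)[rows, ]
  rownames(d) <- NULL
  n <- nrow(d)
  p <- 4L
  if (kernel$n_neighbors > n) stop("n_neighbors exceeds the station count")
  dsub <- station_table(d)
  if (is.null(dist_matrix)) dist_matrix <- station_distance_matrix(dsub)
  y <- d$f_poc
  X <- .ballast_design(d)
  coefs <- matrix(NA_real_, n, 4)
  fitted <- residual <- local_r2 <- hat_diag <- numeric(n)
  trace_s <- 0
  for (i in seq_len(n)) {
    w <- if (force_uniform) rep(1, n) else
      adaptive_gaussian_weights(i, dsub, kernel, dist_matrix)
    lf <- fit_local(i, dsub, w)
    coefs[i, ] <- lf$coefficients
    fitted[i] <- lf$fitted
    residual[i] <- lf$residual
    hat_diag[i] <- lf$hat_row[i]
    trace_s <- trace_s + lf$hat_row[i]
    yhat_i <- drop(X %*% lf$coefficients)
    ybar_w <- sum(w * y) / sum(w)
    tss_w <- sum(w * (y - ybar_w)^2)
    local_r2[i] <- 1 - sum(w * (y - yhat_i)^2) / tss_w
  }
  rss <- sum(residual^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    stations = data.frame(station_id = d$station_id, lat = d$lat, lon = d$lon,
                          a = coefs[, 1], b = coefs[, 2], c = coefs[, 3],
                          d = coefs[, 4], fitted = fitted, residual = residual,
                          local_r2 = local_r2, hat_diag = hat_diag,
                          stringsAsFactors = FALSE),
    kernel = kernel, trace_s = trace_s,
    aicc = aicc_gaussian(rss, n, k_eff = trace_s),
    r2 = 1 - rss / tss, rss = rss, tss = tss, n = n, p = p,
    excluded = setdiff(table$station_id, d$station_id)
  ), class = "ballast_gwr")
}

#' @export
print.ballast_gwr <- function(x, ...) {
  cm <- colMeans(x$stations[, c("a", "b", "c", "d")])
  cat("Geographically weighted ballast regression, n =", x$n, "\n")
  cat("  bandwidth:", x$kernel$n_neighbors, "nearest neighbours (adaptive Gaussian)\n")
  cat(sprintf("  mean local coefficients: a = %.3f, b = %.3f, c = %.3f, d = %.2f\n",
              cm[1], cm[2], cm[3], cm[4]))
  cat(sprintf("  R^2 = %.3f   AICc = %.1f   tr(S) = %.2f\n",
              x$r2, x$aicc, x$trace_s))
  invisible(x)
}

#' Select the adaptive bandwidth by AICc
#'
#' Minimises the GWR AICc over integer neighbour counts with a golden-section
#' search followed by an exhaustive sweep of the bracketing interval. Ties
#' are broken toward the larger (smoother) bandwidth.
#'
#' @param table a [station_table()].
#' @param n_min,n_max inclusive search range; defaults p + 2 = 6 up to the
#'   number of complete stations.
#' @return list with `kernel` (the optimal [adaptive_gaussian_kernel()]),
#'   `n_neighbors`, `aicc`, and `profile`, a data frame of every evaluated
#'   (n_neighbors, aicc) pair.
#' @export
select_bandwidth <- function(table, n_min = 6L, n_max = NULL) {
  rows <- complete_flux_rows(table)
  d <- as.data.frame(table)[rows, ]
  rownames(d) <- NULL
  dsub <- station_table(d)
  n <- nrow(dsub)
  if (is.null(n_max)) n_max <- n
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 6L || n_min >= n_max || n_max > n) {
    stop("invalid bandwidth search range [", n_min, ", ", n_max, "] for n = ", n)
  }
  D <- station_distance_matrix(dsub)
  cache <- new.env(parent = emptyenv())
  f <- function(b) {
    key <- as.character(b)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fit_gwr(dsub, adaptive_gaussian_kernel(b), dist_matrix = D)$aicc
    cache[[key]] <- val
    val
  }
  invphi <- (sqrt(5) - 1) / 2
  lo <- n_min; hi <- n_max
  x1 <- hi - as.integer(round((hi - lo) * invphi))
  x2 <- lo + as.integer(round((hi - lo) * invphi))
  if (x1 >= x2) { x1 <- max(lo, x2 - 1L) }
  while (hi - lo > 4L && x1 < x2) {
    if (f(x1) < f(x2)) {
      hi <- x2
    } else {
      lo <- x1
    }
    x1 <- hi - as.integer(round((hi - lo) * invphi))
    x2 <- lo + as.integer(round((hi - lo) * invphi))
    if (x1 >= x2) break
  }
  # exhaustive sweep of the bracket
  grid <- seq.int(lo, hi)
  aicc_grid <- vapply(grid, f, numeric(1))
  best <- max(grid[aicc_grid <= min(aicc_grid) + 1e-10])  # tie -> smoother
  evaluated <- sort(as.integer(ls(cache)))
  profile <- data.frame(n_neighbors = evaluated,
                        aicc = vapply(as.character(evaluated),
                                      function(k) cache[[k]], numeric(1)))
  rownames(profile) <- NULL
  list(kernel = adaptive_gaussian_kernel(best), n_neighbors = best,
       aicc = f(best), profile = profile)
}

#' ANOVA comparison of the GWR against the global MLRA
#'
#' The GWR-ANOVA convention:
#' `F = [(rss_global - rss_gwr) / nu1] / [rss_gwr / nu2]` with
#' `nu1 = tr(S) - p` (the extra effective parameters spent by the local
#' model) and `nu2 = n - tr(S)`. The degrees of freedom conventionally
#' reported alongside are `df1 = n - p` for the global model and
#' `df2 = round(n - tr(S))`; the p-value uses the real-valued `(nu1, nu2)`.
#'
#' @param global_fit a [fit_mlra()] result.
#' @param gwr_fit a [fit_gwr()] result on the same table.
#' @return object of class `ballast_anova`: `f_stat`, `df1`, `df2`, `nu1`,
#'   `nu2`, `p_value`, and `degenerate` (TRUE when the GWR does not improve
#'   on the global fit and F is reported as 0).
#' @export
anova_gwr_vs_mlra <- function(global_fit, gwr_fit) {
  stopifnot(inherits(global_fit, "ballast_mlra"), inherits(gwr_fit, "ballast_gwr"))
  if (global_fit$n != gwr_fit$n) {
    stop("fits are on different station sets (n = ", global_fit$n,
         " vs ", gwr_fit$n, ")")
  }
  n <- gwr_fit$n; p <- global_fit$p
  nu1 <- gwr_fit$trace_s - p
  nu2 <- n - gwr_fit$trace_s
  degenerate <- gwr_fit$rss >= global_fit$rss || nu1 <= 0
  if (degenerate) {
    warning("GWR does not improve on the global fit; F reported as 0")
    f_stat <- 0; p_value <- 1
  } else {
    f_stat <- ((global_fit$rss - gwr_fit$rss) / nu1) / (gwr_fit$rss / nu2)
    p_value <- stats::pf(f_stat, nu1, nu2, lower.tail = FALSE)
  }
  structure(list(f_stat = f_stat, df1 = n - p, df2 = round(nu2),
                 nu1 = nu1, nu2 = nu2, p_value = p_value,
                 degenerate = degenerate),
            class = "ballast_anova")
}

#' @export
print.ballast_anova <- function(x, ...) {
  cat(sprintf("GWR vs global MLRA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}
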