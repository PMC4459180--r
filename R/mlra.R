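# Global ballast regression: POC flux as a linear combination of the three
# mineral fluxes plus a non-associated intercept,
#   f_poc = a * f_pic + b * f_bsi + c * f_lith + d + error,
# where a, b, c are the "carrying coefficients" (mg POC per mg mineral) and d
# is the POC export not statistically tied to any mineral phase.

#' Small-sample corrected AIC for a Gaussian fit
#'
#' `AICc = 2 n ln(sigma_hat) + n ln(2 pi) + n (n + k) / (n - 2 - k)` with
#' `sigma_hat = sqrt(rss / n)`. `k` is the effective number of parameters: the
#' hat-matrix trace for a geographically weighted fit, or the parameter count
#' of a global linear model. This is the form used throughout the
#' geographically-weighted-regression literature, so global and local models
#' are compared on one scale.
#'
#' @param rss residual sum of squares, > 0.
#' @param n number of observations.
#' @param k_eff effective number of parameters; requires `n > k_eff + 2`.
#' @return AICc (dimensionless).
#' @export
aicc_gaussian <- function(rss, n, k_eff) {
  if (rss <= 0) stop("rss must be > 0")
  if (n <= k_eff + 2) {
    stop("degenerate degrees of freedom: need n > k_eff + 2 (n = ", n,
         ", k_eff = ", signif(k_eff, 4), ")")
  }
  sigma_hat <- sqrt(rss / n)
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + k_eff) / (n - 2 - k_eff)
}

#' Fit the global ballast regression (MLRA)
#'
#' Ordinary least squares of observed POC flux on the three mineral fluxes
#' with an intercept. Coefficients are unconstrained: negative carrying
#' coefficients are reported as-is. Stations missing any of the four fluxes
#' are excluded and recorded in the result.
#'
#' @param table a [station_table()].
#' @return object of class `ballast_mlra` with elements `coefficients`
#'   (named `a`, `b`, `c`, `d`), `r2`, `aicc`, `rss`, `n`, `p` (= 4),
#'   `residuals`, `fitted`, `station_id`, `excluded` (ids of incomplete
#'   stations) and the underlying `lm` fit.
#' @examples
#' tab <- generate_table(default_paperlike_config(n_stations = 30L))$table
#' fit_mlra(tab)
#' @export
fit_mlra <- function(table) {
  stopifnot(inherits(table, "station_table"))
  rows <- complete_flux_rows(table)
  excluded <- setdiff(table$station_id, table$station_id[rows])
  if (length(excluded) > 0L) {
    message("fit_mlra: excluding ", length(excluded),
            " station(s) with incomplete fluxes: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ...")
  }
  d <- as.data.frame(table)[rows, ]
  n <- nrow(d)
  p <- 4L
  if (n < 5L) stop("need at least 5 complete stations to fit the MLRA")
  X <- cbind(d$f_pic, d$f_bsi, d$f_lith, 1)
  qrX <- qr(X)
  if (qrX$rank < p) {
    cols <- c("f_pic", "f_bsi", "f_lith", "intercept")
    dropped <- cols[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(f_poc ~ f_pic + f_bsi + f_lith, data = d)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((d$f_poc - mean(d$f_poc))^2)
  structure(list(
    coefficients = stats::setNames(
      stats::coef(fit)[c("f_pic", "f_bsi", "f_lith", "(Intercept)")],
      c("a", "b", "c", "d")),
    r2 = 1 - rss / tss,
    # +1 effective parameter for the estimated error variance
    aicc = aicc_gaussian(rss, n, k_eff = p + 1),
    rss = rss, tss = tss, n = n, p = p,
    residuals = unname(res), fitted = unname(stats::fitted(fit)),
    station_id = d$station_id, excluded = excluded, lm_fit = fit
  ), class = "ballast_mlra")
}

#' @export
print.ballast_mlra <- function(x, ...) {
  cat("Global ballast regression (MLRA), n =", x$n, "\n")
  cat(sprintf("  a (PIC)  = %8.4f mg C / mg PIC\n", x$coefficients["a"]))
  cat(sprintf("  b (BSi)  = %8.4f mg C / mg BSi\n", x$coefficients["b"]))
  cat(sprintf("  c (lith) = %8.4f mg C / mg lithogenic\n", x$coefficients["c"]))
  cat(sprintf("  d (non-associated) = %.2f mg m^-2 d^-1\n", x$coefficients["d"]))
  cat(sprintf("  R^2 = %.3f   AICc = %.1f   RSS = %.4g\n", x$r2, x$aicc, x$rss))
  if (length(x$excluded) > 0)
    cat("  excluded incomplete stations:", length(x$excluded), "\n")
  invisible(x)
}

#' Predict POC flux from a global fit
#'
#' @param object a `ballast_mlra` fit.
#' @param newdata a [station_table()] or data frame with the mineral fluxes.
#' @param ... unused.
#' @return predicted POC flux, mg m^-2 d^-1.
#' @export
predict.ballast_mlra <- function(object, newdata, ...) {
  cf <- object$coefficients
  cf["a"] * newdata$f_pic + cf["b"] * newdata$f_bsi +
    cf["c"] * newdata$f_lith + cf["d"]
}
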