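# Test of geographical variability (TGV). For each term of the ballast model
# it compares the fully local GWR against a semiparametric ("mixed") model in
# which that one term's coefficient is global while the others stay local.
# The Diff of Criterion is AICc(fully local) - AICc(term-k global): a value
# below -2 supports genuine spatial variability of the term, a value in
# (-2, 2) is weak evidence either way, and a positive value says the global
# term describes the data at least as well.

# GWR smoother matrix S for a given design matrix (columns already chosen):
# row i is x_i' (X' W_i X)^-1 X' W_i.
.gwr_smoother <- function(X, dsub, kernel, dist_matrix) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- adaptive_gaussian_weights(i, dsub, kernel, dist_matrix)
    XtW <- t(X * w)
    S[i, ] <- drop(X[i, , drop = FALSE] %*% solve(XtW %*% X, XtW))
  }
  S
}

#' Test of geographical variability of the local carrying coefficients
#'
#' For each model term (PIC, BSi, lithogenic, intercept), fits a mixed model
#' holding that term's coefficient global while the remaining three stay
#' geographically weighted. The global coefficient is estimated by two-stage
#' back-fitting: the local part is regressed out with the reduced-design GWR
#' smoother, the global coefficient re-estimated on the residuals, and the
#' two stages iterated to convergence (relative tolerance `tol`, at most
#' `max_iter` iterations). The mixed model's effective parameter count is
#' `tr(S_reduced) + 1`, and its AICc is compared with the fully local model's.
#'
#' @param table a [station_table()].
#' @param kernel an [adaptive_gaussian_kernel()] (normally the AICc-optimal
#'   bandwidth from [select_bandwidth()]).
#' @param tol relative convergence tolerance on the global coefficient.
#' @param max_iter back-fitting iteration cap.
#' @return object of class `ballast_tgv`: a data frame with one row per term
#'   (`term`, `coef_global`, `aicc_mixed`, `diff_of_criterion`, `converged`,
#'   `n_iter`) plus attributes `aicc_full` and `kernel`. Negative
#'   `diff_of_criterion` (below -2) supports spatial variability of the term.
#' @export
test_geographical_variability <- function(table, kernel, tol = 1e-6,
                                          max_iter = 100L) {
  stopifnot(inherits(table, "station_table"), inherits(kernel, "kernel_spec"))
  full <- fit_gwr(table, kernel)
  rows <- complete_flux_rows(table)
  d <- as.data.frame(table)[rows, ]
  rownames(d) <- NULL
  dsub <- station_table(d)
  D <- station_distance_matrix(dsub)
  X <- .ballast_design(dsub)
  y <- dsub$f_poc
  terms <- c(pic = 1L, bsi = 2L, lith = 3L, intercept = 4L)
  global_start <- fit_mlra(dsub)$coefficients

  out <- lapply(names(terms), function(nm) {
    k <- terms[[nm]]
    xk <- X[, k]
    Xr <- X[, -k, drop = FALSE]
    S <- .gwr_smoother(Xr, dsub, kernel, D)
    b <- unname(global_start[k])
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      f_local <- drop(S %*% (y - xk * b))     # local part of the fit
      b_new <- sum(xk * (y - f_local)) / sum(xk^2)
      if (abs(b_new - b) <= tol * max(1, abs(b))) {
        b <- b_new
        converged <- TRUE
        break
      }
      b <- b_new
    }
    f_local <- drop(S %*% (y - xk * b))
    rss <- sum((y - f_local - xk * b)^2)
    # effective parameters: trace of the mixed model's hat matrix
    # L = S + (I - S) x m with m = [x'(I-S)x]^-1 x'(I-S); the global term
    # contributes x'(I-S)'(I-S)x / x'(I-S)x, close to (but not exactly) 1
    xs <- xk - drop(S %*% xk)
    xst <- xk - drop(crossprod(S, xk))
    k_eff <- sum(diag(S)) + sum(xst * xs) / sum(xk * xs)
    aicc_mixed <- aicc_gaussian(rss, length(y), k_eff)
    data.frame(term = nm, coef_global = b, aicc_mixed = aicc_mixed,
               diff_of_criterion = full$aicc - aicc_mixed,
               converged = converged, n_iter = iter,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(!res$converged)) {
    warning("TGV back-fitting did not converge for term(s): ",
            paste(res$term[!res$converged], collapse = ", "))
  }
  structure(res, aicc_full = full$aicc, kernel = kernel,
            class = c("ballast_tgv", "data.frame"))
}

#' @export
print.ballast_tgv <- function(x, ...) {
  cat("Test of geographical variability (Diff of Criterion; < -2 supports",
      "spatial variability)\n")
  df <- as.data.frame(x)
  df$diff_of_criterion <- sprintf("%.2f", df$diff_of_criterion)
  print(df[, c("term", "coef_global", "diff_of_criterion", "converged")],
        row.names = FALSE)
  invisible(x)
}
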