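test_that("haversine distances match closed forms and an independent library", {
  expect_equal(great_circle_distance(12, 34, 12, 34), 0)
  expect_equal(great_circle_distance(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(great_circle_distance(90, 0, -90, 0), pi * 6371,
               tolerance = 1e-6)
  expect_error(great_circle_distance(95, 0, 0, 0), "out of range")
  skip_if_not_installed("geosphere")
  set.seed(1)
  p1 <- cbind(runif(20, -180, 180), runif(20, -90, 90))
  p2 <- cbind(runif(20, -180, 180), runif(20, -90, 90))
  ref <- geosphere::distHaversine(p1, p2, r = 6371)
  got <- great_circle_distance(p1[, 2], p1[, 1], p2[, 2], p2[, 1])
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("adaptive Gaussian weights follow the kernel definition", {
  tab <- random_table(25, seed = 4, noise_sd = 10)
  D <- station_distance_matrix(tab)
  kern <- adaptive_gaussian_kernel(8)
  w <- adaptive_gaussian_weights(1, tab, kern, D)
  expect_equal(w[1], 1)                      # d = 0 -> weight 1
  expect_true(all(w > 0 & w <= 1))
  # the 8th-nearest neighbour sits exactly at the local bandwidth:
  # its weight is exp(-1/2)
  h <- sort(D[1, ])[8]
  at_h <- which(D[1, ] == h)[1]
  expect_equal(w[at_h], exp(-0.5))
  # weights decrease with distance (brute-force sort as the oracle)
  ord <- order(D[1, ])
  expect_true(all(diff(w[ord]) <= 1e-15))
  # permuting station order permutes weights identically
  perm <- sample(nrow(tab))
  tab_p <- station_table(as.data.frame(tab)[perm, ])
  w_p <- adaptive_gaussian_weights(which(perm == 1), tab_p, kern)
  expect_equal(w_p, w[perm], tolerance = 1e-12)
})

test_that("co-located stations filling the neighbour set are a clear error", {
  df <- as.data.frame(tiny_table(8))
  df$lat <- 50; df$lon <- -30  # all stations at one point
  tab <- station_table(df)
  expect_error(adaptive_gaussian_weights(1, tab, adaptive_gaussian_kernel(6)),
               "degenerate bandwidth.*jitter")
})

test_that("local weighted fits match a brute-force WLS oracle", {
  tab <- random_table(8, seed = 13, noise_sd = 12)
  set.seed(99)
  for (rep in 1:5) {
    w <- runif(8, 0.05, 1)
    i <- sample(8, 1)
    lf <- fit_local(i, tab, w)
    X <- cbind(tab$f_pic, tab$f_bsi, tab$f_lith, 1)
    beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% tab$f_poc)
    expect_equal(unname(lf$coefficients), drop(beta), tolerance = 1e-8)
    expect_equal(sum(lf$hat_row * tab$f_poc), lf$fitted, tolerance = 1e-9)
  }
})

test_that("uniform weights reduce the local fit to the global one", {
  tab <- random_table(30, seed = 17, noise_sd = 20)
  glob <- fit_mlra(tab)
  lf <- fit_local(5, tab, rep(1, 30))
  expect_equal(lf$coefficients, glob$coefficients, tolerance = 1e-8)
  # hat row of an intercept OLS model sums to 1
  expect_equal(sum(lf$hat_row), 1, tolerance = 1e-10)
})

test_that("uniform-weight GWR reproduces the global fit exactly", {
  tab <- random_table(40, seed = 23, noise_sd = 25)
  glob <- fit_mlra(tab)
  gwr <- fit_gwr(tab, adaptive_gaussian_kernel(40), force_uniform = TRUE)
  expect_equal(gwr$r2, glob$r2, tolerance = 1e-8)
  for (i in seq_len(40)) {
    expect_equal(unname(unlist(gwr$stations[i, c("a", "b", "c", "d")])),
                 unname(glob$coefficients), tolerance = 1e-8)
  }
  expect_equal(gwr$trace_s, 4, tolerance = 1e-8)
  expect_equal(gwr$rss, glob$rss, tolerance = 1e-6)
})

test_that("constant-coefficient tables are recovered within sampling error", {
  cfg <- two_basin_config(60, seed = 31, constant_fields(), noise_sd = 10)
  g <- generate_table(cfg)
  gwr <- fit_gwr(g$table, adaptive_gaussian_kernel(30))
  # local estimates scatter around the constant truth
  expect_lt(median(abs(gwr$stations$a - 0.3)), 0.15)
  expect_lt(median(abs(gwr$stations$b - 0.2)), 0.1)
  expect_lt(max(abs(gwr$stations$d - 50)), 40)
})

test_that("effective parameters shrink as the bandwidth grows", {
  tab <- random_table(50, seed = 41, noise_sd = 20)
  tr <- vapply(c(8, 15, 25, 40, 50), function(b)
    fit_gwr(tab, adaptive_gaussian_kernel(b))$trace_s, numeric(1))
  expect_true(all(diff(tr) < 1e-6))
  expect_true(all(tr > 4 & tr < 50))
})

test_that("the fit is equivariant under station relabelling", {
  tab <- random_table(30, seed = 51, noise_sd = 15)
  gwr <- fit_gwr(tab, adaptive_gaussian_kernel(12))
  perm <- sample(30)
  tab_p <- station_table(as.data.frame(tab)[perm, ])
  gwr_p <- fit_gwr(tab_p, adaptive_gaussian_kernel(12))
  m <- merge(gwr$stations, gwr_p$stations, by = "station_id")
  expect_equal(m$a.x, m$a.y, tolerance = 1e-9)
  expect_equal(m$residual.x, m$residual.y, tolerance = 1e-9)
  expect_equal(gwr_p$trace_s, gwr$trace_s, tolerance = 1e-9)
})

test_that("golden-section bandwidth search agrees with the exhaustive oracle", {
  cfg <- two_basin_config(40, seed = 61, list(
    a = field_logistic_lat(-0.2, 0.9, 0, 12),
    b = field_constant(0.2), c = field_constant(0.1), d = field_constant(60)
  ), noise_sd = 25)
  g <- generate_table(cfg)
  sel <- select_bandwidth(g$table)
  # exhaustive oracle over the full range
  aicc_all <- vapply(6:40, function(b)
    fit_gwr(g$table, adaptive_gaussian_kernel(b))$aicc, numeric(1))
  oracle <- (6:40)[which.min(aicc_all)]
  expect_equal(sel$n_neighbors, oracle)
  expect_equal(sel$aicc, min(aicc_all), tolerance = 1e-10)
  expect_true(all(diff(sel$profile$n_neighbors) > 0))
})

test_that("pure-noise constant-truth tables select a large (smooth) bandwidth", {
  cfg <- two_basin_config(40, seed = 71, constant_fields(), noise_sd = 30)
  g <- generate_table(cfg)
  sel <- select_bandwidth(g$table)
  expect_gte(sel$n_neighbors, 28)  # smoothest 30% of the search range
})

test_that("ANOVA compares the two models on the GWR convention", {
  g <- generate_table(default_paperlike_config(seed = 7))
  glob <- fit_mlra(g$table)
  gwr <- fit_gwr(g$table, adaptive_gaussian_kernel(30))
  an <- anova_gwr_vs_mlra(glob, gwr)
  expect_equal(an$df1, 91)
  expect_equal(an$df2, round(95 - gwr$trace_s))
  # F from its definition
  nu1 <- gwr$trace_s - 4; nu2 <- 95 - gwr$trace_s
  expect_equal(an$f_stat, ((glob$rss - gwr$rss) / nu1) / (gwr$rss / nu2))
  expect_equal(an$p_value, pf(an$f_stat, nu1, nu2, lower.tail = FALSE))
  # degenerate case: uniform-weight GWR equals the global fit
  gwr_u <- fit_gwr(g$table, adaptive_gaussian_kernel(95), force_uniform = TRUE)
  expect_warning(an0 <- anova_gwr_vs_mlra(glob, gwr_u), "F reported as 0")
  expect_equal(an0$f_stat, 0)
})

test_that("a strongly varying field yields an F beyond a coordinate-permutation null", {
  cfg <- two_basin_config(60, seed = 81, list(
    a = field_logistic_lat(-0.1, 1.1, 0, 10),
    b = field_constant(0.2), c = field_constant(0.1), d = field_constant(60)
  ), noise_sd = 20)
  g <- generate_table(cfg)
  glob <- fit_mlra(g$table)
  kern <- adaptive_gaussian_kernel(25)
  f_obs <- anova_gwr_vs_mlra(glob, fit_gwr(g$table, kern))$f_stat
  # null: shuffle the coordinates, breaking any spatial signal
  set.seed(82)
  f_null <- replicate(30, {
    df <- as.data.frame(g$table)
    perm <- sample(nrow(df))
    df$lat <- df$lat[perm]; df$lon <- df$lon[perm]
    tab <- station_table(df)
    suppressWarnings(anova_gwr_vs_mlra(fit_mlra(tab), fit_gwr(tab, kern))$f_stat)
  })
  expect_gt(f_obs, quantile(f_null, 0.99))
})
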