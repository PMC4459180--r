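# minimal fitted-coefficient object for arithmetic cases
fake_gwr <- function(tab, a, b, c, d) {
  n <- nrow(tab)
  structure(list(stations = data.frame(
    station_id = tab$station_id, lat = tab$lat, lon = tab$lon,
    a = rep_len(a, n), b = rep_len(b, n), c = rep_len(c, n), d = rep_len(d, n),
    stringsAsFactors = FALSE
  )), class = "ballast_gwr")
}

test_that("partition arithmetic and percentages are exact", {
  tab <- station_table(data.frame(
    station_id = "S1", date = as.Date("2013-01-01"), lat = 50, lon = -20,
    f_poc = 200, f_pic = 100, f_bsi = 10, f_lith = 5
  ))
  part <- partition_poc(fake_gwr(tab, 0.5, 0, 0, 0), tab)
  expect_equal(part$poc_pic, 50)
  expect_equal(part$pct_pic, 25)
  expect_equal(part$pct_ballasted, 25)
  # intercept-only coefficients give zero ballasted share
  part0 <- partition_poc(fake_gwr(tab, 0, 0, 0, 120), tab)
  expect_equal(part0$pct_ballasted, 0)
  expect_equal(part0$poc_nonassoc, 120)
  expect_equal(part0$residual, 80)
})

test_that("the decomposition is exactly additive for real fits", {
  g <- generate_table(default_paperlike_config(seed = 5))
  gwr <- fit_gwr(g$table, adaptive_gaussian_kernel(30))
  part <- partition_poc(gwr, g$table)
  recon <- part$poc_pic + part$poc_bsi + part$poc_lith + part$poc_nonassoc +
    part$residual
  expect_equal(recon, part$f_poc, tolerance = 1e-12)
  expect_equal(part$pct_ballasted, part$pct_pic + part$pct_bsi + part$pct_lith,
               tolerance = 1e-12)
  glob <- fit_mlra(g$table)
  partg <- partition_poc(glob, g$table)
  expect_equal(partg$poc_pic + partg$poc_bsi + partg$poc_lith +
                 partg$poc_nonassoc + partg$residual,
               partg$f_poc, tolerance = 1e-12)
})

test_that("percentages are invariant to rescaling all fluxes at a station", {
  tab <- random_table(10, seed = 44, noise_sd = 10)
  fit <- fake_gwr(tab, 0.4, 0.2, 0.1, 0)
  part1 <- partition_poc(fit, tab)
  df <- as.data.frame(tab)
  for (col in c("f_poc", "f_pic", "f_bsi", "f_lith")) df[[col]] <- 3 * df[[col]]
  part3 <- partition_poc(fake_gwr(tab, 0.4, 0.2, 0.1, 0), station_table(df))
  expect_equal(part3$pct_pic, part1$pct_pic, tolerance = 1e-12)
  expect_equal(part3$pct_ballasted, part1$pct_ballasted, tolerance = 1e-12)
})

test_that("negative components and zero POC are flagged, not hidden", {
  tab <- station_table(data.frame(
    station_id = c("N", "Z"), date = as.Date("2013-01-01"),
    lat = c(0, 1), lon = c(0, 1),
    f_poc = c(100, 0), f_pic = c(10, 10), f_bsi = c(5, 5), f_lith = c(1, 1)
  ))
  part <- partition_poc(fake_gwr(tab, -0.5, 0.2, 0.1, 50), tab)
  expect_true(part$negative_component[1])
  expect_equal(part$poc_pic[1], -5)
  expect_true(part$zero_poc[2])
  expect_true(is.na(part$pct_pic[2]))
  clipped <- partition_poc(fake_gwr(tab, -0.5, 0.2, 0.1, 50), tab,
                           clip_negative = TRUE)
  expect_equal(clipped$poc_pic[1], 0)
})

test_that("regional summaries aggregate station means with first-match priority", {
  g <- generate_table(default_paperlike_config(seed = 6))
  gwr <- fit_gwr(g$table, adaptive_gaussian_kernel(30))
  part <- partition_poc(gwr, g$table)
  reg <- regional_summary(part)
  glob_row <- reg[reg$region == "global", ]
  expect_equal(glob_row$n, 95)
  expect_equal(sum(reg$n[reg$region != "global"]), 95)
  # a single region covering everything equals the global means
  all_region <- data.frame(name = "all", lat_min = -90, lat_max = 90,
                           lon_min = -180, lon_max = 180, priority = 1)
  reg_all <- regional_summary(part, all_region)
  expect_equal(reg_all$pct_ballasted[reg_all$region == "all"],
               glob_row$pct_ballasted)
  # regional means lie between the regional min and max station values
  hl <- reg[reg$region == "hlna", ]
  in_hl <- part$lat >= 45 & part$lat <= 66.5 & part$lon >= -80 & part$lon <= 20
  in_hl <- in_hl & !(part$lat >= 66.5)
  expect_gte(hl$pct_ballasted, min(part$pct_ballasted[in_hl]))
  expect_lte(hl$pct_ballasted, max(part$pct_ballasted[in_hl]))
})

test_that("latitude-band station counts match the study-like sampling design", {
  g <- generate_table(default_paperlike_config())
  expect_equal(sum(g$table$lat > 45), 49)
  expect_equal(sum(g$table$lat < -45), 24)
})
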