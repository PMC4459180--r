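# Synthetic station tables with known, spatially varying carrying-coefficient
# fields: every pipeline stage can be tested by parameter recovery without
# external data. Generated tables satisfy the ballast model exactly:
#   f_poc = a(s) f_pic + b(s) f_bsi + c(s) f_lith + d(s) + eps,
# with lognormal mineral fluxes, Gaussian noise, and rejection sampling of
# eps so retained stations keep f_poc >= 0 under the exact linear model.

#' Coefficient-field constructors
#'
#' A coefficient field maps (lat, lon) to a carrying-coefficient value.
#' Three forms cover the study designs: spatially constant, linear in
#' latitude, and a logistic (smooth step) front at a stated latitude.
#'
#' @param value constant value.
#' @param at value at latitude 0.
#' @param slope change per degree latitude.
#' @param south,north asymptotic values south/north of the front.
#' @param lat0 front latitude, degrees.
#' @param width front e-folding width, degrees (> 0).
#' @return object of class `coef_field`.
#' @export
field_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "coef_field")
}

#' @rdname field_constant
#' @export
field_linear_lat <- function(at, slope) {
  structure(list(type = "linear_lat", at = at, slope = slope),
            class = "coef_field")
}

#' @rdname field_constant
#' @export
field_logistic_lat <- function(south, north, lat0, width) {
  stopifnot(width > 0)
  structure(list(type = "logistic_lat", south = south, north = north,
                 lat0 = lat0, width = width), class = "coef_field")
}

#' Evaluate a coefficient field
#'
#' @param field a `coef_field`.
#' @param lat,lon coordinates in degrees (vectorised).
#' @return numeric vector of coefficient values.
#' @export
eval_field <- function(field, lat, lon) {
  stopifnot(inherits(field, "coef_field"))
  switch(field$type,
    constant = rep(field$value, length(lat)),
    linear_lat = field$at + field$slope * lat,
    logistic_lat = field$south + (field$north - field$south) /
      (1 + exp(-(lat - field$lat0) / field$width)),
    stop("unknown field type: ", field$type)
  )
}

#' Synthetic-table configuration
#'
#' @param n_stations total station count (>= 10); must equal the sum of the
#'   per-box counts in `domain`.
#' @param domain data frame of lat/lon boxes with columns
#'   `lat_min, lat_max, lon_min, lon_max, n` (stations per box), mimicking
#'   multi-basin clustered sampling.
#' @param coefficient_fields named list with entries `a`, `b`, `c`, `d`, each
#'   a `coef_field` (see [field_constant()]).
#' @param mineral_flux_logmeans,mineral_flux_logsds named numeric vectors
#'   (`pic`, `bsi`, `lith`) of lognormal log-scale means/sds of the mineral
#'   fluxes (mg m^-2 d^-1).
#' @param noise_sd Gaussian noise sd on POC flux, mg m^-2 d^-1, >= 0.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations, domain, coefficient_fields,
                             mineral_flux_logmeans, mineral_flux_logsds,
                             noise_sd, seed = 1L) {
  stopifnot(n_stations >= 10, noise_sd >= 0,
            all(c("a", "b", "c", "d") %in% names(coefficient_fields)),
            all(c("pic", "bsi", "lith") %in% names(mineral_flux_logmeans)),
            all(c("pic", "bsi", "lith") %in% names(mineral_flux_logsds)),
            all(mineral_flux_logsds >= 0),
            all(c("lat_min", "lat_max", "lon_min", "lon_max", "n") %in%
                  names(domain)),
            sum(domain$n) == n_stations)
  structure(list(n_stations = as.integer(n_stations), domain = domain,
                 coefficient_fields = coefficient_fields,
                 mineral_flux_logmeans = mineral_flux_logmeans,
                 mineral_flux_logsds = mineral_flux_logsds,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic station table with known coefficient fields
#'
#' Stations are placed uniformly within each domain box, mineral fluxes drawn
#' lognormal, the true coefficient fields evaluated at each station, and POC
#' flux assembled from the exact linear model plus Gaussian noise. Stations
#' whose noisy POC flux is negative have the noise term redrawn (up to 1000
#' attempts; the redraw count is recorded in attribute `n_resampled`), so the
#' linear model holds exactly for every retained station.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (a [station_table()]) and `truth` (data frame of
#'   `station_id, lat, lon, a, b, c, d` — the true local coefficients).
#'   The same config (including seed) always returns identical output.
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dom <- config$domain
  lat <- lon <- numeric(0)
  for (b in seq_len(nrow(dom))) {
    lat <- c(lat, stats::runif(dom$n[b], dom$lat_min[b], dom$lat_max[b]))
    lon <- c(lon, stats::runif(dom$n[b], dom$lon_min[b], dom$lon_max[b]))
  }
  n <- config$n_stations
  lm_ <- config$mineral_flux_logmeans
  ls_ <- config$mineral_flux_logsds
  f_pic <- stats::rlnorm(n, lm_[["pic"]], ls_[["pic"]])
  f_bsi <- stats::rlnorm(n, lm_[["bsi"]], ls_[["bsi"]])
  f_lith <- stats::rlnorm(n, lm_[["lith"]], ls_[["lith"]])
  cf <- config$coefficient_fields
  a <- eval_field(cf$a, lat, lon)
  b <- eval_field(cf$b, lat, lon)
  c_ <- eval_field(cf$c, lat, lon)
  d_ <- eval_field(cf$d, lat, lon)
  mu <- a * f_pic + b * f_bsi + c_ * f_lith + d_
  eps <- stats::rnorm(n, 0, config$noise_sd)
  n_resampled <- 0L
  for (i in which(mu + eps < 0)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      eps[i] <- stats::rnorm(1, 0, config$noise_sd)
      n_resampled <- n_resampled + 1L
      if (mu[i] + eps[i] >= 0) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not draw a non-negative POC flux at station ", i,
           " after 1000 attempts; noise_sd dominates the signal")
    }
  }
  f_poc <- mu + eps
  ids <- sprintf("S%03d", seq_len(n))
  tab <- station_table(data.frame(
    station_id = ids,
    date = as.Date("2013-06-15") + seq_len(n),
    lat = lat, lon = lon,
    f_poc = f_poc, f_pic = f_pic, f_bsi = f_bsi, f_lith = f_lith,
    pal = NA_real_, f_th = NA_real_, region = NA_character_,
    stringsAsFactors = FALSE))
  truth <- data.frame(station_id = ids, lat = lat, lon = lon,
                      a = a, b = b, c = c_, d = d_, stringsAsFactors = FALSE)
  attr(tab, "n_resampled") <- n_resampled
  list(table = tab, truth = truth)
}

#' Study-like default synthetic configuration
#'
#' Ninety-five stations clustered over the Nordic Seas/Arctic, high-latitude
#' North Atlantic, the Atlantic subtropical gyres and the Southern Ocean
#' (49 north of 45 N, 24 south of 45 S), with coefficient fields chosen to
#' mirror the fitted spatial patterns of the surface-export study this
#' package reproduces: the PIC coefficient steps up across the equator
#' spanning roughly -0.25 to 0.97 (station-weighted mean 0.57 under the
#' north-heavy sampling, range ~1.2), the BSi coefficient a weaker step
#' (0.06 to 0.33, station mean ~0.26), the lithogenic coefficient a very
#' weak northward trend around 0.10, and a constant non-associated intercept
#' of 89 mg m^-2 d^-1. Mineral fluxes are lognormal at magnitudes typical of
#' Th-234-derived surface export, and the noise sd (60 mg m^-2 d^-1) puts
#' the global-fit R^2 of generated tables near the 0.22 the study reports
#' while the geographically weighted fit reaches roughly 0.5.
#'
#' @param seed integer seed.
#' @param n_stations station count; the default box allocation is scaled
#'   proportionally if this is not 95.
#' @param noise_sd Gaussian noise sd, mg m^-2 d^-1.
#' @return a [synthetic_config()].
#' @export
default_paperlike_config <- function(seed = 42L, n_stations = 95L,
                                     noise_sd = 60) {
  boxes <- data.frame(
    name = c("nordic_arctic", "hlna", "natl_gyre", "satl", "southern_ocean"),
    lat_min = c(66.5, 45, 5, -40, -65),
    lat_max = c(80, 66.5, 40, 0, -45),
    lon_min = c(-25, -60, -60, -40, -50),
    lon_max = c(35, 5, -10, 10, 60),
    n = c(12L, 37L, 12L, 10L, 24L),
    stringsAsFactors = FALSE
  )
  if (n_stations != 95L) {
    n_new <- pmax(1L, round(boxes$n * n_stations / 95))
    n_new[1] <- n_new[1] + (n_stations - sum(n_new))
    boxes$n <- as.integer(n_new)
  }
  synthetic_config(
    n_stations = sum(boxes$n), domain = boxes,
    coefficient_fields = list(
      a = field_logistic_lat(south = -0.25, north = 0.97, lat0 = 0, width = 15),
      b = field_logistic_lat(south = 0.06, north = 0.33, lat0 = 0, width = 15),
      c = field_linear_lat(at = 0.10, slope = 3e-4),
      d = field_constant(89)
    ),
    mineral_flux_logmeans = c(pic = log(40), bsi = log(25), lith = log(3)),
    mineral_flux_logsds = c(pic = 0.9, bsi = 1.0, lith = 1.2),
    noise_sd = noise_sd, seed = seed
  )
}
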