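# Partition of the observed POC export into mineral-associated portions.
# At each station the fitted model gives
#   f_poc = a*f_pic + b*f_bsi + c*f_lith + d + residual      (exactly),
# so each product coef x mineral flux is the POC flux statistically
# "carried" by that mineral, d is the non-associated portion, and the
# percentages are taken relative to the OBSERVED POC flux (the residual
# carries the difference, keeping the decomposition exact).

#' Partition POC export into mineral-associated portions
#'
#' Works from either a geographically weighted fit (per-station local
#' coefficients) or the global fit (one coefficient set replicated).
#' Negative associated fluxes (from negative local coefficients) are
#' reported as-is and flagged unless `clip_negative = TRUE`.
#'
#' @param fit a [fit_gwr()] or [fit_mlra()] result.
#' @param table the [station_table()] the fit was computed on.
#' @param clip_negative if `TRUE`, negative associated fluxes are clipped to
#'   zero before percentages are computed (the exact-additivity invariant
#'   then no longer holds; default `FALSE`).
#' @return object of class `ballast_partition`: a data frame with one row per
#'   fitted station — `station_id`, `lat`, `lon`, observed `f_poc`, the
#'   associated fluxes `poc_pic`, `poc_bsi`, `poc_lith`, `poc_nonassoc`
#'   (mg C m^-2 d^-1), `residual`, the percentages `pct_pic`, `pct_bsi`,
#'   `pct_lith`, `pct_nonassoc`, `pct_ballasted` (of observed POC flux) and
#'   flags `negative_component`, `zero_poc`.
#' @export
partition_poc <- function(fit, table, clip_negative = FALSE) {
  stopifnot(inherits(table, "station_table"))
  rows <- complete_flux_rows(table)
  d <- as.data.frame(table)[rows, ]
  rownames(d) <- NULL
  if (inherits(fit, "ballast_gwr")) {
    if (!identical(fit$stations$station_id, d$station_id)) {
      stop("fit and table are not aligned: station ids differ")
    }
    cf <- fit$stations[, c("a", "b", "c", "d")]
  } else if (inherits(fit, "ballast_mlra")) {
    if (!identical(fit$station_id, d$station_id)) {
      stop("fit and table are not aligned: station ids differ")
    }
    cf <- as.data.frame(as.list(fit$coefficients))[rep(1L, nrow(d)), ]
  } else {
    stop("fit must be a ballast_gwr or ballast_mlra object")
  }
  poc_pic <- cf$a * d$f_pic
  poc_bsi <- cf$b * d$f_bsi
  poc_lith <- cf$c * d$f_lith
  poc_nonassoc <- cf$d
  residual <- d$f_poc - (poc_pic + poc_bsi + poc_lith + poc_nonassoc)
  negative_component <- poc_pic < 0 | poc_bsi < 0 | poc_lith < 0 |
    poc_nonassoc < 0
  if (clip_negative) {
    poc_pic <- pmax(poc_pic, 0); poc_bsi <- pmax(poc_bsi, 0)
    poc_lith <- pmax(poc_lith, 0); poc_nonassoc <- pmax(poc_nonassoc, 0)
  }
  zero_poc <- d$f_poc == 0
  denom <- ifelse(zero_poc, NA_real_, d$f_poc)
  pct_pic <- 100 * poc_pic / denom
  pct_bsi <- 100 * poc_bsi / denom
  pct_lith <- 100 * poc_lith / denom
  structure(data.frame(
    station_id = d$station_id, lat = d$lat, lon = d$lon, f_poc = d$f_poc,
    poc_pic = poc_pic, poc_bsi = poc_bsi, poc_lith = poc_lith,
    poc_nonassoc = poc_nonassoc, residual = residual,
    pct_pic = pct_pic, pct_bsi = pct_bsi, pct_lith = pct_lith,
    pct_nonassoc = 100 * poc_nonassoc / denom,
    pct_ballasted = pct_pic + pct_bsi + pct_lith,
    negative_component = negative_component, zero_poc = zero_poc,
    stringsAsFactors = FALSE
  ), clipped = clip_negative, class = c("ballast_partition", "data.frame"))
}

#' Default ocean regions for regional summaries
#'
#' Latitude/longitude boxes, matched in priority order (first match wins):
#' Nordic Seas / Arctic (lat >= 66.5 N), high-latitude North Atlantic
#' (Atlantic sector, 45-66.5 N), subtropical gyres (|lat| < 25) and
#' Southern Ocean (lat <= 45 S). Stations matching none go to "other".
#'
#' @return data frame `name, lat_min, lat_max, lon_min, lon_max, priority`.
#' @export
default_regions <- function() {
  data.frame(
    name = c("nordic_arctic", "hlna", "subtropical_gyres", "southern_ocean"),
    lat_min = c(66.5, 45, -25, -90),
    lat_max = c(90, 66.5, 25, -45),
    lon_min = c(-180, -80, -180, -180),
    lon_max = c(180, 20, 180, 180),
    priority = 1:4,
    stringsAsFactors = FALSE
  )
}

#' Regional summary of a POC partition
#'
#' Assigns each station to the first region (by priority) whose box contains
#' it and averages the partition within regions. The headline aggregate is
#' the unweighted station mean; a POC-flux-weighted mean of the percentages
#' is available with `flux_weighted = TRUE`.
#'
#' @param partition a [partition_poc()] result.
#' @param regions a region table as from [default_regions()].
#' @param flux_weighted weight the percentage means by observed POC flux.
#' @return data frame with one row per region (plus `"other"` and
#'   `"global"`): station count and mean percentages/fluxes.
#' @export
regional_summary <- function(partition, regions = default_regions(),
                             flux_weighted = FALSE) {
  stopifnot(inherits(partition, "ballast_partition"))
  regions <- regions[order(regions$priority), ]
  assign_region <- function(lat, lon) {
    for (r in seq_len(nrow(regions))) {
      if (lat >= regions$lat_min[r] && lat <= regions$lat_max[r] &&
          lon >= regions$lon_min[r] && lon <= regions$lon_max[r]) {
        return(regions$name[r])
      }
    }
    "other"
  }
  region <- mapply(assign_region, partition$lat, partition$lon)
  pct_cols <- c("pct_pic", "pct_bsi", "pct_lith", "pct_nonassoc", "pct_ballasted")
  flux_cols <- c("f_poc", "poc_pic", "poc_bsi", "poc_lith", "poc_nonassoc")
  summarise <- function(idx) {
    if (length(idx) == 0L) {
      return(c(n = 0, stats::setNames(rep(NA_real_, length(c(pct_cols, flux_cols))),
                                      c(pct_cols, flux_cols))))
    }
    sub <- partition[idx, ]
    w <- if (flux_weighted) sub$f_poc else rep(1, nrow(sub))
    pct <- vapply(pct_cols, function(cl)
      stats::weighted.mean(sub[[cl]], w, na.rm = TRUE), numeric(1))
    flx <- vapply(flux_cols, function(cl) mean(sub[[cl]], na.rm = TRUE), numeric(1))
    c(n = length(idx), pct, flx)
  }
  groups <- c(regions$name, "other", "global")
  rows <- lapply(groups, function(g) {
    idx <- if (g == "global") seq_len(nrow(partition)) else which(region == g)
    summarise(idx)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(region = groups, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
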