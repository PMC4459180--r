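# Th-234 based export fluxes.
#
# The Th-234/U-238 pair integrates particle export over the few weeks before
# sampling: U-238 is conservative (scales with salinity) while Th-234 is
# scavenged onto sinking particles, so the upper-ocean deficit of Th-234
# relative to U-238, integrated over depth, balances the downward Th-234 flux
# at steady state. Element fluxes follow from the element:Th ratio of large
# (>53 um) sinking particles.

#' Th-234 decay constant (per day)
#'
#' ln(2) / 24.1 d, from the 24.1-day half-life of Th-234.
#' @export
lambda_th234 <- function() log(2) / 24.1

#' Downward Th-234 flux from an activity profile (1-D steady state)
#'
#' Integrates the Th-234 deficit `A_U - A_Th` from the surface to `z_int` by
#' the trapezoid rule and multiplies by the decay constant:
#' `flux = lambda * integral_0^z_int (A_U - A_Th) dz`, with activities
#' converted from dpm L^-1 to dpm m^-3 (x 1000). If the shallowest
#' measurement is below 0 m the profile is extended to the surface by holding
#' that value constant. The deficit may be negative at some depths (excess
#' Th-234); such intervals subtract from the flux.
#'
#' @param depths depths in m, strictly increasing, >= 0.
#' @param th234 total Th-234 activity at each depth, dpm L^-1.
#' @param u238 U-238 activity at each depth, dpm L^-1 (measured, or via
#'   [u238_from_salinity()]).
#' @param z_int integration depth in m (default 100, the conventional export
#'   horizon for this model).
#' @param lambda Th-234 decay constant, d^-1.
#' @return downward Th-234 flux at `z_int`, dpm m^-2 d^-1.
#' @export
th_flux_steady_state <- function(depths, th234, u238, z_int = 100,
                                 lambda = lambda_th234()) {
  if (z_int <= 0) stop("z_int must be > 0")
  n <- length(depths)
  if (n < 2L || length(th234) != n || length(u238) != n) {
    stop("depths, th234 and u238 must have equal length >= 2")
  }
  if (any(!is.finite(depths)) || is.unsorted(depths, strictly = TRUE) ||
      depths[1] < 0) {
    stop("depths must be finite, non-negative and strictly increasing")
  }
  if (any(!is.finite(th234)) || any(th234 < 0) ||
      any(!is.finite(u238)) || any(u238 < 0)) {
    stop("activities must be finite and >= 0")
  }
  if (depths[n] < z_int) {
    stop("profile reaches only ", depths[n], " m but z_int = ", z_int,
         " m; deepen the profile or reduce z_int")
  }
  deficit <- u238 - th234
  # extend to the surface with the shallowest value
  if (depths[1] > 0) {
    deficit <- c(deficit[1], deficit)
    depths <- c(0, depths)
  }
  # clip the profile at z_int, interpolating the deficit there
  keep <- depths <= z_int
  d_at_z <- stats::approx(depths, deficit, xout = z_int)$y
  depths <- c(depths[keep], if (max(depths[keep]) < z_int) z_int)
  deficit <- c(deficit[keep], if (length(depths) > sum(keep)) d_at_z)
  # trapezoid, dpm L^-1 m -> dpm m^-2 (x 1000)
  integral <- sum(diff(depths) * (utils::head(deficit, -1) + utils::tail(deficit, -1)) / 2)
  lambda * integral * 1000
}

#' U-238 activity from salinity
#'
#' Linear conservative relationship `A_U = slope * S + offset` (dpm L^-1),
#' with coefficients overridable to match any published calibration.
#'
#' @param salinity practical salinity in \[0, 42\].
#' @param slope,offset calibration coefficients (defaults 0.0786 and -0.315).
#' @return U-238 activity, dpm L^-1.
#' @export
u238_from_salinity <- function(salinity, slope = 0.0786, offset = -0.315) {
  if (any(!is.finite(salinity)) || any(salinity < 0) || any(salinity > 42)) {
    stop("salinity must be within [0, 42]")
  }
  slope * salinity + offset
}

#' Element flux from Th-234 flux and a particle element:Th ratio
#'
#' `flux = th_flux * ratio * molar_mass / 1000` converts dpm m^-2 d^-1 times
#' umol dpm^-1 to mg m^-2 d^-1. POC and PIC use the molar mass of carbon
#' (12.011); BSi is reported as mg Si m^-2 d^-1 with 28.086 g mol^-1 (no
#' opal-hydration mass applied).
#'
#' @param th_flux Th-234 flux, dpm m^-2 d^-1, >= 0.
#' @param ratio element:Th-234 ratio of large particles, umol dpm^-1, >= 0.
#' @param molar_mass g mol^-1 of the reported element.
#' @return element flux, mg m^-2 d^-1.
#' @export
element_flux <- function(th_flux, ratio, molar_mass = 12.011) {
  if (any(th_flux < 0) || any(ratio < 0) || any(molar_mass < 0)) {
    stop("element_flux arguments must be >= 0")
  }
  th_flux * ratio * molar_mass * 1e-3
}

#' Aluminium flux from Th-234 flux and a PAl:Th ratio
#'
#' `flux = th_flux * pal_to_th * 26.982e-6` (nmol Al dpm^-1 to mg Al).
#'
#' @param th_flux Th-234 flux, dpm m^-2 d^-1, >= 0.
#' @param pal_to_th particulate-Al : Th-234 ratio, nmol dpm^-1, >= 0.
#' @return Al flux, mg m^-2 d^-1.
#' @export
al_flux_from_pal <- function(th_flux, pal_to_th) {
  if (any(th_flux < 0) || any(pal_to_th < 0)) {
    stop("al_flux_from_pal arguments must be >= 0")
  }
  th_flux * pal_to_th * 26.982e-6
}

#' Lithogenic flux from aluminium flux
#'
#' Lithogenic material is estimated as 100/8 times the Al flux, assuming an
#' 8% Al content of lithogenic particles.
#'
#' @param al_flux Al flux, mg m^-2 d^-1, >= 0.
#' @return lithogenic flux, mg m^-2 d^-1.
#' @export
lithogenic_flux <- function(al_flux) {
  if (any(al_flux < 0)) stop("al_flux must be >= 0")
  (100 / 8) * al_flux
}

#' Literature particulate-Al concentrations (nmol L^-1)
#'
#' Average large-particle Al concentrations used when PAl was not measured:
#' island-plume Southern Ocean stations (chlorophyll plumes of fertilised
#' islands) and non-plume Southern Ocean stations.
#'
#' @return named numeric vector, nmol L^-1.
#' @export
pal_literature_values <- function() {
  c(island_plume = 1.27, non_plume = 0.23)
}

#' Read Th-234 activity profiles
#'
#' Reads the canonical `profiles.csv` schema
#' `station_id,depth_m,th234_dpm_l,u238_dpm_l,salinity`; where `u238_dpm_l`
#' is empty it is derived from salinity.
#'
#' @param path path to the CSV.
#' @param u238_slope,u238_offset coefficients for [u238_from_salinity()].
#' @return data frame with columns `station_id, depth_m, th234_dpm_l,
#'   u238_dpm_l`, ordered by station then depth.
#' @export
read_activity_profiles <- function(path, u238_slope = 0.0786,
                                   u238_offset = -0.315) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("station_id", "depth_m", "th234_dpm_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("profiles file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$u238_dpm_l)) df$u238_dpm_l <- NA_real_
  fill <- is.na(df$u238_dpm_l)
  if (any(fill)) {
    if (is.null(df$salinity) || anyNA(df$salinity[fill])) {
      stop("rows without u238_dpm_l need a salinity to derive it")
    }
    df$u238_dpm_l[fill] <- u238_from_salinity(df$salinity[fill],
                                              u238_slope, u238_offset)
  }
  df <- df[order(df$station_id, df$depth_m), ]
  rownames(df) <- NULL
  df
}

#' Th-234 fluxes for every station in a profile table
#'
#' @param profiles data frame from [read_activity_profiles()].
#' @param z_int integration depth, m.
#' @param lambda decay constant, d^-1.
#' @return data frame `station_id, f_th` (dpm m^-2 d^-1).
#' @export
th_flux_by_station <- function(profiles, z_int = 100, lambda = lambda_th234()) {
  ids <- unique(profiles$station_id)
  f <- vapply(ids, function(id) {
    p <- profiles[profiles$station_id == id, ]
    th_flux_steady_state(p$depth_m, p$th234_dpm_l, p$u238_dpm_l,
                         z_int = z_int, lambda = lambda)
  }, numeric(1))
  data.frame(station_id = ids, f_th = unname(f), stringsAsFactors = FALSE)
}
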