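#' @keywords internal
"_PACKAGE"

# Canonical stations.csv schema. Mandatory columns must be present in the file;
# optional columns may be absent or empty.
.station_cols_mandatory <- c("station_id", "date", "lat", "lon",
                             "f_poc", "f_pic", "f_bsi", "f_lith")
.station_cols_optional <- c("pal", "f_th", "region")
.station_flux_cols <- c("f_poc", "f_pic", "f_bsi", "f_lith", "pal", "f_th")

#' Construct a validated station table
#'
#' A station table holds one row per sampling station: location, date and
#' export fluxes of POC and the three mineral phases (calcite/PIC, biogenic
#' silica/BSi and lithogenic material), all in mg m^-2 d^-1, plus optional
#' particulate-Al concentration (nmol L^-1) and Th-234 flux (dpm m^-2 d^-1).
#' It is the observation unit of both the global and the geographically
#' weighted regression.
#'
#' Longitudes are normalised to (-180, 180]. Fluxes may be missing (NA) but a
#' present value must be finite and non-negative; downstream fits exclude
#' incomplete rows and report them.
#'
#' @param df data frame with at least the mandatory columns
#'   `station_id, date, lat, lon, f_poc, f_pic, f_bsi, f_lith`; optional
#'   `pal, f_th, region`.
#' @param strict if `TRUE` (default) invalid rows are an error; otherwise they
#'   are dropped with a warning and the count recorded in attribute
#'   `n_dropped`.
#' @return a `station_table` (a data frame).
#' @export
station_table <- function(df, strict = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.station_cols_mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("station table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.station_cols_optional, names(df))) {
    df[[col]] <- if (col == "region") NA_character_ else NA_real_
  }
  df <- df[, c(.station_cols_mandatory, .station_cols_optional)]

  df$station_id <- as.character(df$station_id)
  df$date <- as.Date(df$date)
  for (col in c("lat", "lon", .station_flux_cols)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad) > 0L) {
        stop("non-numeric value in column '", col, "' at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  df$region <- as.character(df$region)
  df$lon <- normalize_lon(df$lon)

  problems <- .station_row_problems(df)
  bad_rows <- which(lengths(problems) > 0L)
  if (length(bad_rows) > 0L) {
    msg <- paste(vapply(bad_rows, function(i) {
      paste0("row ", i, " (station_id=", df$station_id[i], "): ",
             paste(problems[[i]], collapse = "; "))
    }, character(1)), collapse = "\n  ")
    if (strict) stop("invalid station record(s):\n  ", msg)
    warning("dropping ", length(bad_rows), " invalid station record(s):\n  ",
            msg, call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("station table has no valid rows")
  if (anyDuplicated(df$station_id)) {
    stop("duplicated station_id: ",
         paste(unique(df$station_id[duplicated(df$station_id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, n_dropped = length(bad_rows),
            class = c("station_table", "data.frame"))
}

# per-row invariant violations, as a list of character vectors
.station_row_problems <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    p <- character(0)
    if (is.na(df$station_id[i]) || !nzchar(df$station_id[i])) {
      p <- c(p, "empty station_id")
    }
    if (is.na(df$lat[i]) || df$lat[i] < -90 || df$lat[i] > 90) {
      p <- c(p, "lat outside [-90, 90]")
    }
    if (is.na(df$lon[i])) p <- c(p, "missing lon")
    for (col in .station_flux_cols) {
      v <- df[[col]][i]
      if (!is.na(v) && (!is.finite(v) || v < 0)) {
        p <- c(p, paste0(col, " negative or non-finite"))
      }
    }
    p
  })
}

#' Normalise longitudes to (-180, 180]
#'
#' @param lon numeric vector of longitudes in degrees east.
#' @return numeric vector in (-180, 180].
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[!is.na(out) & out == -180] <- 180
  out
}

#' Read a station flux table from CSV
#'
#' The file must be comma-separated UTF-8 with a single header row containing
#' the canonical column names
#' `station_id,date,lat,lon,f_poc,f_pic,f_bsi,f_lith[,pal,f_th,region]`,
#' "." as the decimal mark and ISO-8601 dates. Empty cells encode missing
#' optional values.
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE`, any row violating an invariant is an error naming
#'   the row; if `FALSE`, offending rows are dropped with a warning and the
#'   count stored in attribute `n_dropped`.
#' @return a [station_table()].
#' @examples
#' path <- system.file("extdata", "stations_synthetic_example.csv",
#'                     package = "ballastgwr")
#' read_station_table(path)
#' @export
read_station_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  station_table(df, strict = strict)
}

#' Write a station table to CSV
#'
#' Numeric fields are written with 15 significant digits so that a write/read
#' cycle reproduces the table; missing optional values become empty cells.
#'
#' @param table a [station_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(table, path) {
  stopifnot(inherits(table, "station_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty station table")
  out <- as.data.frame(table)
  for (col in c("lat", "lon", .station_flux_cols)) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         trimws(formatC(out[[col]], digits = 15, format = "g")))
  }
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.station_table <- function(x, ...) {
  cat("Station flux table: ", nrow(x), " stations, lat ",
      sprintf("%.1f", min(x$lat)), " to ", sprintf("%.1f", max(x$lat)),
      "\n", sep = "")
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) cat("  (", nd, " invalid rows dropped on read)\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ... and ", nrow(x) - 5L, " more rows\n", sep = "")
  invisible(x)
}

# rows usable in the regression: all four fluxes present
complete_flux_rows <- function(table) {
  which(stats::complete.cases(table[, c("f_poc", "f_pic", "f_bsi", "f_lith")]))
}
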