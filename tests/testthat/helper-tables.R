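# Small fixture builders shared by the tests. Everything is generated in
# code; no data files.

# a tiny hand-written valid station table
tiny_table <- function(n = 3L) {
  station_table(data.frame(
    station_id = paste0("T", seq_len(n)),
    date = as.Date("2013-05-01") + seq_len(n),
    lat = seq(50, 60, length.out = n),
    lon = seq(-30, -20, length.out = n),
    f_poc = 100 + seq_len(n),
    f_pic = 10 * seq_len(n),
    f_bsi = 20 + seq_len(n),
    f_lith = seq_len(n),
    stringsAsFactors = FALSE
  ))
}

# random scattered table with known linear truth (constant coefficients)
random_table <- function(n, seed, coefs = c(a = 0.3, b = 0.2, c = 0.1, d = 50),
                         noise_sd = 0) {
  set.seed(seed)
  lat <- runif(n, -60, 70)
  lon <- runif(n, -170, 170)
  f_pic <- rlnorm(n, log(20), 0.8)
  f_bsi <- rlnorm(n, log(30), 0.9)
  f_lith <- rlnorm(n, log(4), 1.0)
  f_poc <- coefs["a"] * f_pic + coefs["b"] * f_bsi + coefs["c"] * f_lith +
    coefs["d"] + rnorm(n, 0, noise_sd)
  f_poc <- pmax(f_poc, 0)
  station_table(data.frame(
    station_id = sprintf("R%03d", seq_len(n)),
    date = as.Date("2013-01-01") + seq_len(n),
    lat = lat, lon = lon, f_poc = f_poc, f_pic = f_pic, f_bsi = f_bsi,
    f_lith = f_lith, stringsAsFactors = FALSE
  ))
}

# two-basin synthetic config with configurable coefficient fields
two_basin_config <- function(n, seed, fields, noise_sd = 30,
                             logmeans = c(pic = log(30), bsi = log(25),
                                          lith = log(3))) {
  n1 <- floor(n / 2)
  boxes <- data.frame(lat_min = c(-60, 20), lat_max = c(-20, 60),
                      lon_min = c(-40, -40), lon_max = c(10, 10),
                      n = c(n1, n - n1))
  synthetic_config(n, boxes, fields, logmeans,
                   c(pic = 0.9, bsi = 1.0, lith = 1.2), noise_sd, seed)
}

constant_fields <- function(a = 0.3, b = 0.2, c = 0.1, d = 50) {
  list(a = field_constant(a), b = field_constant(b), c = field_constant(c),
       d = field_constant(d))
}

# independent brute-force Moran's I (double loop) for the oracle tests
morans_i_bruteforce <- function(values, lat, lon, bin) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; W <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- great_circle_distance(lat[i], lon[i], lat[j], lon[j])
      if (d >= bin[1] && d < bin[2]) {
        num <- num + z[i] * z[j]
        W <- W + 1
      }
    }
  }
  (n / W) * num / sum(z^2)
}
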