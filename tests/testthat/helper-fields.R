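# Builders for small in-memory fixtures used across the suite.

make_field <- function(values, time = NULL, lat = NULL, lon = NULL,
                       name = "sst", units = "degC") {
  d <- dim(values)
  if (is.null(time)) time <- as.Date("2007-06-01") + seq_len(d[1]) - 1
  if (is.null(lat)) lat <- seq(10, by = 0.25, length.out = d[2])
  if (is.null(lon)) lon <- seq(108, by = 0.25, length.out = d[3])
  gridded_field(name, values, time, lat, lon, units)
}

rand_field <- function(nt = 5, nlat = 4, nlon = 6, seed = 1, ...) {
  set.seed(seed)
  make_field(array(rnorm(nt * nlat * nlon), dim = c(nt, nlat, nlon)), ...)
}

# stress field straight from component arrays (bypasses the bulk formula)
stress_from_arrays <- function(tx, ty, time = NULL, lat, lon) {
  if (is.null(time)) time <- as.Date("2007-06-01") + seq_len(dim(tx)[1]) - 1
  structure(list(
    tau_x = gridded_field("tau_x", tx, time, lat, lon, "N m-2"),
    tau_y = gridded_field("tau_y", ty, time, lat, lon, "N m-2")
  ), class = "stress_field")
}

# tau_y = tau0 * sin(2 pi x / L), tau_x = const, with x the zonal distance
# R cos(phi) * (lambda - lambda0); returns the stress and the analytic curl
sinusoid_stress <- function(tau0 = 0.1, L = 5e5, taux = 0,
                            lat = seq(10, 14, by = 0.125),
                            lon = seq(106, 116, by = 0.125),
                            const = physical_constants()) {
  lam <- (lon - lon[1]) * pi / 180
  phi <- lat * pi / 180
  x <- outer(cos(phi), lam) * const$earth_radius     # lat x lon, metres
  ty <- tau0 * sin(2 * pi * x / L)
  curl_true <- (2 * pi * tau0 / L) * cos(2 * pi * x / L)
  nt <- 1L
  arr <- function(m) array(rep(m, each = nt), dim = c(nt, nrow(m), ncol(m)))
  list(stress = stress_from_arrays(arr(ty * 0 + taux), arr(ty),
                                   lat = lat, lon = lon),
       curl_true = arr(curl_true),
       lat = lat, lon = lon)
}

# small fast synthetic configuration for unit tests
small_config <- function(...) {
  synthetic_config(resolution = 0.5, lat_range = c(8, 18),
                   lon_range = c(106, 114), ...)
}
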