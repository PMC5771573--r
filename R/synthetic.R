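#' Configuration of the synthetic monsoon/bloom field generator
#'
#' Describes a summer-monsoon scenario on a regular grid: a southwesterly
#' background wind shaped into a coast-parallel jet (so both the stress curl
#' and the coast-parallel stress are nonzero), an abrupt late-July wind
#' intensification with a smooth half-cosine ramp, deterministic
#' intraseasonal modulation of wind bearing and jet position, an SST field
#' cooled by the running 15-day integral of the Ekman pumping it induces, a
#' chlorophyll-a field responding linearly (with a configurable lag and
#' floor) to Ekman pumping and transport, Gaussian observation noise, a
#' land mask northwest of an idealized coastline, and i.i.d. cloud masking
#' of chlorophyll. Identical seeds give bit-identical output.
#'
#' @param lon_range,lat_range domain extent, degrees (default 106-116E,
#'   8-22N).
#' @param resolution grid spacing, degrees (default 0.125).
#' @param years season years (default 2007, the case-study summer).
#' @param season_start,season_end season window, `"mm-dd"`.
#' @param wind_background background wind speed, m s-1.
#' @param wind_bearing mean wind bearing, degrees clockwise from north.
#' @param event_start `"mm-dd"` date the intensification begins.
#' @param event_amplitude added wind speed at full ramp, m s-1 (0 disables
#'   the event).
#' @param event_ramp_days half-cosine ramp length, days.
#' @param coast_lon,coast_lat a point on the idealized coastline.
#' @param coast_angle coastline tangent bearing, degrees clockwise from
#'   north; cells on the landward (northwest) side are masked as land.
#' @param jet_center_km,jet_width_km offshore distance and Gaussian width of
#'   the wind-jet axis, km.
#' @param jet_base,jet_amplitude dimensionless jet shape: wind speed is
#'   multiplied by `base + amplitude * exp(-((d - center)/width)^2)`.
#' @param dir_wobble_deg,dir_period_days sinusoidal bearing modulation
#'   (intraseasonal, MJO-like), degrees / days.
#' @param jet_wander_km,jet_period_days sinusoidal modulation of the jet
#'   axis position, km / days.
#' @param sst_base base sea surface temperature, degC.
#' @param sst_gain SST response, degC per metre of 15-day-integrated Ekman
#'   pumping (negative: upwelling cools).
#' @param sst_window_days integration window for the SST response, days.
#' @param chl_base background chlorophyll-a, mg m-3.
#' @param chl_gain_epv,chl_gain_et chlorophyll response gains, mg m-3 per
#'   (m s-1) of EPV and per (m2 s-1) of ET.
#' @param chl_lag chlorophyll response lag, days (>= 0).
#' @param chl_floor lower bound applied to chlorophyll, mg m-3.
#' @param lognormal_chl apply the noise multiplicatively on the log scale
#'   instead of additively (off by default; keeps correlation truth linear).
#' @param noise_wind,noise_sst,noise_chl Gaussian observation noise standard
#'   deviations (m s-1 per component, degC, mg m-3).
#' @param cloud_fraction probability that a chlorophyll cell-day is masked,
#'   in `[0, 1)`.
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(lon_range = c(106, 116), lat_range = c(8, 22),
                             resolution = 0.125,
                             years = 2007,
                             season_start = "06-01", season_end = "08-31",
                             wind_background = 6, wind_bearing = 40,
                             event_start = "07-25", event_amplitude = 4,
                             event_ramp_days = 10,
                             coast_lon = 108.5, coast_lat = 11.5,
                             coast_angle = 35,
                             jet_center_km = 350, jet_width_km = 200,
                             jet_base = 0.6, jet_amplitude = 0.8,
                             dir_wobble_deg = 8, dir_period_days = 30,
                             jet_wander_km = 60, jet_period_days = 45,
                             sst_base = 29.5, sst_gain = -0.05,
                             sst_window_days = 15,
                             chl_base = 0.1, chl_gain_epv = 1e4,
                             chl_gain_et = 0.01, chl_lag = 3,
                             chl_floor = 0.01, lognormal_chl = FALSE,
                             noise_wind = 1.0, noise_sst = 0.2,
                             noise_chl = 0.03, cloud_fraction = 0.2,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    length(cfg$lon_range) == 2L, length(cfg$lat_range) == 2L,
    cfg$resolution > 0, length(cfg$years) >= 1L,
    is.finite(cfg$chl_gain_epv), is.finite(cfg$chl_gain_et),
    is.finite(cfg$sst_gain), cfg$chl_lag >= 0,
    cfg$cloud_fraction >= 0, cfg$cloud_fraction < 1,
    cfg$noise_wind >= 0, cfg$noise_sst >= 0, cfg$noise_chl >= 0,
    cfg$event_ramp_days > 0, cfg$jet_width_km > 0
  )
  cfg$years <- as.integer(cfg$years)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "synthetic_config")
}

# season dates for every configured year
.season_dates <- function(config) {
  do.call(c, lapply(config$years, function(y) {
    seq(as.Date(sprintf("%d-%s", y, config$season_start)),
        as.Date(sprintf("%d-%s", y, config$season_end)), by = "day")
  }))
}

.KM_PER_DEG <- 6371 * pi / 180  # great-circle km per degree

# signed offshore distance (km) from the idealized coastline; negative = land
.cross_shore_km <- function(lat, lon, config) {
  th <- config$coast_angle * pi / 180
  latm <- matrix(rep(lat, times = length(lon)), nrow = length(lat))
  lonm <- matrix(rep(lon, each = length(lat)), nrow = length(lat))
  x <- (lonm - config$coast_lon) * .KM_PER_DEG * cos(latm * pi / 180)
  y <- (latm - config$coast_lat) * .KM_PER_DEG
  x * cos(th) - y * sin(th)
}

# half-cosine ramp of the wind intensification, per date
.event_speed <- function(dates, config) {
  yr <- as.integer(format(dates, "%Y"))
  t0 <- as.Date(sprintf("%d-%s", yr, config$event_start))
  frac <- pmin(pmax(as.numeric(dates - t0) / config$event_ramp_days, 0), 1)
  config$event_amplitude * 0.5 * (1 - cos(pi * frac))
}

# noise-free wind skeleton: closed-form background + event + intraseasonal
# modulation; returns arrays plus the land mask
.wind_skeleton <- function(config) {
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$resolution)
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$resolution)
  time <- .season_dates(config)
  nt <- length(time); nlat <- length(lat); nlon <- length(lon)

  d <- .cross_shore_km(lat, lon, config)       # lat x lon
  land <- d < 0
  dsea <- as.vector(d)

  # day-of-season index within each year, for the intraseasonal sinusoids
  yr <- as.integer(format(time, "%Y"))
  season0 <- as.Date(sprintf("%d-%s", yr, config$season_start))
  tday <- as.numeric(time - season0)

  speed_t <- config$wind_background + .event_speed(time, config)
  bearing_t <- (config$wind_bearing +
    config$dir_wobble_deg * sin(2 * pi * tday / config$dir_period_days)) *
    pi / 180
  center_t <- config$jet_center_km +
    config$jet_wander_km * sin(2 * pi * tday / config$jet_period_days + pi / 3)

  u0 <- array(NA_real_, dim = c(nt, nlat, nlon))
  v0 <- array(NA_real_, dim = c(nt, nlat, nlon))
  landv <- as.vector(land)
  for (t in seq_len(nt)) {
    shape <- config$jet_base +
      config$jet_amplitude * exp(-((dsea - center_t[t]) / config$jet_width_km)^2)
    spd <- speed_t[t] * shape
    spd[landv] <- NA_real_
    u0[t, , ] <- spd * sin(bearing_t[t])
    v0[t, , ] <- spd * cos(bearing_t[t])
  }
  list(u0 = u0, v0 = v0, time = time, lat = lat, lon = lon, land = land)
}

#' Generate the synthetic monsoon wind
#'
#' The noise-free skeleton (background + intensification event + coastal jet
#' + intraseasonal modulation) plus per-component Gaussian noise. With
#' `noise_wind = 0` the output equals the closed-form skeleton exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with [gridded_field()]s `u10`, `v10` (m s-1).
#' @export
generate_monsoon_wind <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sk <- .wind_skeleton(config)
  n <- length(sk$u0)
  u <- sk$u0 + array(stats::rnorm(n, 0, config$noise_wind), dim = dim(sk$u0))
  v <- sk$v0 + array(stats::rnorm(n, 0, config$noise_wind), dim = dim(sk$v0))
  list(u10 = gridded_field("u10", u, sk$time, sk$lat, sk$lon, "m s-1"),
       v10 = gridded_field("v10", v, sk$time, sk$lat, sk$lon, "m s-1"))
}

# running backward sum over `win` days, restarted each year; m is time x cell
.running_window_sum <- function(m, time, win) {
  out <- m * NA_real_
  for (y in unique(format(time, "%Y"))) {
    rows <- which(format(time, "%Y") == y)
    cs <- apply(m[rows, , drop = FALSE], 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = length(rows))
    lagd <- rbind(matrix(0, min(win, length(rows)), ncol(m)),
                  cs[seq_len(max(length(rows) - win, 0)), , drop = FALSE])
    out[rows, ] <- cs - lagd
  }
  out
}

# shift rows back by `lag` days within each year, holding the first value
.lag_within_year <- function(m, time, lag) {
  if (lag == 0) return(m)
  out <- m
  for (y in unique(format(time, "%Y"))) {
    rows <- which(format(time, "%Y") == y)
    src <- pmax(seq_along(rows) - lag, 1L)
    out[rows, ] <- m[rows[src], , drop = FALSE]
  }
  out
}

#' Generate coupled synthetic wind, SST and chlorophyll fields
#'
#' Encodes the causal chain the analysis is designed to detect: the
#' noise-free wind drives Ekman pumping (EPV) and offshore Ekman transport
#' (ET) through [wind_stress()], [ekman_pumping()] and [ekman_transport()];
#' SST is a constant base plus `sst_gain` times the running 15-day integral
#' of EPV (upwelling cools cumulatively); chlorophyll-a is a base plus
#' linear responses to EPV and ET lagged by `chl_lag` days, floored at
#' `chl_floor`. Observation noise is then added (winds, SST, Chl-a) and
#' chlorophyll cell-days are cloud-masked i.i.d. with probability
#' `cloud_fraction`. The returned `truth` holds the noise-free forcing and
#' responses together with the configured gains and lag.
#'
#' @param config a [synthetic_config()].
#' @param const a [physical_constants()].
#' @return list with [gridded_field()]s `u10`, `v10`, `sst`, `chl` and a
#'   `truth` list (`epv`, `et`, `sst`, `chl` noise-free fields; `gains`,
#'   `lag`, `config`).
#' @export
generate_coupled_fields <- function(config = synthetic_config(),
                                    const = physical_constants()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sk <- .wind_skeleton(config)
  nt <- length(sk$time)
  dims <- dim(sk$u0)
  n <- length(sk$u0)
  ncell <- prod(dims[2:3])

  # fixed draw order so paired configs (e.g. event vs no event) share noise
  noise_u <- stats::rnorm(n, 0, config$noise_wind)
  noise_v <- stats::rnorm(n, 0, config$noise_wind)
  noise_sst <- stats::rnorm(n, 0, config$noise_sst)
  noise_chl <- stats::rnorm(n, 0, config$noise_chl)
  cloud <- stats::runif(n) < config$cloud_fraction

  u0f <- gridded_field("u10", sk$u0, sk$time, sk$lat, sk$lon, "m s-1")
  v0f <- gridded_field("v10", sk$v0, sk$time, sk$lat, sk$lon, "m s-1")
  stress0 <- wind_stress(u0f, v0f, const)
  epv0 <- ekman_pumping(stress0, const)
  et0 <- ekman_transport(stress0, coastline_spec(config$coast_angle), const)

  epv_m <- matrix(epv0$values, nrow = nt)
  et_m <- matrix(et0$values, nrow = nt)

  upw <- .running_window_sum(epv_m * 86400, sk$time, config$sst_window_days)
  sst0 <- config$sst_base + config$sst_gain * upw
  chl0 <- config$chl_base +
    config$chl_gain_epv * .lag_within_year(epv_m, sk$time, config$chl_lag) +
    config$chl_gain_et * .lag_within_year(et_m, sk$time, config$chl_lag)
  chl0 <- pmax(chl0, config$chl_floor)

  u <- sk$u0 + array(noise_u, dims)
  v <- sk$v0 + array(noise_v, dims)
  sst <- array(sst0, dims) + array(noise_sst, dims)
  if (config$lognormal_chl) {
    # noise_chl is the log-scale sd in this mode (multiplicative noise)
    chl <- array(chl0, dims) * exp(array(noise_chl, dims))
  } else {
    chl <- array(chl0, dims) + array(noise_chl, dims)
  }
  chl <- pmax(chl, config$chl_floor)
  chl[array(cloud, dims)] <- NA_real_

  truth <- list(
    epv = epv0, et = et0,
    sst = gridded_field("sst", array(sst0, dims), sk$time, sk$lat, sk$lon,
                        "degC"),
    chl = gridded_field("chl", array(chl0, dims), sk$time, sk$lat, sk$lon,
                        "mg m-3"),
    gains = list(sst_gain = config$sst_gain,
                 chl_gain_epv = config$chl_gain_epv,
                 chl_gain_et = config$chl_gain_et),
    lag = config$chl_lag,
    config = config
  )
  list(u10 = gridded_field("u10", u, sk$time, sk$lat, sk$lon, "m s-1"),
       v10 = gridded_field("v10", v, sk$time, sk$lat, sk$lon, "m s-1"),
       sst = gridded_field("sst", sst, sk$time, sk$lat, sk$lon, "degC"),
       chl = gridded_field("chl", chl, sk$time, sk$lat, sk$lon, "mg m-3"),
       truth = truth)
}

#' Write a synthetic fixture set to disk
#'
#' One CF-style NetCDF file per variable plus a ground-truth JSON (gains,
#' lag, noise levels, config) and a manifest JSON listing the files and the
#' config hash.
#'
#' @param config a [synthetic_config()].
#' @param out_dir writable output directory (created if needed).
#' @return the manifest, invisibly (list with `files`, `config_hash`).
#' @export
write_fixture_set <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  fields <- generate_coupled_fields(config)
  files <- character(0)
  for (nm in c("u10", "v10", "sst", "chl")) {
    p <- file.path(out_dir, paste0(nm, ".nc"))
    write_gridded(fields[[nm]], p)
    files[nm] <- p
  }
  hash <- rlang::hash(unclass(config))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(gains = fields$truth$gains, lag = fields$truth$lag,
         noise = list(wind = config$noise_wind, sst = config$noise_sst,
                      chl = config$noise_chl),
         cloud_fraction = config$cloud_fraction,
         config = unclass(config), config_hash = hash),
    truth_path, auto_unbox = TRUE, digits = NA)
  files["truth"] <- truth_path
  manifest <- list(files = as.list(files), config_hash = hash)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
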