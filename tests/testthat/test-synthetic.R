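test_that("identical seeds give bit-identical fields", {
  cfg <- small_config(seed = 42)
  a <- generate_coupled_fields(cfg)
  b <- generate_coupled_fields(cfg)
  for (nm in c("u10", "v10", "sst", "chl")) {
    expect_identical(a[[nm]]$values, b[[nm]]$values, info = nm)
  }
  expect_identical(a$truth$epv$values, b$truth$epv$values)
})

test_that("zero noise reduces the wind to its closed-form skeleton", {
  cfg <- small_config(noise_wind = 0, dir_wobble_deg = 0, jet_wander_km = 0,
                      seed = 3)
  w <- generate_monsoon_wind(cfg)
  # closed form: (background + event ramp) * jet shape, along a fixed bearing
  day <- as.numeric(w$u10$time - as.Date("2007-06-01"))
  t0 <- as.numeric(as.Date("2007-07-25") - as.Date("2007-06-01"))
  frac <- pmin(pmax((day - t0) / cfg$event_ramp_days, 0), 1)
  speed_t <- cfg$wind_background +
    cfg$event_amplitude * 0.5 * (1 - cos(pi * frac))
  km <- 6371 * pi / 180
  th <- cfg$coast_angle * pi / 180
  for (pick in list(c(5, 10, 12), c(80, 3, 7))) {
    t <- pick[1]; i <- pick[2]; j <- pick[3]
    x <- (w$u10$lon[j] - cfg$coast_lon) * km * cos(w$u10$lat[i] * pi / 180)
    y <- (w$u10$lat[i] - cfg$coast_lat) * km
    d <- x * cos(th) - y * sin(th)
    if (d < 0) { expect_true(is.na(w$u10$values[t, i, j])); next }
    shape <- cfg$jet_base +
      cfg$jet_amplitude * exp(-((d - cfg$jet_center_km) / cfg$jet_width_km)^2)
    b <- cfg$wind_bearing * pi / 180
    expect_equal(w$u10$values[t, i, j], speed_t[t] * shape * sin(b),
                 tolerance = 1e-12)
    expect_equal(w$v10$values[t, i, j], speed_t[t] * shape * cos(b),
                 tolerance = 1e-12)
  }
})

test_that("without an event the wind is stationary across the season", {
  # mean |U| of first vs second season half differs by less than a
  # noise-driven bound across seeds
  diffs <- vapply(1:20, function(s) {
    cfg <- small_config(event_amplitude = 0, seed = s)
    w <- generate_monsoon_wind(cfg)
    spd <- sqrt(w$u10$values^2 + w$v10$values^2)
    nt <- dim(spd)[1]
    h1 <- mean(spd[1:(nt %/% 2), , ], na.rm = TRUE)
    h2 <- mean(spd[(nt %/% 2 + 1):nt, , ], na.rm = TRUE)
    h2 - h1
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)  # << event amplitude (4 m/s)
  cfg <- small_config(event_amplitude = 4, seed = 1)
  w <- generate_monsoon_wind(cfg)
  spd <- sqrt(w$u10$values^2 + w$v10$values^2)
  nt <- dim(spd)[1]
  jump <- mean(spd[(nt %/% 2 + 1):nt, , ], na.rm = TRUE) -
    mean(spd[1:(nt %/% 2), , ], na.rm = TRUE)
  expect_gt(jump, 10 * abs(mean(diffs)))
})

test_that("null coupling leaves SST and chlorophyll uncorrelated with forcing", {
  cfg <- small_config(sst_gain = 0, chl_gain_epv = 0, chl_gain_et = 0,
                      cloud_fraction = 0, seed = 11)
  g <- generate_coupled_fields(cfg)
  box <- region_box(109.3, 113, 10.8, 13.8)
  epv <- ekman_pumping(wind_stress(g$u10, g$v10))
  s_epv <- area_mean_series(epv, box)$value
  s_chl <- area_mean_series(g$chl, box)$value
  s_sst <- area_mean_series(g$sst, box)$value
  n <- sum(complete.cases(cbind(s_epv, s_chl)))
  expect_lt(abs(cor(s_epv, s_chl, use = "complete.obs")), 2 / sqrt(n) + 0.1)
  expect_lt(abs(cor(s_epv, s_sst, use = "complete.obs")), 2 / sqrt(n) + 0.1)
})

test_that("noise-free truth: SST minimum trails the EPV maximum", {
  cfg <- small_config(noise_wind = 0, noise_sst = 0, noise_chl = 0,
                      cloud_fraction = 0, seed = 2)
  g <- generate_coupled_fields(cfg)
  box <- region_box(109.3, 113, 10.8, 13.8)
  epv <- area_mean_series(g$truth$epv, box)$value
  sst <- area_mean_series(g$truth$sst, box)$value
  t_epv_max <- which.max(epv)
  t_sst_min <- which.min(sst)
  t_event <- as.numeric(as.Date("2007-07-25") - as.Date("2007-06-01")) + 1
  expect_gte(t_sst_min, t_epv_max)   # cumulative response lags the forcing
  expect_gte(t_sst_min, t_event)     # never before the event start
})

test_that("truth chlorophyll tracks EPV at exactly the configured lag", {
  cfg <- small_config(noise_wind = 0, noise_sst = 0, noise_chl = 0,
                      cloud_fraction = 0, chl_lag = 5, chl_gain_et = 0,
                      chl_gain_epv = 1e4, seed = 2)
  g <- generate_coupled_fields(cfg)
  # inspect the strongest-upwelling cell, where the chlorophyll floor never
  # binds and the response is exactly linear in the lagged forcing
  epv_t <- subset_region(g$truth$epv, region_box(109.3, 113, 10.8, 13.8))
  chl_t <- subset_region(g$truth$chl, region_box(109.3, 113, 10.8, 13.8))
  mu <- colMeans(matrix(epv_t$values, nrow = dim(epv_t$values)[1]))
  cell <- which.max(mu)
  epv <- matrix(epv_t$values, nrow = dim(epv_t$values)[1])[, cell]
  chl <- matrix(chl_t$values, nrow = dim(chl_t$values)[1])[, cell]
  nt <- length(epv)
  lags <- 0:10
  cc <- vapply(lags, function(L) {
    idx <- (L + 6):nt  # skip the padded start-of-season samples
    cor(chl[idx], epv[idx - L])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 5)
  expect_gt(max(cc), 0.999)  # exact linear response at the right lag
})

test_that("realized cloud mask fraction matches the configured probability", {
  cfg <- small_config(cloud_fraction = 0.3, seed = 13)
  g <- generate_coupled_fields(cfg)
  # count over ocean cells only (land is masked regardless of clouds)
  ocean <- !is.na(g$sst$values)
  frac <- mean(is.na(g$chl$values[ocean]))
  expect_lt(abs(frac - 0.3), 0.02)
})

test_that("fixture sets round-trip through NetCDF with stable config hashes", {
  cfg <- synthetic_config(resolution = 1, lat_range = c(9, 15),
                          lon_range = c(107, 113), seed = 5)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  m1 <- write_fixture_set(cfg, d1)
  m2 <- write_fixture_set(cfg, d2)
  expect_identical(m1$config_hash, m2$config_hash)

  g <- generate_coupled_fields(cfg)
  for (nm in c("u10", "sst", "chl")) {
    f <- read_gridded(m1$files[[nm]], nm)
    expect_identical(f$values, g[[nm]]$values, info = nm)
    expect_identical(f$units, g[[nm]]$units, info = nm)
  }
  truth <- jsonlite::read_json(m1$files$truth)
  expect_equal(truth$gains$chl_gain_epv, cfg$chl_gain_epv)
  unlink(c(d1, d2), recursive = TRUE)
})
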