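test_that("bulk formula reproduces the hand-evaluated stress and calm limit", {
  lat <- c(10, 11); lon <- c(108, 109)
  mk <- function(u) make_field(array(u, dim = c(1, 2, 2)), lat = lat, lon = lon,
                               name = "u10", units = "m s-1")
  calm <- wind_stress(mk(0), mk(0))
  expect_true(all(calm$tau_x$values == 0) && all(calm$tau_y$values == 0))

  # u = 10, v = 0: tau_x = 1.225 * 1.3e-3 * 10 * 10
  s <- wind_stress(mk(10), mk(0))
  expect_equal(s$tau_x$values[1, 1, 1], 1.225 * 1.3e-3 * 100, tolerance = 1e-12)
  expect_equal(round(s$tau_x$values[1, 1, 1], 3), 0.159)
  expect_true(all(s$tau_y$values == 0))

  # stress is odd under wind reversal
  s2 <- wind_stress(mk(-10), mk(0))
  expect_equal(s2$tau_x$values, -s$tau_x$values)

  expect_error(wind_stress(mk(1), rand_field(nt = 2, nlat = 2, nlon = 2)),
               "share")
})

test_that("curl of uniform stress vanishes in the interior and edges are masked", {
  lat <- seq(10, 12, by = 0.25); lon <- seq(108, 110, by = 0.25)
  d <- c(2, length(lat), length(lon))
  st <- stress_from_arrays(array(0.1, d), array(0.05, d), lat = lat, lon = lon)
  curl <- stress_curl(st)
  inner <- curl$values[, 2:(d[2] - 1), 2:(d[3] - 1)]
  expect_equal(max(abs(inner)), 0, tolerance = 1e-20)
  expect_true(all(is.na(curl$values[, 1, ])))  # default edge masking
  curl2 <- stress_curl(st, edge = "one_sided")
  expect_equal(max(abs(curl2$values)), 0, tolerance = 1e-20)
})

test_that("finite-difference curl matches the analytic sinusoid within 1%", {
  sin_case <- sinusoid_stress(tau0 = 0.1, L = 5e5)
  curl <- stress_curl(sin_case$stress)
  ok <- !is.na(curl$values)
  err <- curl$values[ok] - sin_case$curl_true[ok]
  rel_rms <- sqrt(mean(err^2)) / sqrt(mean(sin_case$curl_true[ok]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("solid-body stress on a tangent plane has curl approximately 2c", {
  const <- physical_constants()
  lat <- seq(1.5, 2.5, by = 0.05); lon <- seq(110, 111, by = 0.05)
  cc <- 1e-6
  phi0 <- mean(lat) * pi / 180; lam0 <- mean(lon) * pi / 180
  y <- const$earth_radius * (lat * pi / 180 - phi0)
  x <- const$earth_radius * cos(phi0) * (lon * pi / 180 - lam0)
  tx <- array(rep(outer(-cc * y, rep(1, length(lon))), each = 1),
              dim = c(1, length(lat), length(lon)))
  ty <- array(rep(outer(rep(1, length(lat)), cc * x), each = 1),
              dim = c(1, length(lat), length(lon)))
  st <- stress_from_arrays(tx, ty, lat = lat, lon = lon)
  curl <- stress_curl(st)
  expect_equal(mean(curl$values, na.rm = TRUE), 2 * cc, tolerance = 0.01)
})

test_that("curl of an exactly curl-free stress shrinks like O(dx^2) under refinement", {
  # tau_x = A k phi cos(k lambda), tau_y = A cos(phi) sin(k lambda) satisfies
  # d(tau_y)/dx = d(tau_x)/dy exactly under the spherical-metric operator, so
  # any finite-difference output is pure truncation error
  A <- 0.1; k <- 60
  mk <- function(step) {
    lat <- seq(10, 12, by = step); lon <- seq(108, 110, by = step)
    phi <- lat * pi / 180; lam <- lon * pi / 180
    tx <- outer(A * k * phi, cos(k * lam))
    ty <- outer(A * cos(phi), sin(k * lam))
    arr <- function(m) array(rep(m, each = 1), dim = c(1, dim(m)))
    curl <- stress_curl(stress_from_arrays(arr(tx), arr(ty),
                                           lat = lat, lon = lon))
    max(abs(curl$values), na.rm = TRUE)
  }
  e1 <- mk(0.25); e2 <- mk(0.125)
  expect_lt(e2, e1)               # refinement reduces the residual curl
  expect_lt(e2 / e1, 0.3)         # ~0.25 for a second-order scheme
})

test_that("Ekman pumping matches hand-evaluated beta term and analytic oracle", {
  const <- physical_constants()
  # uniform stress -> zero curl -> EPV 0 without beta
  lat <- seq(11, 13, by = 0.25); lon <- seq(108, 110, by = 0.25)
  d <- c(1, length(lat), length(lon))
  st <- stress_from_arrays(array(0.1, d), array(0, d), lat = lat, lon = lon)
  epv0 <- ekman_pumping(st, const, include_beta = FALSE)
  expect_equal(max(abs(epv0$values), na.rm = TRUE), 0, tolerance = 1e-20)

  # with beta: EPV = beta tau_x / (rho f^2) evaluated at 12N
  epvb <- ekman_pumping(st, const, include_beta = TRUE)
  i12 <- which(abs(lat - 12) < 1e-9)
  f12 <- 2 * const$omega_earth * sin(12 * pi / 180)
  b12 <- 2 * const$omega_earth * cos(12 * pi / 180) / const$earth_radius
  want <- b12 * 0.1 / (const$rho_water * f12^2)
  expect_equal(epvb$values[1, i12, 3], want, tolerance = 1e-12)
  expect_equal(want, 2.4e-6, tolerance = 0.02)        # ~0.21 m/day
  expect_equal(want * 86400, 0.21, tolerance = 0.03)

  # sinusoidal stress: EPV = analytic curl / (rho f) within 1%
  sin_case <- sinusoid_stress(tau0 = 0.1, L = 5e5)
  epv <- ekman_pumping(sin_case$stress, const)
  f <- 2 * const$omega_earth * sin(sin_case$lat * pi / 180)
  want_epv <- sweep(sin_case$curl_true, 2, const$rho_water * f, `/`)
  ok <- !is.na(epv$values)
  rel <- sqrt(mean((epv$values[ok] - want_epv[ok])^2)) /
    sqrt(mean(want_epv[ok]^2))
  expect_lt(rel, 0.01)
})

test_that("Ekman transport reproduces the hand-evaluated projection cases", {
  const <- physical_constants()
  lat <- c(11.75, 12, 12.25); lon <- c(108, 108.25, 108.5)
  d <- c(1, 3, 3)
  f12 <- 2 * const$omega_earth * sin(12 * pi / 180)

  # wind stress exactly perpendicular to the coast: tau_c = 0 -> ET = 0
  # coast bearing 0 (due north): perpendicular stress is purely zonal
  st_perp <- stress_from_arrays(array(0.1, d), array(0, d), lat = lat, lon = lon)
  et0 <- ekman_transport(st_perp, coastline_spec(0), const)
  expect_equal(max(abs(et0$values)), 0, tolerance = 1e-20)

  # tau_c = 0.1 at 12N: ET = 0.1 / (rho f) ~ 3.2 m2/s
  st_par <- stress_from_arrays(array(0, d), array(0.1, d), lat = lat, lon = lon)
  et1 <- ekman_transport(st_par, coastline_spec(0), const)
  expect_equal(et1$values[1, 2, 2], 0.1 / (const$rho_water * f12),
               tolerance = 1e-12)
  expect_equal(et1$values[1, 2, 2], 3.2, tolerance = 0.01)

  # southwesterly stress on a 45-degree coast gives the same tau_c = 0.1
  st_sw <- stress_from_arrays(array(0.1 / sqrt(2), d), array(0.1 / sqrt(2), d),
                              lat = lat, lon = lon)
  et2 <- ekman_transport(st_sw, coastline_spec(45), const)
  expect_equal(et2$values[1, 2, 2], et1$values[1, 2, 2], tolerance = 1e-12)
})

test_that("EPV and ET are linear in stress and odd under wind reversal", {
  set.seed(8)
  lat <- seq(10, 13, by = 0.25); lon <- seq(107, 111, by = 0.25)
  d <- c(2, length(lat), length(lon))
  t1x <- array(rnorm(prod(d), 0, 0.05), d); t1y <- array(rnorm(prod(d), 0, 0.05), d)
  t2x <- array(rnorm(prod(d), 0, 0.05), d); t2y <- array(rnorm(prod(d), 0, 0.05), d)
  mk <- function(tx, ty) stress_from_arrays(tx, ty, lat = lat, lon = lon)
  a <- 2.3; b <- -0.7
  comb <- mk(a * t1x + b * t2x, a * t1y + b * t2y)
  lin <- a * ekman_pumping(mk(t1x, t1y))$values +
    b * ekman_pumping(mk(t2x, t2y))$values
  expect_equal(ekman_pumping(comb)$values, lin, tolerance = 1e-12)

  coast <- coastline_spec(35)
  lin_et <- a * ekman_transport(mk(t1x, t1y), coast)$values +
    b * ekman_transport(mk(t2x, t2y), coast)$values
  expect_equal(ekman_transport(comb, coast)$values, lin_et, tolerance = 1e-12)

  rev <- mk(-t1x, -t1y)
  expect_equal(ekman_pumping(rev)$values, -ekman_pumping(mk(t1x, t1y))$values)
  expect_equal(ekman_transport(rev, coast)$values,
               -ekman_transport(mk(t1x, t1y), coast)$values)
})

test_that("beta term is under 10% of the curl term in the study band", {
  # representative: |tau| <= 0.2, sinusoidal curl-bearing tau_y at L = 500 km
  const <- physical_constants()
  sin_case <- sinusoid_stress(tau0 = 0.2, L = 5e5, taux = 0.2)
  curl_term <- ekman_pumping(sin_case$stress, const, include_beta = FALSE)
  both <- ekman_pumping(sin_case$stress, const, include_beta = TRUE)
  beta_term <- both$values - curl_term$values
  ratio <- max(abs(beta_term), na.rm = TRUE) /
    max(abs(curl_term$values), na.rm = TRUE)
  expect_lt(ratio, 0.1)
})

test_that("latitudes within the equatorial guard band are masked with a warning", {
  lat <- seq(-2, 2, by = 0.5); lon <- c(108, 108.5, 109)
  d <- c(1, length(lat), length(lon))
  st <- stress_from_arrays(array(0.1, d), array(0.1, d), lat = lat, lon = lon)
  expect_warning(et <- ekman_transport(st, coastline_spec(35)), "equator")
  expect_true(all(is.na(et$values[, abs(lat) < 1, ])))
  expect_true(all(is.finite(et$values[, abs(lat) >= 1, ])))
})
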