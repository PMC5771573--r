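#' Physical constants for air-sea momentum transfer
#'
#' @param rho_water sea-water density, kg m-3.
#' @param rho_air air density, kg m-3.
#' @param drag_coefficient dimensionless 10-m drag coefficient (used by the
#'   constant-Cd bulk formula).
#' @param omega_earth Earth's rotation rate, rad s-1.
#' @param earth_radius Earth radius, m.
#' @return an object of class `physical_constants`.
#' @export
physical_constants <- function(rho_water = 1025, rho_air = 1.225,
                               drag_coefficient = 1.3e-3,
                               omega_earth = 7.2921e-5,
                               earth_radius = 6.371e6) {
  vals <- c(rho_water, rho_air, drag_coefficient, omega_earth, earth_radius)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(rho_water = rho_water, rho_air = rho_air,
                 drag_coefficient = drag_coefficient,
                 omega_earth = omega_earth, earth_radius = earth_radius),
            class = "physical_constants")
}

#' Coriolis parameter and its meridional gradient
#'
#' `f = 2 Omega sin(lat)`, `beta = 2 Omega cos(lat) / R`.
#'
#' @param lat latitude, degrees.
#' @param const a [physical_constants()].
#' @return numeric vector, s-1 (`coriolis_f`) or m-1 s-1 (`coriolis_beta`).
#' @export
coriolis_f <- function(lat, const = physical_constants()) {
  2 * const$omega_earth * sin(lat * pi / 180)
}

#' @rdname coriolis_f
#' @export
coriolis_beta <- function(lat, const = physical_constants()) {
  2 * const$omega_earth * cos(lat * pi / 180) / const$earth_radius
}

#' Coastline orientation
#'
#' The local coastline tangent bearing, degrees clockwise from true north.
#' With the ocean to the east of a roughly north-south coast, wind stress
#' projected onto this tangent (positive along-bearing) drives offshore Ekman
#' transport, so positive transport is upwelling-favorable. The default 35
#' degrees approximates the southeast Vietnam coast. A per-latitude table
#' (`data.frame(lat, angle)`) may be supplied instead of a single angle.
#'
#' @param angle bearing in `[0, 360)` degrees clockwise from north.
#' @param table optional `data.frame` with columns `lat`, `angle`.
#' @return an object of class `coastline_spec`.
#' @export
coastline_spec <- function(angle = 35, table = NULL) {
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), all(c("lat", "angle") %in% names(table)))
    if (any(table$angle < 0 | table$angle >= 360)) {
      stop("coastline angles must lie in [0, 360)", call. = FALSE)
    }
  } else if (angle < 0 || angle >= 360) {
    stop("coastline angle must lie in [0, 360)", call. = FALSE)
  }
  structure(list(angle = angle, table = table), class = "coastline_spec")
}

.coast_angle_at <- function(coast, lat) {
  if (is.null(coast$table)) return(rep(coast$angle, length(lat)))
  stats::approx(coast$table$lat, coast$table$angle, xout = lat, rule = 2)$y
}

#' Surface wind stress from 10-m winds
#'
#' Bulk formula `tau = rho_air * Cd * |U| * (u, v)`. By default the drag
#' coefficient is the constant in `const`; `cd_scheme = "large_pond"` uses
#' the piecewise neutral coefficient `1.2e-3` below 11 m s-1 and
#' `(0.49 + 0.065 |U|) * 1e-3` above.
#'
#' @param u10,v10 eastward/northward 10-m wind, [gridded_field()]s on one
#'   grid and time axis, m s-1.
#' @param const a [physical_constants()].
#' @param cd_scheme `"constant"` (default) or `"large_pond"`.
#' @return an object of class `stress_field`: list with [gridded_field()]s
#'   `tau_x`, `tau_y` in N m-2.
#' @export
wind_stress <- function(u10, v10, const = physical_constants(),
                        cd_scheme = c("constant", "large_pond")) {
  cd_scheme <- match.arg(cd_scheme)
  stopifnot(inherits(u10, "gridded_field"), inherits(v10, "gridded_field"))
  if (!identical(dim(u10$values), dim(v10$values)) ||
      !isTRUE(all.equal(u10$lat, v10$lat)) ||
      !isTRUE(all.equal(u10$lon, v10$lon)) ||
      !identical(u10$time, v10$time)) {
    stop("u10 and v10 must share grid and time axis", call. = FALSE)
  }
  spd <- sqrt(u10$values^2 + v10$values^2)
  cd <- if (cd_scheme == "constant") const$drag_coefficient
        else ifelse(spd < 11, 1.2e-3, (0.49 + 0.065 * spd) * 1e-3)
  tx <- const$rho_air * cd * spd * u10$values
  ty <- const$rho_air * cd * spd * v10$values
  structure(list(
    tau_x = gridded_field("tau_x", tx, u10$time, u10$lat, u10$lon, "N m-2"),
    tau_y = gridded_field("tau_y", ty, u10$time, u10$lat, u10$lon, "N m-2")
  ), class = "stress_field")
}

# uniform grid spacing in degrees, with a sanity check
.grid_step <- function(co, what) {
  d <- diff(co)
  if (any(abs(d - d[1]) > 1e-6 * abs(d[1]))) {
    stop(sprintf("%s grid must be regular for finite differences", what),
         call. = FALSE)
  }
  d[1]
}

# central difference along dimension `dm` (2 = lat, 3 = lon) of a
# (time, lat, lon) array; boundary handling "mask" (NA) or "one_sided".
.fd_central <- function(a, dm, step, edge) {
  n <- dim(a)[dm]
  if (n < 3L) stop("need at least 3 grid points for central differences",
                   call. = FALSE)
  idx <- function(i) {
    if (dm == 2L) a[, i, , drop = FALSE] else a[, , i, drop = FALSE]
  }
  out <- array(NA_real_, dim = dim(a))
  ins <- 2:(n - 1L)
  ctr <- (idx(ins + 1L) - idx(ins - 1L)) / (2 * step)
  if (dm == 2L) out[, ins, ] <- ctr else out[, , ins] <- ctr
  if (edge == "one_sided") {
    lo <- (idx(2L) - idx(1L)) / step
    hi <- (idx(n) - idx(n - 1L)) / step
    if (dm == 2L) { out[, 1L, ] <- lo; out[, n, ] <- hi }
    else { out[, , 1L] <- lo; out[, , n] <- hi }
  }
  out
}

#' Curl of the wind stress on a sphere
#'
#' `curl = d(tau_y)/dx - d(tau_x)/dy` with the spherical metric
#' `d/dx = (1 / (R cos(lat))) d/dlon`, `d/dy = (1/R) d/dlat` (angles in
#' radians). Central differences in the interior; the domain boundary is
#' masked by default (`edge = "one_sided"` uses one-sided differences there
#' instead). Cells adjacent to masked cells are masked, since a central
#' difference touching a missing value is undefined.
#'
#' @param stress a [wind_stress()] result.
#' @param const a [physical_constants()].
#' @param edge `"mask"` (default) or `"one_sided"`.
#' @return a [gridded_field()] of stress curl, N m-3.
#' @export
stress_curl <- function(stress, const = physical_constants(),
                        edge = c("mask", "one_sided")) {
  edge <- match.arg(edge)
  stopifnot(inherits(stress, "stress_field"))
  tx <- stress$tau_x; ty <- stress$tau_y
  if (all(is.na(tx$values)) && all(is.na(ty$values))) {
    stop("stress field is entirely masked", call. = FALSE)
  }
  dlam <- .grid_step(tx$lon, "lon") * pi / 180
  dphi <- .grid_step(tx$lat, "lat") * pi / 180
  dty_dlam <- .fd_central(ty$values, 3L, dlam, edge)
  dtx_dphi <- .fd_central(tx$values, 2L, dphi, edge)
  d <- dim(tx$values)
  cphi <- array(rep(cos(tx$lat * pi / 180), each = d[1]), dim = d)
  curl <- dty_dlam / (const$earth_radius * cphi) - dtx_dphi / const$earth_radius
  gridded_field("stress_curl", curl, tx$time, tx$lat, tx$lon, "N m-3")
}

.equatorial_guard <- function(vals, lat, guard = 1) {
  bad <- abs(lat) < guard
  if (any(bad)) {
    warning(sprintf(
      "%d latitude row(s) within %g deg of the equator masked (f too small)",
      sum(bad), guard), call. = FALSE)
    vals[, bad, ] <- NA_real_
  }
  vals
}

#' Ekman pumping velocity
#'
#' `EPV = curl(tau) / (rho f)`, optionally plus the planetary-gradient term
#' `beta tau_x / (rho f^2)` (`tau_x` the eastward stress). The beta term is
#' small at the latitudes of interest and is off by default; it is
#' implemented so the neglect can be quantified. `f` and `beta` are evaluated
#' at each cell's latitude. Latitudes within 1 degree of the equator are
#' masked (f -> 0).
#'
#' @param stress a [wind_stress()] result.
#' @param const a [physical_constants()].
#' @param include_beta include the `beta tau_x / (rho f^2)` term?
#' @param edge boundary handling passed to [stress_curl()].
#' @return a [gridded_field()] of vertical velocity, m s-1, positive upward
#'   (upwelling).
#' @export
ekman_pumping <- function(stress, const = physical_constants(),
                          include_beta = FALSE,
                          edge = c("mask", "one_sided")) {
  curl <- stress_curl(stress, const, edge)
  lat <- curl$lat
  d <- dim(curl$values)
  f <- array(rep(coriolis_f(lat, const), each = d[1]), dim = d)
  epv <- curl$values / (const$rho_water * f)
  if (include_beta) {
    b <- array(rep(coriolis_beta(lat, const), each = d[1]), dim = d)
    epv <- epv + b * stress$tau_x$values / (const$rho_water * f^2)
  }
  epv <- .equatorial_guard(epv, lat)
  gridded_field("epv", epv, curl$time, lat, curl$lon, "m s-1")
}

#' Offshore Ekman transport
#'
#' `ET = tau_c / (rho f)` where `tau_c` is the wind-stress component along
#' the coastline tangent defined by [coastline_spec()]. Positive values are
#' upwelling-favorable (offshore surface transport for a coast with the
#' ocean on its right-hand side looking along the bearing). Units are
#' m2 s-1: volume transport per unit coastline length.
#'
#' @param stress a [wind_stress()] result.
#' @param coast a [coastline_spec()].
#' @param const a [physical_constants()].
#' @return a [gridded_field()] of Ekman transport, m2 s-1.
#' @export
ekman_transport <- function(stress, coast = coastline_spec(),
                            const = physical_constants()) {
  stopifnot(inherits(stress, "stress_field"), inherits(coast, "coastline_spec"))
  tx <- stress$tau_x; ty <- stress$tau_y
  d <- dim(tx$values)
  th <- .coast_angle_at(coast, tx$lat) * pi / 180
  sth <- array(rep(sin(th), each = d[1]), dim = d)
  cth <- array(rep(cos(th), each = d[1]), dim = d)
  tau_c <- tx$values * sth + ty$values * cth
  f <- array(rep(coriolis_f(tx$lat, const), each = d[1]), dim = d)
  et <- tau_c / (const$rho_water * f)
  et <- .equatorial_guard(et, tx$lat)
  gridded_field("et", et, tx$time, tx$lat, tx$lon, "m2 s-1")
}
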