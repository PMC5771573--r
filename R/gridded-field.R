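#' Gridded geophysical field
#'
#' The common currency of the pipeline: one physical variable on a regular
#' latitude/longitude grid with a calendar time axis. Values are stored as a
#' numeric array with dimensions `(time, lat, lon)`; missing or land cells are
#' `NA` and are excluded from every mean, anomaly, EOF and correlation
#' downstream.
#'
#' Coordinates are cell centers. Latitude and longitude may be supplied in
#' either direction; they are normalized to ascending order (values reordered
#' consistently). Longitudes on the `[0, 360)` convention are mapped to
#' `(-180, 180]`. The time axis must be strictly increasing after sorting.
#'
#' @param name variable name, e.g. `"sst"`.
#' @param values numeric array, `dim = c(length(time), length(lat), length(lon))`.
#' @param time `Date` vector, one per time step.
#' @param lat,lon numeric coordinate vectors in degrees, strictly monotonic.
#' @param units non-empty units string (e.g. `"degC"`, `"mg m-3"`, `"m s-1"`).
#'
#' @return An object of class `gridded_field`: a list with elements `name`,
#'   `values`, `time`, `lat`, `lon`, `units`.
#' @export
gridded_field <- function(name, values, time, lat, lon, units) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("`units` must be a non-empty string", call. = FALSE)
  }
  time <- as.Date(time)
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  values <- as.array(values)
  if (length(dim(values)) != 3L ||
      !all(dim(values) == c(length(time), length(lat), length(lon)))) {
    stop("`values` must be a (time, lat, lon) array matching the coordinates",
         call. = FALSE)
  }

  # time: sort ascending, then require strict increase
  ot <- order(time)
  time <- time[ot]
  values <- values[ot, , , drop = FALSE]
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0)) {
    stop("time axis must be strictly increasing (duplicate timestamps found)",
         call. = FALSE)
  }

  # longitudes [0, 360) -> (-180, 180]
  if (any(lon > 180)) lon <- ifelse(lon > 180, lon - 360, lon)

  for (ax in c("lat", "lon")) {
    co <- get(ax)
    if (length(co) > 1L && !(all(diff(co) > 0) || all(diff(co) < 0))) {
      stop(sprintf("%s must be strictly monotonic", ax), call. = FALSE)
    }
  }
  if (length(lat) > 1L && lat[1] > lat[2]) {
    lat <- rev(lat)
    values <- values[, rev(seq_along(lat)), , drop = FALSE]
  }
  if (length(lon) > 1L && lon[1] > lon[2]) {
    lon <- rev(lon)
    values <- values[, , rev(seq_along(lon)), drop = FALSE]
  }

  structure(
    list(name = name, values = values, time = time,
         lat = lat, lon = lon, units = units),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %s [%s]\n", x$name, x$units))
  cat(sprintf("  time: %d steps (%s .. %s)\n", d[1],
              format(min(x$time)), format(max(x$time))))
  cat(sprintf("  grid: %d lat x %d lon (%.3f..%.3fN, %.3f..%.3fE)\n",
              d[2], d[3], min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  missing: %.1f%% of cells\n",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Missing-data mask of a gridded field
#'
#' @param field a [gridded_field()].
#' @return logical array, `TRUE` where the value is missing (land, cloud,
#'   or undefined after differencing).
#' @export
field_mask <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  is.na(field$values)
}

#' Rectangular analysis region
#'
#' A closed longitude/latitude box; grid cells belong to the box when their
#' centers lie inside it (closed on all edges).
#'
#' @param lon_min,lon_max,lat_min,lat_max box corners in degrees.
#' @return an object of class `region_box`.
#' @export
region_box <- function(lon_min, lon_max, lat_min, lat_max) {
  if (!(lon_min < lon_max) || !(lat_min < lat_max)) {
    stop("require lon_min < lon_max and lat_min < lat_max", call. = FALSE)
  }
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = "region_box")
}

#' Subset a field to an analysis box
#'
#' Keeps the cells whose centers fall inside the closed box. Coordinates and
#' the time axis are preserved.
#'
#' @param field a [gridded_field()].
#' @param box a [region_box()].
#' @return a [gridded_field()] restricted to the box.
#' @export
subset_region <- function(field, box) {
  stopifnot(inherits(field, "gridded_field"), inherits(box, "region_box"))
  ilat <- which(field$lat >= box$lat_min & field$lat <= box$lat_max)
  ilon <- which(field$lon >= box$lon_min & field$lon <= box$lon_max)
  if (length(ilat) == 0L || length(ilon) == 0L) {
    stop("box does not intersect the field's domain", call. = FALSE)
  }
  gridded_field(field$name,
                field$values[, ilat, ilon, drop = FALSE],
                field$time, field$lat[ilat], field$lon[ilon], field$units)
}

#' Box-averaged time series
#'
#' Per-time-step spatial mean over the unmasked cells of an analysis box,
#' optionally weighted by `cos(latitude)` (the default, approximating cell
#' area on a regular grid). Time steps with no unmasked cell yield `NA`,
#' which downstream correlation code removes pairwise.
#'
#' @param field a [gridded_field()].
#' @param box a [region_box()]; use the full domain if `NULL`.
#' @param weighting `"cos_lat"` (default) or `"none"`.
#' @return a `data.frame` with columns `time`, `value`, `n_cells`.
#' @export
area_mean_series <- function(field, box = NULL,
                             weighting = c("cos_lat", "none")) {
  weighting <- match.arg(weighting)
  if (!is.null(box)) field <- subset_region(field, box)
  d <- dim(field$values)
  w <- if (weighting == "cos_lat") cos(field$lat * pi / 180) else rep(1, d[2])
  wmat <- matrix(rep(w, times = d[3]), nrow = d[2])  # lat x lon
  v <- matrix(field$values, nrow = d[1])             # time x (lat*lon)
  wrow <- as.vector(wmat)
  num <- rowSums(sweep(v, 2L, wrow, `*`), na.rm = TRUE)
  den <- rowSums(sweep(!is.na(v), 2L, wrow, `*`))
  n_cells <- rowSums(!is.na(v))
  value <- ifelse(den > 0, num / den, NA_real_)
  data.frame(time = field$time, value = value, n_cells = n_cells)
}
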