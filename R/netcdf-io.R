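# CF-style NetCDF reading/writing for gridded_field objects (via ncdf4).

.coord_aliases <- list(
  time = c("time", "t", "date"),
  lat  = c("lat", "latitude", "y"),
  lon  = c("lon", "longitude", "x")
)

.find_dim <- function(dims, axis) {
  nms <- vapply(dims, function(d) d$name, character(1))
  hit <- which(tolower(nms) %in% .coord_aliases[[axis]])
  if (length(hit) == 0L) return(NA_integer_)
  hit[1]
}

.parse_time_units <- function(vals, units) {
  vals <- as.numeric(vals)  # drop any dim attribute from ncdf4
  m <- regmatches(units, regexec(
    "^(seconds|hours|days) since ([0-9]{4}-[0-9]{2}-[0-9]{2})", units))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("unsupported time units in NetCDF file: '%s'", units),
         call. = FALSE)
  }
  origin <- as.Date(m[3])
  fac <- switch(m[2], seconds = 86400, hours = 24, days = 1)
  origin + round(vals / fac)
}

#' Read one variable from a CF-style NetCDF file
#'
#' Expects coordinate variables for time, latitude and longitude (common
#' aliases accepted). Fill values become `NA`; coordinates are normalized to
#' ascending order by the [gridded_field()] constructor.
#'
#' @param path NetCDF file path.
#' @param variable variable name to read.
#' @return a [gridded_field()].
#' @export
read_gridded <- function(path, variable) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!variable %in% names(nc$var)) {
    stop(sprintf("variable '%s' not found in %s (has: %s)", variable, path,
                 paste(names(nc$var), collapse = ", ")), call. = FALSE)
  }
  v <- nc$var[[variable]]
  it <- .find_dim(v$dim, "time")
  iy <- .find_dim(v$dim, "lat")
  ix <- .find_dim(v$dim, "lon")
  missing_ax <- c("time", "lat", "lon")[is.na(c(it, iy, ix))]
  if (length(missing_ax) > 0L) {
    stop(sprintf("file %s lacks coordinate(s) for variable '%s': %s",
                 path, variable, paste(missing_ax, collapse = ", ")),
         call. = FALSE)
  }
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  # ncvar_get returns dims in the variable's storage order; put (time, lat, lon)
  vals <- aperm(vals, c(it, iy, ix))
  tdim <- v$dim[[it]]
  time <- .parse_time_units(tdim$vals, tdim$units)
  units <- if (nzchar(v$units)) v$units else {
    att <- ncdf4::ncatt_get(nc, variable, "units")
    if (isTRUE(att$hasatt)) att$value else ""
  }
  if (!nzchar(units)) units <- "1"
  gridded_field(variable, vals, time, v$dim[[iy]]$vals, v$dim[[ix]]$vals, units)
}

#' Write a gridded field to CF-style NetCDF
#'
#' Dimensions `lon`, `lat`, `time` (days since 1970-01-01); `NA` is written
#' as the fill value. A write/read round trip preserves values, mask, units
#' and coordinates exactly.
#'
#' @param field a [gridded_field()].
#' @param path output file path.
#' @param extra_atts named list of additional character/numeric attributes to
#'   attach to the variable.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path, extra_atts = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dtim <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                           as.numeric(field$time), unlim = TRUE)
  fill <- 1e30
  var <- ncdf4::ncvar_def(field$name, field$units, list(dlon, dlat, dtim),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # storage order (lon, lat, time)
  ncdf4::ncvar_put(nc, var, aperm(field$values, c(3, 2, 1)))
  if (!is.null(extra_atts)) {
    for (nm in names(extra_atts)) {
      ncdf4::ncatt_put(nc, field$name, nm, extra_atts[[nm]])
    }
  }
  invisible(path)
}
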