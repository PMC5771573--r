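#' Bilinear regridding
#'
#' Interpolates a field onto a target grid that lies inside the source
#' domain. Interpolation is bilinear in longitude/latitude; the rule for
#' missing data is conservative: a target cell whose 4-point stencil touches
#' any masked source cell is masked, even when the masked corner carries zero
#' weight. Bilinear interpolation is exact for fields linear in lon and lat.
#'
#' @param field a [gridded_field()].
#' @param target_lat,target_lon target cell-center coordinates (degrees,
#'   monotonic).
#' @return a [gridded_field()] on the target grid.
#' @export
regrid_bilinear <- function(field, target_lat, target_lon) {
  stopifnot(inherits(field, "gridded_field"))
  target_lat <- sort(as.numeric(target_lat))
  target_lon <- sort(as.numeric(target_lon))
  slat <- field$lat; slon <- field$lon
  if (min(target_lat) < min(slat) || max(target_lat) > max(slat) ||
      min(target_lon) < min(slon) || max(target_lon) > max(slon)) {
    stop("target grid extends outside the source domain", call. = FALSE)
  }
  nlat <- length(slat); nlon <- length(slon)
  nt <- length(field$time)

  bracket <- function(tx, sx) {
    i <- findInterval(tx, sx, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(sx) - 1L)
    w <- (tx - sx[i]) / (sx[i + 1L] - sx[i])
    list(i = i, w = w)
  }
  by <- bracket(target_lat, slat)
  bx <- bracket(target_lon, slon)

  ntlat <- length(target_lat); ntlon <- length(target_lon)
  IY <- rep(by$i, times = ntlon); WY <- rep(by$w, times = ntlon)
  IX <- rep(bx$i, each = ntlat);  WX <- rep(bx$w, each = ntlat)

  V <- matrix(field$values, nrow = nt)  # time x (lat*lon), lat fastest
  k <- function(iy, ix) (ix - 1L) * nlat + iy
  expand <- function(w) matrix(rep(w, each = nt), nrow = nt)
  out <- V[, k(IY, IX), drop = FALSE]          * expand((1 - WY) * (1 - WX)) +
         V[, k(IY + 1L, IX), drop = FALSE]     * expand(WY * (1 - WX)) +
         V[, k(IY, IX + 1L), drop = FALSE]     * expand((1 - WY) * WX) +
         V[, k(IY + 1L, IX + 1L), drop = FALSE] * expand(WY * WX)

  gridded_field(field$name, array(out, dim = c(nt, ntlat, ntlon)),
                field$time, target_lat, target_lon, field$units)
}
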