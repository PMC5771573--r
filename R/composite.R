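#' Compositing specification
#'
#' Describes how a field's time axis is reduced: per-year seasonal means
#' (default season 1 Jun - 31 Aug), the six summer fifteen-day windows
#' (Jun 1-15, Jun 16-30, Jul 1-15, Jul 16-31, Aug 1-15, Aug 16-31 -- the two
#' late windows hold 16 days so the season is tiled without overlap),
#' calendar-month means, or a multi-year climatology that pools one of those
#' window kinds across `years` (default 1998-2014).
#'
#' @param kind one of `"seasonal_mean"`, `"fifteen_day"`, `"monthly"`,
#'   `"climatology"`.
#' @param season_start,season_end season window as `"mm-dd"` strings.
#' @param years climatology years (used only for `kind = "climatology"`).
#' @param of window kind pooled by the climatology (`"fifteen_day"` or
#'   `"seasonal_mean"`).
#' @return an object of class `composite_spec`.
#' @export
composite_spec <- function(kind = c("seasonal_mean", "fifteen_day",
                                    "monthly", "climatology"),
                           season_start = "06-01", season_end = "08-31",
                           years = 1998:2014,
                           of = c("fifteen_day", "seasonal_mean")) {
  kind <- match.arg(kind)
  of <- match.arg(of)
  stopifnot(length(years) >= 1L)
  structure(list(kind = kind, season_start = season_start,
                 season_end = season_end, years = as.integer(years), of = of),
            class = "composite_spec")
}

# fifteen-day summer windows as mm-dd pairs
.fifteen_day_windows <- function() {
  list(c("06-01", "06-15"), c("06-16", "06-30"),
       c("07-01", "07-15"), c("07-16", "07-31"),
       c("08-01", "08-15"), c("08-16", "08-31"))
}

.mmdd <- function(dates) format(dates, "%m-%d")
.year <- function(dates) as.integer(format(dates, "%Y"))

# windows: list of (label_date, logical index into field$time)
.composite_windows <- function(field, spec) {
  tt <- field$time
  yrs <- sort(unique(.year(tt)))
  md <- .mmdd(tt)
  win <- list()
  add <- function(label, idx) {
    if (any(idx)) win[[length(win) + 1L]] <<- list(label = label, idx = idx)
  }
  mmdd_in <- function(a, b) md >= a & md <= b
  switch(spec$kind,
    seasonal_mean = for (y in yrs) {
      add(as.Date(sprintf("%d-%s", y, spec$season_start)),
          .year(tt) == y & mmdd_in(spec$season_start, spec$season_end))
    },
    fifteen_day = for (y in yrs) {
      for (w in .fifteen_day_windows()) {
        add(as.Date(sprintf("%d-%s", y, w[1])),
            .year(tt) == y & mmdd_in(w[1], w[2]))
      }
    },
    monthly = {
      ym <- format(tt, "%Y-%m")
      for (u in sort(unique(ym))) add(as.Date(paste0(u, "-01")), ym == u)
    },
    climatology = {
      wins <- if (spec$of == "fifteen_day") .fifteen_day_windows()
              else list(c(spec$season_start, spec$season_end))
      y0 <- spec$years[1]
      for (w in wins) {
        add(as.Date(sprintf("%d-%s", y0, w[1])),
            .year(tt) %in% spec$years & mmdd_in(w[1], w[2]))
      }
    }
  )
  win
}

#' Time composites of a gridded field
#'
#' Per-cell arithmetic mean over the unmasked samples inside each window of
#' the spec. A cell with no unmasked sample in a window is masked there. The
#' number of contributing time steps per cell is returned in the `count`
#' element of the result.
#'
#' @param field a [gridded_field()].
#' @param spec a [composite_spec()].
#' @return a [gridded_field()] whose time axis holds one step per window
#'   (labelled by window start; climatologies are labelled in the first
#'   climatology year), with an extra element `count`.
#' @export
composite <- function(field, spec) {
  stopifnot(inherits(field, "gridded_field"), inherits(spec, "composite_spec"))
  win <- .composite_windows(field, spec)
  if (length(win) == 0L) {
    stop("field's time axis does not cover any composite window", call. = FALSE)
  }
  d <- dim(field$values)
  nw <- length(win)
  vals <- array(NA_real_, dim = c(nw, d[2], d[3]))
  cnt <- array(0L, dim = c(nw, d[2], d[3]))
  for (i in seq_len(nw)) {
    sl <- field$values[win[[i]]$idx, , , drop = FALSE]
    n <- colSums(!is.na(sl), dims = 1)
    m <- colMeans(sl, na.rm = TRUE, dims = 1)
    m[n == 0L] <- NA_real_
    vals[i, , ] <- m
    cnt[i, , ] <- n
  }
  out <- gridded_field(field$name, vals,
                       as.Date(vapply(win, function(w) as.character(w$label),
                                      character(1))),
                       field$lat, field$lon, field$units)
  out$count <- cnt
  out$composite <- spec$kind
  out
}
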