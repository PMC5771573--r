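#' Remove a per-cell baseline to form anomalies
#'
#' `baseline = "time_mean"` subtracts each cell's mean over the whole record.
#' `baseline = "climatology"` subtracts the mean of the same calendar unit
#' across years: calendar month when the record is monthly (all time stamps
#' on the same day of month, fewer than 20 per year), otherwise day of year.
#' Masked cells stay masked.
#'
#' @param field a [gridded_field()].
#' @param baseline `"time_mean"` or `"climatology"`.
#' @return an `anomaly_field` (a [gridded_field()] with a `baseline`
#'   element recording what was removed).
#' @export
build_anomalies <- function(field, baseline = c("time_mean", "climatology")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(field, "gridded_field"))
  nt <- length(field$time)
  if (nt < 2L) {
    stop("need at least 2 time steps to form anomalies", call. = FALSE)
  }
  v <- matrix(field$values, nrow = nt)  # time x cell
  if (baseline == "time_mean") {
    mu <- colMeans(v, na.rm = TRUE)
    a <- sweep(v, 2L, mu, `-`)
  } else {
    day_gap <- stats::median(diff(as.numeric(field$time)))
    key <- if (day_gap >= 20) format(field$time, "%m") else format(field$time, "%m-%d")
    a <- v
    for (k in unique(key)) {
      rows <- which(key == k)
      mu <- colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
      a[rows, ] <- sweep(v[rows, , drop = FALSE], 2L, mu, `-`)
    }
  }
  out <- gridded_field(field$name, array(a, dim = dim(field$values)),
                       field$time, field$lat, field$lon, field$units)
  out$baseline <- baseline
  class(out) <- c("anomaly_field", class(out))
  out
}

#' Empirical orthogonal function decomposition
#'
#' Decomposes an anomaly field `X` (cells x time) into orthonormal spatial
#' modes `L` and amplitude-carrying principal-component time series `Y`,
#' `X = L Y`, ordered by decreasing explained variance. The decomposition is
#' computed from the eigenstructure of the smaller of the two covariance-type
#' matrices (`X X'` or `X' X`), which share the nonzero eigenvalues
#' `lambda_k`; `variance_fraction_k = 100 lambda_k / sum(lambda)`.
#'
#' Grid cells with any missing time step are excluded listwise and reported
#' in `cell_index`/`n_dropped`. Sign convention: the largest-magnitude
#' element of each spatial mode is positive (the PC absorbs the flip).
#'
#' @param anom an [build_anomalies()] result (or any [gridded_field()]
#'   already centered in time).
#' @param n_modes number of modes to retain (truncated to the matrix rank,
#'   with a warning, if larger).
#' @param weighting `"none"` (default) or `"sqrt_cos_lat"` row weighting.
#' @return an object of class `eof_result`: `spatial_modes` (cells x k,
#'   orthonormal columns), `temporal_modes` (k x time), `variance_fraction`
#'   (length-k, percent of total variance), `eigenvalues` (all nonzero),
#'   `n_modes`, `cell_index` (data.frame `lat_index`, `lon_index`, `lat`,
#'   `lon` for retained cells), plus grid/time metadata.
#' @export
eof_decompose <- function(anom, n_modes = 1,
                          weighting = c("none", "sqrt_cos_lat")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(anom, "gridded_field"))
  nt <- length(anom$time)
  if (nt < 2L) stop("need at least 2 time steps", call. = FALSE)
  d <- dim(anom$values)
  v <- matrix(anom$values, nrow = nt)      # time x cell
  complete <- colSums(is.na(v)) == 0L
  if (!any(complete)) {
    stop("no grid cell has a complete time series", call. = FALSE)
  }
  X <- t(v[, complete, drop = FALSE])      # cells x time
  cells <- which(complete)
  lat_index <- ((cells - 1L) %% d[2]) + 1L
  lon_index <- ((cells - 1L) %/% d[2]) + 1L

  w <- rep(1, nrow(X))
  if (weighting == "sqrt_cos_lat") {
    w <- sqrt(cos(anom$lat[lat_index] * pi / 180))
    X <- X * w
  }

  p <- nrow(X)
  if (p <= nt) {
    S <- tcrossprod(X)                     # cells x cells
    eg <- eigen(S, symmetric = TRUE)
    lam <- eg$values
    rank <- sum(lam > max(lam[1], 0) * 1e-12)
    rank <- max(rank, 1L)
    L <- eg$vectors[, seq_len(rank), drop = FALSE]
    Y <- crossprod(L, X)                   # rank x time
  } else {
    S <- crossprod(X)                      # time x time
    eg <- eigen(S, symmetric = TRUE)
    lam <- eg$values
    rank <- sum(lam > max(lam[1], 0) * 1e-12)
    rank <- max(rank, 1L)
    V <- eg$vectors[, seq_len(rank), drop = FALSE]
    L <- X %*% V %*% diag(1 / sqrt(lam[seq_len(rank)]), rank)
    Y <- sqrt(lam[seq_len(rank)]) * t(V)
  }
  lam <- pmax(lam, 0)
  if (n_modes > rank) {
    warning(sprintf("n_modes = %d exceeds rank %d; truncated", n_modes, rank),
            call. = FALSE)
    n_modes <- rank
  }
  # sign convention: dominant spatial element positive
  for (k in seq_len(rank)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) { L[, k] <- -L[, k]; Y[k, ] <- -Y[k, ] }
  }
  structure(list(
    spatial_modes = L[, seq_len(n_modes), drop = FALSE],
    temporal_modes = Y[seq_len(n_modes), , drop = FALSE],
    variance_fraction = 100 * lam[seq_len(n_modes)] / sum(lam),
    eigenvalues = lam[seq_len(rank)],
    total_variance = sum(lam),
    n_modes = n_modes,
    cell_index = data.frame(lat_index = lat_index, lon_index = lon_index,
                            lat = anom$lat[lat_index],
                            lon = anom$lon[lon_index]),
    weights = w,
    n_dropped = sum(!complete),
    time = anom$time, lat = anom$lat, lon = anom$lon,
    units = anom$units, name = anom$name
  ), class = "eof_result")
}

#' @export
print.eof_result <- function(x, ...) {
  cat(sprintf("<eof_result> %s: %d mode(s) over %d cells x %d steps\n",
              x$name, x$n_modes, nrow(x$spatial_modes),
              length(x$time)))
  vf <- sprintf("%.2f%%", x$variance_fraction)
  cat("  variance fraction:", paste(vf, collapse = ", "), "\n")
  if (x$n_dropped > 0) {
    cat(sprintf("  %d cell(s) dropped (incomplete time series)\n", x$n_dropped))
  }
  invisible(x)
}

#' Reconstruct an anomaly field from leading EOF modes
#'
#' Partial sum of the first `k` mode outer products, mapped back onto the
#' grid; cells dropped from the decomposition stay masked. With `k` equal to
#' the matrix rank this reproduces the input anomalies.
#'
#' @param result an [eof_decompose()] result.
#' @param k number of modes to use, `1 <= k <= n_modes`.
#' @return an `anomaly_field`.
#' @export
reconstruct <- function(result, k) {
  stopifnot(inherits(result, "eof_result"))
  if (k < 1 || k > result$n_modes) {
    stop(sprintf("k must be in 1..%d", result$n_modes), call. = FALSE)
  }
  Xk <- result$spatial_modes[, seq_len(k), drop = FALSE] %*%
    result$temporal_modes[seq_len(k), , drop = FALSE]
  Xk <- Xk / result$weights
  nt <- length(result$time)
  vals <- array(NA_real_, dim = c(nt, length(result$lat), length(result$lon)))
  ci <- result$cell_index
  for (i in seq_len(nrow(ci))) {
    vals[, ci$lat_index[i], ci$lon_index[i]] <- Xk[i, ]
  }
  out <- gridded_field(result$name, vals, result$time,
                       result$lat, result$lon, result$units)
  out$baseline <- "reconstructed"
  class(out) <- c("anomaly_field", class(out))
  out
}
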