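#' Table of aligned time series for correlation analysis
#'
#' Holds the response (chlorophyll-a in the canonical analysis) and the
#' predictor series (SST, Ekman transport, Ekman pumping) on one shared time
#' axis. Missing samples are handled by pairwise deletion for simple
#' correlations and listwise deletion for the multivariate statistics.
#'
#' @param data a `data.frame` of numeric series (an optional `time` column
#'   is kept as metadata).
#' @param response name of the dependent series.
#' @param predictors predictor names, in the order they index the
#'   correlation matrix; defaults to every non-response numeric column in
#'   `data`'s column order.
#' @return an object of class `series_table`.
#' @export
series_table <- function(data, response, predictors = NULL) {
  stopifnot(is.data.frame(data), response %in% names(data))
  time <- if ("time" %in% names(data)) data$time else seq_len(nrow(data))
  cols <- setdiff(names(data), "time")
  if (is.null(predictors)) predictors <- setdiff(cols, response)
  stopifnot(all(predictors %in% cols), length(predictors) >= 1L)
  series <- data[c(predictors, response)]
  if (!all(vapply(series, is.numeric, logical(1)))) {
    stop("all series must be numeric", call. = FALSE)
  }
  structure(list(series = series, response = response,
                 predictors = predictors, time = time),
            class = "series_table")
}

#' Correlation matrix of predictors and response
#'
#' Pearson correlation matrix ordered `(x1, ..., xm, y)`, with pairwise
#' deletion of missing samples. Errors if any series is constant (its
#' correlations are undefined) or if any pair has fewer than 3 complete
#' samples.
#'
#' @param table a [series_table()].
#' @return a symmetric correlation matrix with unit diagonal; attribute
#'   `n_pairwise` holds the per-pair sample counts.
#' @export
correlation_matrix <- function(table) {
  stopifnot(inherits(table, "series_table"))
  s <- table$series
  sds <- vapply(s, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  bad <- names(s)[is.na(sds) | sds == 0]
  if (length(bad) > 0L) {
    stop(sprintf("series with zero variance: %s (correlation undefined)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(s)
  npair <- crossprod(!is.na(m))
  if (any(npair < 3L)) {
    stop("fewer than 3 complete samples for some series pair", call. = FALSE)
  }
  R <- stats::cor(m, use = "pairwise.complete.obs")
  attr(R, "n_pairwise") <- npair
  R
}

# signed cofactor (algebraic complement) of entry (i, j)
.cofactor <- function(M, i, j) {
  (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
}

#' Multiple correlation via correlation-matrix cofactors
#'
#' The correlation between the response and its best linear combination of
#' the predictors, computed from the joint correlation matrix `R` as
#' `sqrt(1 - |R| / C_yy)` with `C_yy` the cofactor of the response's
#' diagonal entry. The p-value comes from the F statistic of the equivalent
#' coefficient of determination, `F = (R^2/m) / ((1-R^2)/(n-m-1))`, with
#' `(m, n-m-1)` degrees of freedom; `n` is the number of complete cases.
#'
#' @param table a [series_table()].
#' @return list with `multiple_R`, `p_value`, `f_statistic`, `df`, `n`.
#' @export
multiple_correlation <- function(table) {
  stopifnot(inherits(table, "series_table"))
  R <- correlation_matrix(table)
  m <- length(table$predictors)
  iy <- m + 1L
  detR <- det(R)
  Cyy <- .cofactor(R, iy, iy)
  if (abs(Cyy) < 1e-12) {
    stop(sprintf("predictors are collinear (singular predictor block): %s",
                 paste(table$predictors, collapse = ", ")), call. = FALSE)
  }
  R2 <- 1 - detR / Cyy
  R2 <- min(max(R2, 0), 1)
  n <- sum(stats::complete.cases(table$series))
  df2 <- n - m - 1L
  if (R2 >= 1) {
    fstat <- Inf; p <- 0
  } else if (df2 <= 0) {
    fstat <- NA_real_; p <- NA_real_
  } else {
    fstat <- (R2 / m) / ((1 - R2) / df2)
    p <- stats::pf(fstat, m, df2, lower.tail = FALSE)
  }
  list(multiple_R = sqrt(R2), p_value = p, f_statistic = fstat,
       df = c(m, df2), n = n)
}

#' Partial correlation via correlation-matrix cofactors
#'
#' Correlation of the response with one predictor, controlling for the
#' remaining predictors: `-C_yi / sqrt(C_yy * C_ii)` with `C` the signed
#' cofactors of the joint correlation matrix. The p-value comes from
#' `t = r sqrt((n - m - 1) / (1 - r^2))` with `n - m - 1` degrees of
#' freedom (two-sided).
#'
#' @param table a [series_table()].
#' @param predictor name of the predictor of interest.
#' @return list with `partial_r`, `p_value`, `t_statistic`, `df`, `n`.
#' @export
partial_correlation <- function(table, predictor) {
  stopifnot(inherits(table, "series_table"))
  if (!predictor %in% table$predictors) {
    stop(sprintf("'%s' is not a predictor of this table", predictor),
         call. = FALSE)
  }
  R <- correlation_matrix(table)
  m <- length(table$predictors)
  iy <- m + 1L
  ii <- match(predictor, table$predictors)
  Cyy <- .cofactor(R, iy, iy)
  Cii <- .cofactor(R, ii, ii)
  if (Cyy * Cii <= 1e-24) {
    stop(sprintf("predictors are collinear (singular cofactors): %s",
                 paste(table$predictors, collapse = ", ")), call. = FALSE)
  }
  Cyi <- .cofactor(R, iy, ii)
  r <- -Cyi / sqrt(Cyy * Cii)
  r <- min(max(r, -1), 1)
  n <- sum(stats::complete.cases(table$series))
  df <- n - m - 1L
  if (df <= 0) {
    tt <- NA_real_; p <- NA_real_
  } else if (abs(r) >= 1) {
    tt <- Inf * sign(r); p <- 0
  } else {
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  list(partial_r = r, p_value = p, t_statistic = tt, df = df, n = n)
}

#' Significance of a Pearson correlation
#'
#' Two-sided p-value from `t = r sqrt((n-2) / (1-r^2))` with `n-2` degrees
#' of freedom. `method = "effective_n"` first deflates the sample size for
#' serial correlation, `n_eff = n (1 - rho1 rho2) / (1 + rho1 rho2)` with
#' the two series' lag-1 autocorrelations -- a standard heuristic for
#' autocorrelated geophysical series.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @param n sample size (pairs), `>= 3`.
#' @param method `"t_test"` (default) or `"effective_n"`.
#' @param ar1 length-2 numeric, the lag-1 autocorrelations of the two
#'   series (required for `"effective_n"`).
#' @return list with `p_value`, `t_statistic`, `df`, `n_effective`.
#' @export
correlation_significance <- function(r, n, method = c("t_test", "effective_n"),
                                     ar1 = NULL) {
  method <- match.arg(method)
  stopifnot(abs(r) <= 1, n >= 3)
  n_eff <- n
  if (method == "effective_n") {
    if (is.null(ar1) || length(ar1) != 2L) {
      stop("method 'effective_n' needs ar1 = c(rho1, rho2)", call. = FALSE)
    }
    n_eff <- n * (1 - ar1[1] * ar1[2]) / (1 + ar1[1] * ar1[2])
    n_eff <- max(n_eff, 3)
  }
  df <- n_eff - 2
  if (abs(r) == 1) {
    return(list(p_value = 0, t_statistic = Inf * sign(r), df = df,
                n_effective = n_eff, degenerate = TRUE))
  }
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  list(p_value = p, t_statistic = tt, df = df, n_effective = n_eff,
       degenerate = FALSE)
}

#' Full correlation report for a series table
#'
#' Bundles the correlation matrix, simple correlations of the response with
#' each predictor (with p-values), the cofactor-formula multiple
#' correlation, and every partial correlation.
#'
#' @param table a [series_table()].
#' @param method significance method for the simple correlations, see
#'   [correlation_significance()].
#' @return an object of class `correlation_report`.
#' @export
correlation_report <- function(table, method = c("t_test", "effective_n")) {
  method <- match.arg(method)
  R <- correlation_matrix(table)
  npair <- attr(R, "n_pairwise")
  iy <- length(table$predictors) + 1L
  simple <- lapply(seq_along(table$predictors), function(i) {
    r <- R[iy, i]
    n <- npair[iy, i]
    ar1 <- NULL
    if (method == "effective_n") {
      lag1 <- function(x) {
        x <- x[!is.na(x)]
        stats::cor(x[-length(x)], x[-1])
      }
      ar1 <- c(lag1(table$series[[i]]), lag1(table$series[[iy]]))
    }
    sig <- correlation_significance(r, n, method, ar1)
    list(predictor = table$predictors[i], r = r, p_value = sig$p_value,
         n = n)
  })
  names(simple) <- table$predictors
  partials <- lapply(table$predictors, partial_correlation, table = table)
  names(partials) <- table$predictors
  structure(list(
    R = R, response = table$response, predictors = table$predictors,
    simple = simple,
    multiple = multiple_correlation(table),
    partial = partials,
    n_complete = sum(stats::complete.cases(table$series)),
    method = method
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %s ~ %s (n = %d complete)\n",
              x$response, paste(x$predictors, collapse = " + "), x$n_complete))
  for (s in x$simple) {
    cat(sprintf("  r(%s, %s) = %+.4f  (p = %.3g, n = %d)\n",
                x$response, s$predictor, s$r, s$p_value, s$n))
  }
  cat(sprintf("  multiple R = %.4f  (p = %.3g)\n",
              x$multiple$multiple_R, x$multiple$p_value))
  for (nm in names(x$partial)) {
    p <- x$partial[[nm]]
    cat(sprintf("  partial r(%s | rest) = %+.4f  (p = %.3g)\n",
                nm, p$partial_r, p$p_value))
  }
  invisible(x)
}
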