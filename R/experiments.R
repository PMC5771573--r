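# Canonical validation experiments for the upwelling/bloom workflow: an
# analytic Ekman benchmark, the beta-term neglect audit, and paired
# synthetic-recovery experiments used by the analysis scripts and tests.

# sinusoidal stress tau_y = tau0 sin(2 pi x / L) with optional uniform tau_x;
# x is the zonal distance R cos(phi) (lambda - lambda0)
.sinusoid_case <- function(tau0, L, taux, lat, lon,
                           const = physical_constants()) {
  lam <- (lon - lon[1]) * pi / 180
  phi <- lat * pi / 180
  x <- outer(cos(phi), lam) * const$earth_radius
  ty <- tau0 * sin(2 * pi * x / L)
  curl_true <- (2 * pi * tau0 / L) * cos(2 * pi * x / L)
  arr <- function(m) array(rep(m, each = 1), dim = c(1, nrow(m), ncol(m)))
  time <- as.Date("2007-06-01")
  stress <- structure(list(
    tau_x = gridded_field("tau_x", arr(ty * 0 + taux), time, lat, lon, "N m-2"),
    tau_y = gridded_field("tau_y", arr(ty), time, lat, lon, "N m-2")
  ), class = "stress_field")
  list(stress = stress, curl_true = arr(curl_true))
}

#' Analytic Ekman pumping benchmark
#'
#' Builds the closed-form test stress `tau_y = tau0 sin(2 pi x / L)`,
#' `tau_x = 0` on a 0.125-degree grid in the 10-14N band, runs
#' [ekman_pumping()], and reports the relative RMS error of the computed
#' field against the analytic `curl(tau) / (rho f)`.
#'
#' @param tau0 stress amplitude, N m-2.
#' @param L zonal wavelength, m.
#' @param lat,lon benchmark grid, degrees.
#' @param const a [physical_constants()].
#' @return list with `rel_rms_error`, `n_cells`.
#' @export
epv_analytic_benchmark <- function(tau0 = 0.1, L = 5e5,
                                   lat = seq(10, 14, by = 0.125),
                                   lon = seq(106, 116, by = 0.125),
                                   const = physical_constants()) {
  case <- .sinusoid_case(tau0, L, 0, lat, lon, const)
  epv <- ekman_pumping(case$stress, const)
  f <- coriolis_f(lat, const)
  want <- sweep(case$curl_true, 2, const$rho_water * f, `/`)
  ok <- !is.na(epv$values)
  err <- epv$values[ok] - want[ok]
  list(rel_rms_error = sqrt(mean(err^2)) / sqrt(mean(want[ok]^2)),
       n_cells = sum(ok))
}

#' Magnitude of the planetary beta term relative to the curl term
#'
#' For a representative stress in the study band -- uniform eastward stress
#' `taux` plus a curl-bearing sinusoidal `tau_y` of amplitude `tau0` -- the
#' ratio of the largest beta-term contribution to the largest curl-term
#' contribution in the Ekman pumping velocity. Small values justify
#' neglecting the beta term.
#'
#' @param tau0,taux stress amplitudes, N m-2.
#' @param L zonal wavelength of the sinusoid, m.
#' @param lat,lon evaluation grid, degrees.
#' @param const a [physical_constants()].
#' @return list with `ratio`, `max_beta_term`, `max_curl_term` (m s-1).
#' @export
beta_term_ratio <- function(tau0 = 0.2, taux = 0.2, L = 5e5,
                            lat = seq(10, 14, by = 0.125),
                            lon = seq(106, 116, by = 0.125),
                            const = physical_constants()) {
  case <- .sinusoid_case(tau0, L, taux, lat, lon, const)
  curl_only <- ekman_pumping(case$stress, const, include_beta = FALSE)
  with_beta <- ekman_pumping(case$stress, const, include_beta = TRUE)
  beta_term <- with_beta$values - curl_only$values
  mb <- max(abs(beta_term), na.rm = TRUE)
  mc <- max(abs(curl_only$values), na.rm = TRUE)
  list(ratio = mb / mc, max_beta_term = mb, max_curl_term = mc)
}

#' Sign-recovery experiment over synthetic seeds
#'
#' Runs the full analysis on freshly generated coupled fields for each seed
#' and records the box-series correlations. A seed counts as recovered when
#' the qualitative structure built into the generator comes back out:
#' `r(chl, epv) > r(chl, et) > 0`, `r(sst, epv) < 0`, and the partial
#' correlation of chlorophyll with Ekman pumping exceeds the one with Ekman
#' transport (both controlling for the other, predictors ET + EPV).
#'
#' @param seeds integer vector of generator seeds.
#' @param config base [analysis_config()]; its synthetic seed is replaced
#'   per run.
#' @return data.frame with one row per seed: the correlations, partials and
#'   a logical `recovered`.
#' @export
sign_recovery_experiment <- function(seeds = 1:20,
                                     config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"), !is.null(config$synth))
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$synth$seed <- as.integer(s)
    b <- suppressMessages(run_full_analysis(cfg))
    up <- b$report_upwelling
    data.frame(
      seed = s,
      r_chl_epv = b$report$simple$epv$r,
      r_chl_et = b$report$simple$et$r,
      r_sst_epv = cor(b$series$sst, b$series$epv, use = "complete.obs"),
      partial_chl_epv = up$partial$epv$partial_r,
      partial_chl_et = up$partial$et$partial_r,
      multiple_R = up$multiple$multiple_R
    )
  })
  out <- do.call(rbind, rows)
  out$recovered <- out$r_chl_epv > out$r_chl_et & out$r_chl_et > 0 &
    out$r_sst_epv < 0 & out$partial_chl_epv > out$partial_chl_et
  out
}

#' Event-versus-control bloom contrast
#'
#' For each seed, generates one season with the configured late-July wind
#' intensification and one with the event amplitude set to zero (same seed,
#' hence identical noise), and compares the box-mean chlorophyll of the
#' final fifteen-day window (Aug 16-31). The intensification should raise
#' it in every pair.
#'
#' @param seeds integer vector of generator seeds.
#' @param config a [synthetic_config()] with a nonzero event amplitude.
#' @param box the chlorophyll analysis [region_box()].
#' @return data.frame with `seed`, `chl_event`, `chl_control`, `gain`.
#' @export
event_contrast_experiment <- function(seeds = 1:20,
                                      config = synthetic_config(),
                                      box = region_box(109.3, 113, 10.8, 13.8)) {
  stopifnot(inherits(config, "synthetic_config"), config$event_amplitude > 0)
  final_chl <- function(cfg) {
    g <- generate_coupled_fields(cfg)
    cmp <- composite(g$chl, composite_spec("fifteen_day"))
    last <- length(cmp$time)
    area_mean_series(cmp, box)$value[last]
  }
  rows <- lapply(seeds, function(s) {
    ev <- config; ev$seed <- as.integer(s)
    ct <- ev; ct$event_amplitude <- 0
    a <- final_chl(ev); b <- final_chl(ct)
    data.frame(seed = s, chl_event = a, chl_control = b, gain = a - b)
  })
  do.call(rbind, rows)
}
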