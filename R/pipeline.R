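#' End-to-end analysis configuration
#'
#' One configuration object drives the whole pipeline: synthetic generation
#' (or NetCDF inputs), Ekman forcing, composites, EOF decomposition, box
#' series and the correlation report. Defaults encode the canonical
#' analysis: chlorophyll/EPV box 109.3-113E, 10.8-13.8N; Ekman-transport box
#' 109-112E, 9.5-14.5N; summer season 1 Jun - 31 Aug; sea-water density
#' 1025 kg m-3; first EOF mode retained.
#'
#' @param synth a [synthetic_config()], or `NULL` when `inputs` are given.
#' @param inputs named list of NetCDF paths (`u10`, `v10`, `sst`, `chl`),
#'   or `NULL` to generate synthetic fields.
#' @param chl_box,et_box [region_box()]s for the chlorophyll/EPV and
#'   Ekman-transport analyses.
#' @param coast a [coastline_spec()].
#' @param const a [physical_constants()].
#' @param climatology_years years pooled by climatology composites.
#' @param eof_n_modes EOF modes retained (default 1, the leading mode).
#' @param eof_baseline anomaly baseline for the EOFs.
#' @param area_weighting `"cos_lat"` or `"none"` for box means.
#' @param sig_method significance method for simple correlations.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(synth = synthetic_config(),
                            inputs = NULL,
                            chl_box = region_box(109.3, 113, 10.8, 13.8),
                            et_box = region_box(109, 112, 9.5, 14.5),
                            coast = coastline_spec(),
                            const = physical_constants(),
                            climatology_years = 1998:2014,
                            eof_n_modes = 1,
                            eof_baseline = c("time_mean", "climatology"),
                            area_weighting = c("cos_lat", "none"),
                            sig_method = c("t_test", "effective_n")) {
  eof_baseline <- match.arg(eof_baseline)
  area_weighting <- match.arg(area_weighting)
  sig_method <- match.arg(sig_method)
  if (is.null(synth) && is.null(inputs)) {
    stop("provide either a synthetic config or input paths", call. = FALSE)
  }
  structure(list(synth = synth, inputs = inputs,
                 chl_box = chl_box, et_box = et_box, coast = coast,
                 const = const, climatology_years = climatology_years,
                 eof_n_modes = eof_n_modes, eof_baseline = eof_baseline,
                 area_weighting = area_weighting, sig_method = sig_method),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [analysis_config()] (boxes as `[lon_min, lon_max, lat_min, lat_max]`,
#' `synth` as a mapping of [synthetic_config()] arguments).
#'
#' @param path YAML file path.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synthetic_config, y$synth)
  if (!is.null(y$inputs)) { args$inputs <- y$inputs; if (is.null(y$synth)) args$synth <- NULL }
  for (bx in c("chl_box", "et_box")) {
    if (!is.null(y[[bx]])) args[[bx]] <- do.call(region_box, as.list(y[[bx]]))
  }
  if (!is.null(y$coast_angle)) args$coast <- coastline_spec(y$coast_angle)
  for (nm in c("climatology_years", "eof_n_modes", "eof_baseline",
               "area_weighting", "sig_method")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(analysis_config, args)
}

.stage_log <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(log, sprintf("[%s] %s", stage, msg))
}

#' Run the full upwelling/bloom analysis
#'
#' Executes the pipeline end to end: ingest or generate the fields, compute
#' wind stress, Ekman pumping and transport, build fifteen-day and seasonal
#' composites (plus a multi-year climatology when several years are
#' present), decompose SST and chlorophyll anomalies into EOFs, average the
#' analysis boxes into time series, and assemble the correlation report
#' linking chlorophyll to SST, ET and EPV. Deterministic given the
#' configuration (and its seed).
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, composites are written as
#'   NetCDF, the correlation report and run log as JSON.
#' @return an object of class `results_bundle`: fields, forcing, composites,
#'   `eof` (SST and chl), `series` (box-averaged data.frame), `report`
#'   (correlation_report for predictors SST, ET, EPV) and
#'   `report_upwelling` (predictors ET, EPV only), `log`, `config`.
#' @export
run_full_analysis <- function(config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character(0)

  if (!is.null(config$inputs)) {
    for (nm in c("u10", "v10", "sst", "chl")) {
      if (is.null(config$inputs[[nm]]) || !file.exists(config$inputs[[nm]])) {
        stop(sprintf("input file for '%s' missing: %s", nm,
                     if (is.null(config$inputs[[nm]])) "(not configured)"
                     else config$inputs[[nm]]), call. = FALSE)
      }
    }
    fields <- Map(read_gridded, config$inputs[c("u10", "v10", "sst", "chl")],
                  c("u10", "v10", "sst", "chl"))
    names(fields) <- c("u10", "v10", "sst", "chl")
    truth <- NULL
    log <- .stage_log(log, "ingest", "read %d NetCDF inputs", length(fields))
    # common analysis grid: everything is brought to the wind grid
    for (nm in c("sst", "chl")) {
      f <- fields[[nm]]
      if (!isTRUE(all.equal(f$lat, fields$u10$lat)) ||
          !isTRUE(all.equal(f$lon, fields$u10$lon))) {
        fields[[nm]] <- regrid_bilinear(f, fields$u10$lat, fields$u10$lon)
        log <- .stage_log(log, "regrid", "%s -> wind grid", nm)
      }
    }
  } else {
    gen <- generate_coupled_fields(config$synth, config$const)
    fields <- gen[c("u10", "v10", "sst", "chl")]
    truth <- gen$truth
    log <- .stage_log(log, "synth", "generated fields (seed %d, hash %s)",
                      config$synth$seed, rlang::hash(unclass(config$synth)))
  }

  stress <- wind_stress(fields$u10, fields$v10, config$const)
  epv <- ekman_pumping(stress, config$const)
  et <- ekman_transport(stress, config$coast, config$const)
  log <- .stage_log(log, "ekman", "EPV/ET on %d x %d grid, %d steps",
                    length(epv$lat), length(epv$lon), length(epv$time))

  years_present <- unique(as.integer(format(fields$sst$time, "%Y")))
  composites <- list(
    chl_fifteen_day = composite(fields$chl, composite_spec("fifteen_day")),
    sst_fifteen_day = composite(fields$sst, composite_spec("fifteen_day")),
    epv_fifteen_day = composite(epv, composite_spec("fifteen_day")),
    chl_seasonal = composite(fields$chl, composite_spec("seasonal_mean")),
    sst_seasonal = composite(fields$sst, composite_spec("seasonal_mean"))
  )
  if (length(years_present) > 1L) {
    yrs <- intersect(config$climatology_years, years_present)
    if (length(yrs) > 1L) {
      composites$chl_climatology <-
        composite(fields$chl, composite_spec("climatology", years = yrs))
      composites$sst_climatology <-
        composite(fields$sst, composite_spec("climatology", years = yrs))
    }
  }
  log <- .stage_log(log, "composite", "%d composite products",
                    length(composites))

  # EOFs are computed on monthly composites: cloud gaps in daily Chl-a leave
  # no cell with a complete daily record, while monthly means average them out
  eof <- list(
    sst = eof_decompose(
      build_anomalies(composite(fields$sst, composite_spec("monthly")),
                      config$eof_baseline), config$eof_n_modes),
    chl = eof_decompose(
      build_anomalies(composite(fields$chl, composite_spec("monthly")),
                      config$eof_baseline), config$eof_n_modes)
  )
  log <- .stage_log(log, "eof",
                    "first-mode variance: SST %.1f%%, Chl %.1f%%",
                    eof$sst$variance_fraction[1], eof$chl$variance_fraction[1])

  w <- config$area_weighting
  series <- data.frame(
    time = fields$chl$time,
    chl = area_mean_series(fields$chl, config$chl_box, w)$value,
    sst = area_mean_series(fields$sst, config$chl_box, w)$value,
    epv = area_mean_series(epv, config$chl_box, w)$value,
    et = area_mean_series(et, config$et_box, w)$value
  )
  log <- .stage_log(log, "series", "%d time steps, %d complete",
                    nrow(series), sum(stats::complete.cases(series[-1])))

  report <- correlation_report(
    series_table(series, "chl", c("sst", "et", "epv")), config$sig_method)
  report_upwelling <- correlation_report(
    series_table(series, "chl", c("et", "epv")), config$sig_method)
  log <- .stage_log(log, "correlate",
                    "r(chl,epv)=%.3f r(chl,et)=%.3f multiple R(et,epv)=%.3f",
                    report$simple$epv$r, report$simple$et$r,
                    report_upwelling$multiple$multiple_R)

  bundle <- structure(list(
    fields = fields, truth = truth, epv = epv, et = et,
    composites = composites, eof = eof, series = series,
    report = report, report_upwelling = report_upwelling,
    log = log, config = config,
    version = as.character(utils::packageVersion("ekmanbloom"))
  ), class = "results_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(composites)) {
      write_gridded(composites[[nm]], file.path(out_dir, paste0(nm, ".nc")))
    }
    jsonlite::write_json(report_to_list(bundle),
                         file.path(out_dir, "correlation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  bundle
}

#' Flatten a results bundle's correlation output for serialization
#'
#' @param bundle a [run_full_analysis()] result.
#' @return a plain list (JSON-ready) with the simple, multiple and partial
#'   correlations of both reports.
#' @export
report_to_list <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  pick <- function(rep) list(
    predictors = rep$predictors,
    R = unname(as.matrix(rep$R)),
    simple = lapply(rep$simple, function(s)
      list(r = s$r, p_value = s$p_value, n = unname(s$n))),
    multiple_R = rep$multiple$multiple_R,
    multiple_p = rep$multiple$p_value,
    partial = lapply(rep$partial, function(p)
      list(r = p$partial_r, p_value = p$p_value)),
    n_complete = rep$n_complete
  )
  list(full = pick(bundle$report),
       upwelling_only = pick(bundle$report_upwelling),
       version = bundle$version)
}
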