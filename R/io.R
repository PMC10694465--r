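#' Read and write gridded daily fields as plain-text tables
#'
#' Gridded day-by-cell fields are serialized to a long-format CSV (one row
#' per day-cell, one column per variable) with a JSON sidecar
#' (`<path>.meta.json`) carrying the grid georeference, calendar and
#' scenario metadata, so a write/read round trip reproduces the object to
#' float precision.
#'
#' @param x a `climate_field` or `wbgt_daily` object.
#' @param path output CSV path.
#' @return `write_gridded_csv` returns `path` invisibly;
#'   `read_climate_field` / `read_wbgt_daily` return the reconstructed
#'   object.
#' @export
write_gridded_csv <- function(x, path) {
  stopifnot(inherits(x, c("climate_field", "wbgt_daily")))
  vars <- intersect(c("tas", "tasmax", "hurs", "sfcWind", "rsds",
                      "mean_indoor", "max_indoor", "mean_outdoor",
                      "max_outdoor"), names(x))
  ndays <- nrow(x[[vars[1]]]); ncell <- ncol(x[[vars[1]]])
  df <- data.frame(day = rep(seq_len(ndays), times = ncell),
                   cell = rep(seq_len(ncell), each = ndays))
  for (v in vars) df[[v]] <- as.vector(x[[v]])
  utils::write.csv(df, path, row.names = FALSE)
  g <- x$grid
  meta <- list(class = class(x)[1], vars = vars,
               year = x$year, doy = x$doy,
               scenario = x$scenario, gcm = x$gcm,
               grid = list(rows = g$rows, cols = g$cols, cell_km = g$cell_km,
                           lat = g$lat, province = g$province,
                           province_names = g$province_names))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_gridded_csv <- function(path, expect_class) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  if (!identical(meta$class, expect_class))
    stop("file holds a ", meta$class, ", expected ", expect_class)
  df <- utils::read.csv(path)
  ndays <- length(meta$year)
  g <- meta$grid
  grid <- structure(list(rows = g$rows, cols = g$cols, cell_km = g$cell_km,
                         lat = g$lat, province = g$province,
                         province_names = g$province_names),
                    class = "whl_grid")
  out <- list()
  for (v in meta$vars) out[[v]] <- matrix(df[[v]], nrow = ndays)
  out$year <- meta$year; out$doy <- meta$doy
  out$scenario <- meta$scenario; out$gcm <- meta$gcm; out$grid <- grid
  structure(out, class = expect_class)
}

#' @rdname write_gridded_csv
#' @param path CSV path written by [write_gridded_csv()].
#' @export
read_climate_field <- function(path) .read_gridded_csv(path, "climate_field")

#' @rdname write_gridded_csv
#' @export
read_wbgt_daily <- function(path) .read_gridded_csv(path, "wbgt_daily")

#' Work/rest table CSV adapters
#'
#' @param table a `workrest_table` data frame.
#' @param path CSV path with header `intensity_w, wbgt_c, work_fraction`.
#' @return the table (validated on read; malformed values are rejected
#'   with the offending column named).
#' @export
write_workrest_csv <- function(table, path) {
  table <- validate_workrest_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_workrest_csv
#' @export
read_workrest_csv <- function(path) {
  validate_workrest_table(utils::read.csv(path))
}

#' Exposure-response parameter YAML adapters
#'
#' @param params an [erf_params()].
#' @param path YAML path.
#' @return the parameters (round-trip preserves values and provenance).
#' @export
write_erf_yaml <- function(params, path) {
  params <- validate_erf_params(params)
  yaml::write_yaml(list(provenance = attr(params, "provenance"),
                        intensity_w = params$intensity_w,
                        prodmean = params$prodmean,
                        prodsd = params$prodsd), path)
  invisible(path)
}

#' @rdname write_erf_yaml
#' @export
read_erf_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ord <- match(c(200, 300, 400), y$intensity_w)
  erf_params(y$prodmean[ord], y$prodsd[ord], provenance = y$provenance)
}

#' Read a labelled province raster from CSV
#'
#' The CSV holds one row per grid row and one column per grid column,
#' each entry the province label of that cell. Empty or NA entries are a
#' coverage error reported with the offending cell indices.
#'
#' @param path CSV path (no header).
#' @return character vector of per-cell labels, column-major.
#' @export
read_province_raster <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE,
                                 colClasses = "character"))
  lab <- as.vector(m)                      # column-major like the grid
  lab[lab == ""] <- NA_character_
  if (anyNA(lab))
    stop("cells in no province at indices: ",
         paste(utils::head(which(is.na(lab)), 20), collapse = ", "))
  lab
}

# ---------------------------------------------------------------------------
# pipeline

#' Validate a pipeline run configuration
#'
#' @param config named list; recognized fields: `scenarios`, `years`,
#'   `grid_shape`, `n_pseudo_gcms`, `seed`, `peak_year`, `peak_total`,
#'   `ac_rate`, `ac_target`, `fertility` (low/moderate/high), `erf_source`
#'   (`"calibrated"` or `"global-anchor"`), `delay` (workday shift, h),
#'   `unit_value` (USD/h), `out_dir`.
#' @return the config with defaults filled in, or an error.
#' @export
validate_run_config <- function(config) {
  defaults <- list(scenarios = c("rcp26", "rcp45", "rcp85"),
                   years = seq(1986, 2100, by = 5), grid_shape = c(8, 8),
                   n_pseudo_gcms = 2, seed = 1,
                   peak_year = 2030, peak_total = 0.75e9,
                   ac_rate = 0.6, ac_target = NULL,
                   fertility = "moderate", erf_source = "calibrated",
                   delay = 0, unit_value = 5, out_dir = tempfile("whlrun"))
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$scenarios, names(.scenario_defaults))
  if (length(bad))
    stop("unknown scenario id(s): ", paste(bad, collapse = ", "))
  if (!config$fertility %in% c("low", "moderate", "high"))
    stop("fertility must be one of low/moderate/high")
  if (!config$erf_source %in% c("calibrated", "global-anchor"))
    stop("erf_source must be 'calibrated' or 'global-anchor'")
  if (config$peak_year < min(config$years) ||
      config$peak_year > max(config$years))
    stop("peak_year must lie within the simulated year range")
  config
}

#' Run the full synthetic projection pipeline
#'
#' Executes generate -> WBGT -> ERF calibration -> exposure -> WHL ->
#' attribution/benefit for every requested scenario, writes the summary
#' CSVs and a manifest (config, seed, package version, output checksums)
#' that makes the run reproducible bit for bit, and returns the in-memory
#' results.
#'
#' The attribution stage decomposes the change in national WHL from the
#' first to the last simulated 20-year window into climate, population
#' and interaction effects; the benefit stage (when `"cool15"` is among
#' the scenarios, or `benefit = TRUE` adds it) computes the mid-century
#' avoided WHL of the 1.5-degree analogue against each RCP scenario and
#' its human-capital economic value.
#'
#' @param config a run configuration (see [validate_run_config()]).
#' @param benefit compute the 1.5-degree benefit stage (default `TRUE`).
#' @return invisibly, a list with per-scenario `whl_result`s, summary
#'   tables, decompositions, benefits, the ERF used and the manifest path.
#' @export
run_pipeline <- function(config = list(), benefit = TRUE) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # exposure inputs are scenario-independent
  cfg0 <- synth_config(grid_shape = config$grid_shape, years = config$years,
                       scenario = config$scenarios[1],
                       n_pseudo_gcms = config$n_pseudo_gcms,
                       seed = config$seed)
  popin <- generate_population_inputs(cfg0, peak_year = config$peak_year,
                                      peak_total = config$peak_total,
                                      ac_rate = config$ac_rate)
  fmult <- popin$fertility[[config$fertility]]
  workers <- working_population(popin$pop, popin$rates,
                                fertility_multiplier = fmult)
  ac <- if (is.null(config$ac_target)) config$ac_rate else
    ac_rate_path(config$years, current = config$ac_rate,
                 target = config$ac_target)
  exposed <- apply_ac_adjustment(workers, ac)

  # ERF: fit the occupational standard, transfer onto the anchor
  inputs <- default_erf_inputs()
  tab <- generate_workrest_table(inputs$standard, seq(24, 40, by = 2),
                                 noise_sd = 0, seed = config$seed)
  standard_fit <- fit_workrest_cdf(tab)
  params <- if (config$erf_source == "calibrated")
    calibrate_chinese_erf(standard_fit, inputs$anchor300)
  else erf_params(c(inputs$anchor300[1] + 3, inputs$anchor300[1],
                    inputs$anchor300[1] - 2),
                  rep(inputs$anchor300[2], 3), provenance = "global-anchor")
  write_erf_yaml(params, file.path(config$out_dir, "erf_params.yaml"))

  workday <- workday_def(delay = config$delay)
  scenarios <- config$scenarios
  if (benefit && !"cool15" %in% scenarios) scenarios <- c(scenarios, "cool15")
  results <- list(); summaries <- list(); wbgt_mid <- list()
  mid <- period_def("middle", 2051, 2070)
  for (sc in scenarios) {
    cfg <- synth_config(grid_shape = config$grid_shape, years = config$years,
                        scenario = sc, n_pseudo_gcms = config$n_pseudo_gcms,
                        seed = config$seed)
    ens <- generate_climate(cfg)
    results[[sc]] <- project_whl(ens, exposed, params, workday)
    summaries[[sc]] <- aggregate_whl(results[[sc]], "province")
    wbgt_mid[[sc]] <- climate_to_wbgt(ens$members[[1]])
  }
  summary_tab <- do.call(rbind, summaries)
  utils::write.csv(summary_tab,
                   file.path(config$out_dir, "whl_by_province.csv"),
                   row.names = FALSE)

  # driver decomposition: first vs last simulated 20-year window
  yrs <- config$years
  p0 <- period_def("start", yrs[1], yrs[1] + 19)
  p1 <- period_def("end", max(yrs) - 19, max(yrs))
  decomp <- lapply(results[config$scenarios], function(res) {
    pcm <- function(p) {      # ensemble-mean per-capita [cell x sector]
      yr <- res$years >= p$start_year & res$years <= p$end_year
      apply(res$per_capita[, yr, , , drop = FALSE], c(3, 4), mean)
    }
    popm <- function(p) {
      yr <- exposed$years >= p$start_year & exposed$years <= p$end_year
      apply(exposed$workers[yr, , , drop = FALSE], c(2, 3), mean)
    }
    factor_separation(function(cl, pp) sum(cl * pp),
                      pcm(p0), pcm(p1), popm(p0), popm(p1))
  })
  decomp_tab <- do.call(rbind, lapply(names(decomp), function(sc) {
    d <- decomp[[sc]]
    data.frame(scenario = sc, total = d$total_change,
               climate = d$climate_effect, population = d$population_effect,
               interaction = d$interaction_effect)
  }))
  utils::write.csv(decomp_tab, file.path(config$out_dir, "whl_drivers.csv"),
                   row.names = FALSE)

  benefits <- NULL
  if (benefit) {
    benefits <- lapply(config$scenarios, function(sc) {
      b <- avoided_whl_15C(wbgt_mid[[sc]], wbgt_mid[["cool15"]], exposed,
                           params, period = mid, workday = workday)
      data.frame(scenario = sc, avoided_whl = b$national,
                 avoided_per_capita = b$per_capita,
                 economic_cost_usd = economic_cost_hc(b$national,
                                                      config$unit_value))
    })
    benefits <- do.call(rbind, benefits)
    utils::write.csv(benefits,
                     file.path(config$out_dir, "benefit_15C.csv"),
                     row.names = FALSE)
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_out <- config; cfg_out$out_dir <- NULL
  jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA)
  outputs <- setdiff(list.files(config$out_dir, full.names = TRUE),
                     file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("heatwhl")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, summary = summary_tab,
                 decomposition = decomp_tab, benefits = benefits,
                 params = params, exposed = exposed,
                 manifest = file.path(config$out_dir, "manifest.json"),
                 out_dir = config$out_dir))
}
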