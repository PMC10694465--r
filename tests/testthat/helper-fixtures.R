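# small shared fixtures; everything is generated in code at test time

tiny_cfg <- function(scenario = "rcp85", years = c(1990, 2050, 2090),
                     grid = c(4, 4), gcms = 1, seed = 42, ...) {
  synth_config(grid_shape = grid, years = years, scenario = scenario,
               n_pseudo_gcms = gcms, seed = seed, ...)
}

# calibrated ERF used across the WHL tests
tiny_erf <- function() {
  inp <- default_erf_inputs()
  calibrate_chinese_erf(fit_workrest_cdf(generate_workrest_table(inp$standard)),
                        inp$anchor300)
}

# a flat erf (same curve at all intensities) for closed-form checks
flat_erf <- function(m = 33, s = 4) {
  erf_params(prodmean = c(m, m, m), prodsd = c(s, s, s),
             provenance = "global-anchor")
}

# hand-built single-cell wbgt_daily with constant mean = max = value
constant_wbgt_daily <- function(value, ndays = 100, year = 2060,
                                grid = make_grid(1, 1)) {
  m <- matrix(value, ndays, grid$rows * grid$cols)
  structure(list(mean_indoor = m, max_indoor = m,
                 mean_outdoor = m, max_outdoor = m,
                 year = rep(year, ndays), doy = seq_len(ndays),
                 grid = grid, scenario = "toy", gcm = 1),
            class = "wbgt_daily")
}

# exposed population with given worker counts in one sector, zeros elsewhere
toy_exposed <- function(workers, sector = "agriculture", years = 2060,
                        grid = make_grid(1, 1)) {
  st <- heatwhl:::sector_table()
  ncell <- grid$rows * grid$cols
  arr <- array(0, c(length(years), ncell, 4),
               dimnames = list(NULL, NULL, st$sector))
  arr[, , sector] <- workers
  structure(list(workers = arr, years = years, grid = grid, sectors = st),
            class = c("exposed_population", "sector_population"))
}

run_scenario_whl <- function(scenario, years = seq(1986, 2100, 5),
                             grid = c(8, 8), gcms = 2, seed = 1,
                             ac = 0.6, erf = tiny_erf()) {
  cfg <- synth_config(grid_shape = grid, years = years, scenario = scenario,
                      n_pseudo_gcms = gcms, seed = seed)
  ens <- generate_climate(cfg)
  peak <- min(max(2030, min(years)), max(years))
  pin <- generate_population_inputs(cfg, peak_year = peak)
  exposed <- apply_ac_adjustment(working_population(pin$pop, pin$rates), ac)
  project_whl(ens, exposed, erf)
}
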