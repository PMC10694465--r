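#' Synthetic study-domain grid with rectangular toy provinces
#'
#' Builds the rectangular analysis grid used throughout the package. Cell
#' latitudes decrease along rows from `lat_max` to `lat_min` (row 1 is the
#' northernmost), longitude varies along columns but plays no role in the
#' synthetic climate. Provinces are axis-aligned rectangles given as a data
#' frame with columns `name`, `row_min`, `row_max`, `col_min`, `col_max`;
#' every cell must fall in exactly one province (cell-center containment is
#' trivial for rectangles). The default layout splits the grid into three
#' vertical bands named "West", "Centre", "East".
#'
#' @param rows,cols grid dimensions (cells).
#' @param cell_km cell size in km (metadata only; the synthetic grid nests
#'   exactly so regridding never needs true georeferencing).
#' @param lat_min,lat_max latitude range (degrees N) spanned by the rows.
#' @param province_layout data frame describing rectangular provinces, or
#'   `NULL` for the default three vertical bands.
#' @return an object of class `whl_grid`: list with `rows`, `cols`,
#'   `cell_km`, `lat` (per-cell latitude, column-major), `province`
#'   (per-cell province label), `province_names`.
#' @export
make_grid <- function(rows, cols, cell_km = 50, lat_min = 20, lat_max = 45,
                      province_layout = NULL) {
  stopifnot(rows >= 1, cols >= 1, cell_km > 0, lat_max > lat_min)
  if (is.null(province_layout)) {
    cuts <- unique(round(seq(0, cols, length.out = min(3, cols) + 1)))
    nms <- c("West", "Centre", "East")[seq_len(length(cuts) - 1)]
    province_layout <- data.frame(
      name = nms,
      row_min = 1, row_max = rows,
      col_min = head(cuts, -1) + 1, col_max = cuts[-1],
      stringsAsFactors = FALSE
    )
  }
  req <- c("name", "row_min", "row_max", "col_min", "col_max")
  if (!all(req %in% names(province_layout)))
    stop("province_layout must have columns: ", paste(req, collapse = ", "))
  lat_row <- seq(lat_max, lat_min, length.out = rows)
  lat <- rep(lat_row, times = cols)                       # column-major cells
  prov <- rep(NA_character_, rows * cols)
  for (k in seq_len(nrow(province_layout))) {
    p <- province_layout[k, ]
    rr <- p$row_min:p$row_max
    cc <- p$col_min:p$col_max
    idx <- as.vector(outer(rr, (cc - 1) * rows, `+`))
    if (any(!is.na(prov[idx])))
      stop("province_layout overlaps at cells: ",
           paste(head(idx[!is.na(prov[idx])], 10), collapse = ", "))
    prov[idx] <- p$name
  }
  if (anyNA(prov))
    stop("cells not covered by any province: ",
         paste(head(which(is.na(prov)), 10), collapse = ", "))
  structure(list(rows = rows, cols = cols, cell_km = cell_km,
                 lat = lat, province = prov,
                 province_names = unique(province_layout$name)),
            class = "whl_grid")
}

#' @export
print.whl_grid <- function(x, ...) {
  cat(sprintf("<whl_grid> %d x %d cells (%g km), %d provinces: %s\n",
              x$rows, x$cols, x$cell_km, length(x$province_names),
              paste(x$province_names, collapse = ", ")))
  invisible(x)
}

# scenario defaults: warming rate (degC/decade at end of century) and
# stabilization year (trend flat afterwards; Inf = never)
.scenario_defaults <- list(
  rcp26  = list(warming_rate = 0.20, stabilization_year = 2050),
  rcp45  = list(warming_rate = 0.35, stabilization_year = Inf),
  rcp85  = list(warming_rate = 0.50, stabilization_year = Inf),
  cool15 = list(warming_rate = 0.20, stabilization_year = 2035)
)

#' Configuration for the synthetic study domain
#'
#' Bundles every knob of the synthetic generator. Scenario ids follow the
#' RCP family (`rcp26`, `rcp45`, `rcp85`) plus `cool15`, a 1.5-degree
#' analogue generated like `rcp26` but stabilizing earlier. Defaults for
#' `warming_rate` and `stabilization_year` come from the scenario id and can
#' be overridden. Identical configuration and seed reproduce every generated
#' array bit for bit.
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param years integer vector of calendar years to simulate (365-day
#'   no-leap calendar; may be a sampled subset, e.g. every 5th year).
#' @param scenario one of `"rcp26"`, `"rcp45"`, `"rcp85"`, `"cool15"`.
#' @param warming_rate linear warming trend, degC per decade, reached by the
#'   end of the century; `NULL` uses the scenario default.
#' @param stabilization_year year after which the trend is flat; `NULL` uses
#'   the scenario default (`Inf` for rcp45/rcp85).
#' @param n_pseudo_gcms number of pseudo-GCM ensemble members (>= 1); each
#'   member gets independent weather noise and a small trend perturbation.
#' @param seed integer master seed.
#' @param cell_size_km,province_layout,lat_range passed to [make_grid()].
#' @param ar1 daily AR(1) autocorrelation of the temperature noise.
#' @param noise_sd marginal standard deviation (degC) of daily temperature
#'   noise; 0 gives a fully deterministic climate.
#' @param humidity_temp_coef humidity response to temperature anomaly, in
#'   percentage points per degC (negative = drier when hot).
#' @param trend_jitter half-range of the multiplicative trend perturbation
#'   across pseudo-GCMs (members span `1 +/- trend_jitter`).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(8, 8), years = 1986:2100,
                         scenario = "rcp26",
                         warming_rate = NULL, stabilization_year = NULL,
                         n_pseudo_gcms = 1, seed = 1,
                         cell_size_km = 50, province_layout = NULL,
                         lat_range = c(20, 45),
                         ar1 = 0.7, noise_sd = 2,
                         humidity_temp_coef = -1, trend_jitter = 0.08) {
  scenario <- match.arg(scenario, names(.scenario_defaults))
  if (length(years) < 1L) stop("years must be non-empty")
  if (any(grid_shape < 1) || length(grid_shape) != 2L)
    stop("grid_shape must be two positive integers")
  if (n_pseudo_gcms < 1) stop("n_pseudo_gcms must be >= 1")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  def <- .scenario_defaults[[scenario]]
  if (is.null(warming_rate)) warming_rate <- def$warming_rate
  if (is.null(stabilization_year)) stabilization_year <- def$stabilization_year
  grid <- make_grid(grid_shape[1], grid_shape[2], cell_km = cell_size_km,
                    lat_min = lat_range[1], lat_max = lat_range[2],
                    province_layout = province_layout)
  structure(list(grid = grid, years = sort(unique(as.integer(years))),
                 scenario = scenario, warming_rate = warming_rate,
                 stabilization_year = stabilization_year,
                 n_pseudo_gcms = as.integer(n_pseudo_gcms),
                 seed = as.integer(seed),
                 ar1 = ar1, noise_sd = noise_sd,
                 humidity_temp_coef = humidity_temp_coef,
                 trend_jitter = trend_jitter),
            class = "synth_config")
}

# deterministic per-(scenario, gcm) seed below 2^31
.derive_seed <- function(seed, scenario, gcm) {
  scen_idx <- match(scenario, names(.scenario_defaults))
  (abs(seed) %% 1000003L) * 1009L + scen_idx * 101L + gcm
}

# trend (degC above the first simulated year) for calendar year y
.trend_degC <- function(cfg, years, gcm_factor = 1) {
  slope <- cfg$warming_rate / 10 * gcm_factor
  eff <- pmin(years, cfg$stabilization_year)
  slope * (eff - cfg$years[1])
}

# multiplicative trend perturbation per pseudo-GCM member
.gcm_factors <- function(cfg) {
  n <- cfg$n_pseudo_gcms
  if (n == 1L) return(1)
  1 + cfg$trend_jitter * seq(-1, 1, length.out = n)
}

# AR(1) recursion down the rows of a [ndays x ncell] innovation matrix
.ar1_filter <- function(innov, phi) {
  if (phi == 0) return(innov)
  out <- innov
  for (j in seq_len(ncol(innov)))
    out[, j] <- as.numeric(stats::filter(innov[, j], phi, method = "recursive"))
  out
}

#' Generate gridded daily meteorology for one scenario
#'
#' Produces the five daily variables the WBGT pipeline consumes --- mean and
#' maximum near-surface air temperature (`tas`, `tasmax`, degC), relative
#' humidity (`hurs`, %), wind speed (`sfcWind`, m/s) and downwelling
#' shortwave radiation (`rsds`, W/m2) --- on a 365-day calendar for every
#' year in the configuration and every pseudo-GCM member.
#'
#' The temperature model is a latitudinal gradient plus a sinusoidal
#' seasonal cycle peaking in mid-July, a scenario-specific linear trend
#' (flat after the stabilization year), and AR(1) daily noise. `tasmax`
#' exceeds `tas` by a seasonally varying half diurnal range; humidity is
#' anticorrelated with the temperature anomaly and clipped to [0, 100];
#' wind and radiation are non-negative with their own noise, radiation with
#' a seasonal cycle. Pseudo-GCM members differ by their noise stream and a
#' small multiplicative trend perturbation.
#'
#' @param cfg a [synth_config()].
#' @return object of class `climate_ensemble`: list with `members` (one
#'   `climate_field` per pseudo-GCM: matrices `[day x cell]` named `tas`,
#'   `tasmax`, `hurs`, `sfcWind`, `rsds` plus calendar vectors `year`,
#'   `doy`) and the originating `cfg`.
#' @export
generate_climate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- cfg$grid
  ncell <- grid$rows * grid$cols
  nyears <- length(cfg$years)
  ndays <- nyears * 365L
  day_year <- rep(cfg$years, each = 365L)
  doy <- rep(1:365, times = nyears)

  # deterministic climatology, identical across members
  # subtropical-to-temperate climatology: annual-mean tas ~22 degC at the
  # southern edge falling ~0.6 degC per degree of latitude, summer peak
  # daily means near 29-30 degC in the south
  tbar <- 22 - 0.6 * (grid$lat - min(grid$lat))            # per cell
  amp <- 7 + 0.15 * (grid$lat - min(grid$lat))             # seasonal amplitude
  season <- cos(2 * pi * (doy - 196) / 365)                # +1 mid-July
  clim <- outer(season, amp) + matrix(tbar, ndays, ncell, byrow = TRUE)
  half_drange <- 4 + 1 * season                            # tasmax - tas >= 3
  rsds_clim <- 180 + 90 * season

  factors <- .gcm_factors(cfg)
  members <- vector("list", cfg$n_pseudo_gcms)
  for (g in seq_len(cfg$n_pseudo_gcms)) {
    trend <- .trend_degC(cfg, day_year, factors[g])        # per day
    set.seed(.derive_seed(cfg$seed, cfg$scenario, g))
    if (cfg$noise_sd > 0) {
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1^2)
      tnoise <- .ar1_filter(matrix(stats::rnorm(ndays * ncell, sd = innov_sd),
                                   ndays, ncell), cfg$ar1)
    } else tnoise <- matrix(0, ndays, ncell)
    hnoise <- matrix(stats::rnorm(ndays * ncell, sd = 5), ndays, ncell)
    wnoise <- .ar1_filter(matrix(stats::rnorm(ndays * ncell, sd = 1), ndays, ncell), 0.5)
    rnoise <- matrix(stats::rnorm(ndays * ncell, sd = 25), ndays, ncell)

    tas <- clim + trend + tnoise
    anomaly <- tas - matrix(tbar, ndays, ncell, byrow = TRUE)
    members[[g]] <- structure(list(
      tas = tas,
      tasmax = tas + half_drange,                          # >= tas everywhere
      hurs = pmin(pmax(70 + cfg$humidity_temp_coef * anomaly + hnoise, 0), 100),
      sfcWind = pmax(3 + wnoise, 0),
      rsds = pmax(rsds_clim + rnoise, 0),
      year = day_year, doy = doy, grid = grid,
      scenario = cfg$scenario, gcm = g
    ), class = "climate_field")
  }
  structure(list(members = members, cfg = cfg), class = "climate_ensemble")
}

#' @export
print.climate_ensemble <- function(x, ...) {
  f <- x$members[[1]]
  cat(sprintf("<climate_ensemble> %s: %d member(s), %d years x 365 d, %d cells\n",
              x$cfg$scenario, length(x$members),
              length(unique(f$year)), ncol(f$tas)))
  invisible(x)
}

#' Generate gridded population and province rates tables
#'
#' National total population follows a smooth bell-shaped trajectory rising
#' to `peak_total` persons in `peak_year` and declining afterwards,
#' emulating a working population that grows, peaks around 2030, then
#' shrinks. The national total is split across provinces by fixed random
#' shares and within each province across cells by fixed random weights, so
#' per-province totals are exactly conserved on the grid. Urbanization rises
#' along a logistic path per province; the agriculture and non-agriculture
#' employment rates are constant over time (the pipeline's standing
#' assumption); the sector split of non-agricultural employment and the AC
#' penetration rate are constant defaults. Fertility-scenario multipliers
#' (low/moderate/high) are returned as scalar paths applied to population.
#'
#' @param cfg a [synth_config()] (grid, years and seed are used).
#' @param peak_year calendar year of the national population peak; must lie
#'   within `cfg$years`.
#' @param peak_total national population at the peak (persons).
#' @param ac_rate current air-conditioning penetration rate (fraction of
#'   indoor workers protected), default 0.6.
#' @param sector_split length-3 fractions (construction, manufacturing,
#'   service) of non-agricultural employment; must sum to 1.
#' @return list with `pop` (class `population_raster`: matrix
#'   `[year x cell]`, plus `years` and `grid`), `rates` (province-year data
#'   frame with urban/rural, agriculture and non-agriculture rates, sector
#'   split and `ac_rate`), `province_totals` (province-year totals used in
#'   the construction), and `fertility` (year x scenario multiplier table).
#' @export
generate_population_inputs <- function(cfg, peak_year = 2030,
                                       peak_total = 0.75e9,
                                       ac_rate = 0.6,
                                       sector_split = c(0.15, 0.35, 0.50)) {
  stopifnot(inherits(cfg, "synth_config"))
  if (peak_year < min(cfg$years) || peak_year > max(cfg$years))
    stop("peak_year must lie within the simulated year range")
  if (abs(sum(sector_split) - 1) > 1e-9)
    stop("sector_split must sum to 1")
  grid <- cfg$grid
  ncell <- grid$rows * grid$cols
  years <- cfg$years
  provs <- grid$province_names
  np <- length(provs)

  set.seed(.derive_seed(cfg$seed, cfg$scenario, 0L) + 17L)
  prov_share <- stats::rgamma(np, shape = 5); prov_share <- prov_share / sum(prov_share)
  cell_w <- stats::rgamma(ncell, shape = 2) + 0.05
  # normalize weights within each province
  for (p in provs) {
    idx <- grid$province == p
    cell_w[idx] <- cell_w[idx] / sum(cell_w[idx])
  }
  # per-province constant employment rates and urbanization path offsets
  agri_rate <- stats::runif(np, 0.20, 0.45)
  nonag_rate <- stats::runif(np, 0.50, 0.60)
  urb_off <- stats::runif(np, -0.05, 0.05)

  # asymmetric bell: slow rise to the peak, gentler decline afterwards
  # (roughly -30% by 2100 for a 2030 peak), as national working-population
  # projections show
  pop_sd <- ifelse(years <= peak_year, 55, 80)
  national <- peak_total * exp(-0.5 * ((years - peak_year) / pop_sd)^2)
  pop <- matrix(0, length(years), ncell)
  prov_tot <- expand.grid(province = provs, year = years,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prov_tot <- prov_tot[order(prov_tot$province, prov_tot$year), ]
  prov_tot$total_pop <- NA_real_
  for (i in seq_along(years)) {
    for (k in seq_len(np)) {
      idx <- grid$province == provs[k]
      tot <- national[i] * prov_share[k]
      pop[i, idx] <- tot * cell_w[idx]
      prov_tot$total_pop[prov_tot$province == provs[k] &
                           prov_tot$year == years[i]] <- tot
    }
  }

  urban <- function(y, off) {
    pmin(0.95, pmax(0.05, 0.45 + off + 0.40 / (1 + exp(-(y - 2030) / 25))))
  }
  rates <- do.call(rbind, lapply(seq_len(np), function(k) {
    data.frame(province = provs[k], year = years,
               urban_rate = urban(years, urb_off[k]),
               agriculture_rate = agri_rate[k],
               non_agriculture_rate = nonag_rate[k],
               construction_share = sector_split[1],
               manufacturing_share = sector_split[2],
               service_share = sector_split[3],
               ac_rate = ac_rate,
               stringsAsFactors = FALSE)
  }))
  rates$rural_rate <- 1 - rates$urban_rate

  ramp <- pmax(0, pmin(1, (years - 2020) / (2100 - 2020)))
  fertility <- data.frame(year = years,
                          low = 1 - 0.15 * ramp,
                          moderate = rep(1, length(years)),
                          high = 1 + 0.10 * ramp)

  list(pop = structure(list(pop = pop, years = years, grid = grid,
                            resolution_km = grid$cell_km),
                       class = "population_raster"),
       rates = rates, province_totals = prov_tot, fertility = fertility)
}

#' Generate a synthetic work/rest table with known ground truth
#'
#' Builds the table of recommended work fractions per work intensity and
#' WBGT that the exposure-response fitting step consumes, from known
#' generating parameters, so that fitting can be validated by parameter
#' recovery. The work fraction is `1 - loss_fraction(WBGT)` under the
#' normal-CDF exposure-response model, plus optional Gaussian noise,
#' clipped to [0, 1].
#'
#' @param params an [erf_params()] object providing the generating
#'   (Prodmean, Prodsd) per intensity.
#' @param wbgt_points numeric WBGT grid (degC); at least 4 distinct values.
#' @param noise_sd standard deviation of additive noise on the work
#'   fraction (fractional units), >= 0.
#' @param seed integer seed for the noise.
#' @return data frame of class `workrest_table` with columns `intensity_w`,
#'   `wbgt_c`, `work_fraction`.
#' @export
generate_workrest_table <- function(params, wbgt_points = seq(24, 40, by = 2),
                                    noise_sd = 0, seed = 1) {
  params <- validate_erf_params(params)
  if (length(unique(wbgt_points)) < 4)
    stop("need at least 4 distinct WBGT points per intensity")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  out <- do.call(rbind, lapply(params$intensity_w, function(w) {
    wf <- 1 - loss_fraction(wbgt_points, w, params)
    if (noise_sd > 0) wf <- wf + stats::rnorm(length(wf), sd = noise_sd)
    data.frame(intensity_w = w, wbgt_c = wbgt_points,
               work_fraction = pmin(1, pmax(0, wf)))
  }))
  class(out) <- c("workrest_table", "data.frame")
  out
}
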