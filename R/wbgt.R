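#' Indoor wet bulb globe temperature (simplified WBGT)
#'
#' The two-variable regression approximation widely used for shaded or
#' indoor settings, needing only air temperature and relative humidity:
#' \deqn{sWBGT = 0.567\,T_a + 0.393\,e + 3.94}
#' with water-vapor pressure \eqn{e} (hPa) from the Magnus form
#' \eqn{e = (rh/100)\, 6.105 \exp(17.27\,T_a/(237.7 + T_a))}.
#'
#' @param ta air temperature, degC (daily mean or daily max).
#' @param rh relative humidity, percent, in [0, 100].
#' @return WBGT in degC, same shape as `ta`.
#' @export
indoor_wbgt <- function(ta, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop("rh must be within [0, 100]")
  e <- (rh / 100) * 6.105 * exp(17.27 * ta / (237.7 + ta))
  0.567 * ta + 0.393 * e + 3.94
}

# Stull (2011) psychrometric wet-bulb regression (degC), valid for ordinary
# surface conditions; rh in percent.
psychro_wetbulb <- function(ta, rh) {
  ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
}

# Globe temperature from a spherical energy balance:
#   q_abs = h(u) (Tg - Ta) + eps sigma (Tg_K^4 - Ta_K^4)
# with absorbed solar flux q_abs = 0.25 * 0.95 * rsds (projected-area factor
# 1/4, globe absorptivity 0.95), convective coefficient h = 6.3 u^0.6
# (W m-2 K-1, wind floored at 0.1 m/s), eps = 0.95. Solved by Newton
# iteration; f is increasing and convex in Tg so the iteration is safe.
globe_temperature <- function(ta, wind, rsds, tol = 1e-8, maxit = 60) {
  sigma <- 5.670374419e-8
  eps <- 0.95
  h <- 6.3 * pmax(wind, 0.1)^0.6
  q <- 0.25 * 0.95 * rsds
  tg <- ta + q / (h + 5)                       # linearized start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    fk <- h * (tg - ta) + eps * sigma * ((tg + 273.15)^4 - (ta + 273.15)^4) - q
    dfk <- h + 4 * eps * sigma * (tg + 273.15)^3
    step <- fk / dfk
    tg <- tg - step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    bad <- which(abs(step) >= tol)
    stop("globe temperature failed to converge at ", length(bad),
         " cell(s), e.g. index ", bad[1])
  }
  tg
}

#' Outdoor wet bulb globe temperature
#'
#' Standard composition `WBGT = 0.7 Tnwb + 0.2 Tg + 0.1 Ta`, with globe
#' temperature `Tg` from an iterative energy-balance estimator (see
#' [globe_temperature]) and natural wet-bulb temperature
#' `Tnwb = Tpwb + 0.25 (Tg - Ta)`, where `Tpwb` is the psychrometric
#' wet-bulb from the Stull regression. The radiation correction to the
#' wet-bulb mirrors the behaviour of full natural-wet-bulb models: with no
#' radiation `Tnwb` collapses to the psychrometric wet-bulb, and strong sun
#' or calm air raises it. The result is non-decreasing in radiation and
#' non-increasing in wind when radiation is positive; at high wind the
#' globe temperature approaches the air temperature.
#'
#' A different estimator can be substituted through `backend`, which must
#' be a function `(ta, rh, wind, rsds) -> degC`.
#'
#' @param ta air temperature, degC.
#' @param rh relative humidity, percent.
#' @param wind wind speed, m/s, >= 0.
#' @param rsds downwelling shortwave radiation, W/m2, >= 0.
#' @param backend optional replacement estimator function.
#' @return outdoor WBGT in degC, same shape as `ta`.
#' @export
outdoor_wbgt <- function(ta, rh, wind, rsds, backend = NULL) {
  if (any(wind < 0, na.rm = TRUE)) stop("wind must be >= 0")
  if (any(rsds < 0, na.rm = TRUE)) stop("rsds must be >= 0")
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) stop("rh must be within [0, 100]")
  if (!is.null(backend)) return(backend(ta, rh, wind, rsds))
  tg <- globe_temperature(ta, wind, rsds)
  tnwb <- psychro_wetbulb(ta, rh) + 0.25 * (tg - ta)
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}

#' Daily indoor and outdoor WBGT fields from a climate field
#'
#' Applies [indoor_wbgt()] to daily mean and max temperature (with the
#' daily humidity) and [outdoor_wbgt()] likewise, using the daily mean wind
#' and radiation for both the mean and the max (sub-daily meteorology is
#' not ingested). Both estimators are monotone in temperature at fixed
#' covariates, so the max field dominates the mean field everywhere.
#'
#' @param clim a `climate_field` (one member of [generate_climate()]).
#' @return object of class `wbgt_daily`: matrices `[day x cell]`
#'   `mean_indoor`, `max_indoor`, `mean_outdoor`, `max_outdoor` plus the
#'   calendar (`year`, `doy`), `grid`, `scenario`, `gcm`.
#' @export
climate_to_wbgt <- function(clim) {
  stopifnot(inherits(clim, "climate_field"))
  structure(list(
    mean_indoor = indoor_wbgt(clim$tas, clim$hurs),
    max_indoor = indoor_wbgt(clim$tasmax, clim$hurs),
    mean_outdoor = outdoor_wbgt(clim$tas, clim$hurs, clim$sfcWind, clim$rsds),
    max_outdoor = outdoor_wbgt(clim$tasmax, clim$hurs, clim$sfcWind, clim$rsds),
    year = clim$year, doy = clim$doy, grid = clim$grid,
    scenario = clim$scenario, gcm = clim$gcm
  ), class = "wbgt_daily")
}

#' Workday definition
#'
#' Eight working clock hours within the day. The default is 08:00-12:00 and
#' 13:00-17:00 (a one-hour lunch break); `delay` shifts the whole window
#' later by whole hours, representing work schedules postponed into the
#' evening (+1 h and +2 h are the standard sensitivity settings).
#'
#' @param morning_start,morning_end,afternoon_start,afternoon_end clock
#'   hours bounding the two work blocks (an hour h means the interval
#'   `[h, h+1)`; a block `start:end` contributes hours `start ... end-1`).
#' @param delay whole-hour shift applied to every work hour.
#' @return object of class `workday_def` with the 8 working hour starts.
#' @export
workday_def <- function(morning_start = 8, morning_end = 12,
                        afternoon_start = 13, afternoon_end = 17, delay = 0) {
  hours <- c(seq(morning_start, morning_end - 1),
             seq(afternoon_start, afternoon_end - 1)) + delay
  if (length(hours) != 8L)
    stop("workday must total exactly 8 working hours, got ", length(hours))
  if (any(hours < 0 | hours > 23)) stop("work hours fall outside 0..23")
  structure(list(hours = as.integer(hours), delay = delay), class = "workday_def")
}

# hour -> level under the "4+4+4" daylight layout, symmetric around 13:00:
# 11:00-15:00 carries the daily max, 09:00-11:00 and 15:00-17:00 the
# max/mean midpoint, 07:00-09:00 and 17:00-19:00 the daily mean; all hours
# outside the 07:00-19:00 daylight block carry the daily mean.
hour_level_map <- function(hours) {
  lvl <- rep("mean", length(hours))
  lvl[hours %in% 9:10 | hours %in% 15:16] <- "mid"
  lvl[hours %in% 11:14] <- "max"
  lvl
}

#' Disaggregate daily WBGT to work-hour values ("4+4+4" method)
#'
#' Approximates the diurnal WBGT cycle from the daily mean and max: a 12-h
#' daylight block carries 4 h at the daily max, 4 h at the max/mean
#' midpoint and 4 h at the daily mean, assigned to clock hours by a fixed
#' layout symmetric around 13:00 (see [hour_level_map]); hours outside the
#' daylight block carry the daily mean. The workday then selects its 8
#' working clock hours. Because only three distinct values occur, the
#' result is stored as the three level fields plus the number of work hours
#' at each level; [workhour_values()] materializes the 8 per-hour values.
#'
#' @param wbgt_mean,wbgt_max daily mean and max WBGT (same shape; max >=
#'   mean required).
#' @param workday a [workday_def()].
#' @return object of class `workhour_wbgt`: `levels` (list of the mean,
#'   mid, max fields), `counts` (named work-hour counts per level, summing
#'   to 8), `hour_levels` (level of each working hour), `workday`.
#' @export
disaggregate_444 <- function(wbgt_mean, wbgt_max, workday = workday_def()) {
  stopifnot(inherits(workday, "workday_def"))
  if (any(wbgt_max < wbgt_mean, na.rm = TRUE))
    stop("wbgt_max must be >= wbgt_mean everywhere")
  lv <- hour_level_map(workday$hours)
  counts <- c(mean = sum(lv == "mean"), mid = sum(lv == "mid"),
              max = sum(lv == "max"))
  structure(list(
    levels = list(mean = wbgt_mean, mid = (wbgt_mean + wbgt_max) / 2,
                  max = wbgt_max),
    counts = counts, hour_levels = lv, workday = workday
  ), class = "workhour_wbgt")
}

#' Materialize per-work-hour WBGT values
#'
#' @param wh a `workhour_wbgt` from [disaggregate_444()].
#' @return array with one slice per working hour (last dimension 8), each
#'   carrying that hour's WBGT field.
#' @export
workhour_values <- function(wh) {
  stopifnot(inherits(wh, "workhour_wbgt"))
  base <- wh$levels$mean
  d <- if (is.null(dim(base))) length(base) else dim(base)
  out <- array(NA_real_, c(d, 8L))
  flat <- prod(d)
  for (h in 1:8)
    out[(h - 1) * flat + seq_len(flat)] <- wh$levels[[wh$hour_levels[h]]]
  out
}

#' Annual count of days exceeding a WBGT threshold
#'
#' Per-cell annual mean number of days on which the daily WBGT reaches or
#' exceeds `threshold`, computed for the indoor or outdoor setting on the
#' daily mean (or max) field, over the years of a period.
#'
#' @param wbgt a `wbgt_daily` from [climate_to_wbgt()].
#' @param threshold WBGT threshold, degC (default 25).
#' @param setting `"indoor"` or `"outdoor"`.
#' @param stat daily statistic to threshold: `"mean"` or `"max"`.
#' @param period a [period_def()] or `NULL` for all available years.
#' @return numeric vector of days/year per cell.
#' @export
count_threshold_days <- function(wbgt, threshold = 25,
                                 setting = c("indoor", "outdoor"),
                                 stat = c("mean", "max"), period = NULL) {
  stopifnot(inherits(wbgt, "wbgt_daily"))
  setting <- match.arg(setting)
  stat <- match.arg(stat)
  field <- wbgt[[paste(stat, setting, sep = "_")]]
  keep <- if (is.null(period)) rep(TRUE, length(wbgt$year)) else {
    stopifnot(inherits(period, "period_def"))
    wbgt$year >= period$start_year & wbgt$year <= period$end_year
  }
  if (!any(keep)) stop("period contains no simulated days")
  nyears <- length(unique(wbgt$year[keep]))
  colSums(field[keep, , drop = FALSE] >= threshold) / nyears
}
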