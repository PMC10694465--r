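#' Analysis period definition
#'
#' Standard periods are the baseline 1986-2005 and the early (2021-2040,
#' centred on 2030), middle (2051-2070, centred on 2060) and late
#' (2081-2100, centred on 2090) future windows.
#'
#' @param label short name.
#' @param start_year,end_year inclusive year range.
#' @return object of class `period_def`.
#' @export
period_def <- function(label, start_year, end_year) {
  if (start_year > end_year) stop("start_year must be <= end_year")
  structure(list(label = label, start_year = start_year, end_year = end_year),
            class = "period_def")
}

#' @rdname period_def
#' @export
standard_periods <- function() {
  list(baseline = period_def("baseline", 1986, 2005),
       early = period_def("early", 2021, 2040),
       middle = period_def("middle", 2051, 2070),
       late = period_def("late", 2081, 2100))
}

#' Per-capita work hours lost
#'
#' Daily per-capita WHL is the sum over the 8 working hours of the loss
#' fraction at that hour's WBGT; since the "4+4+4" disaggregation yields
#' only three distinct hourly values, this is the count-weighted sum of
#' the loss fraction at the three level fields. Units: hours lost per
#' worker per day.
#'
#' @param workhour a `workhour_wbgt` from [disaggregate_444()].
#' @param intensity work intensity (200, 300 or 400 W).
#' @param params an [erf_params()].
#' @return matrix of daily per-capita WHL, same shape as the level fields.
#' @export
per_capita_whl <- function(workhour, intensity, params) {
  stopifnot(inherits(workhour, "workhour_wbgt"))
  out <- 0
  for (l in names(workhour$counts)) {
    n <- workhour$counts[[l]]
    if (n > 0) out <- out + n * loss_fraction(workhour$levels[[l]], intensity, params)
  }
  out
}

# sum a [day x cell] matrix into a [year x cell] matrix following `years`
annual_sum <- function(daily, day_year, years) {
  out <- rowsum(daily, group = day_year, reorder = TRUE)
  out[match(years, sort(unique(day_year))), , drop = FALSE]
}

#' Total work hours lost from per-capita losses and exposed workers
#'
#' Multiplies the annual per-capita WHL grid by the exposed workers,
#' per cell and sector.
#'
#' @param per_capita array `[year x cell x sector]` of annual per-capita
#'   WHL (hours/worker/year).
#' @param exposed an `exposed_population` (or `sector_population`).
#' @return array `[year x cell x sector]` of total WHL (hours).
#' @export
total_whl <- function(per_capita, exposed) {
  stopifnot(inherits(exposed, "sector_population"))
  if (!all(dim(per_capita) == dim(exposed$workers)))
    stop("per-capita WHL and exposed population dimensions do not align")
  if (any(per_capita < 0, na.rm = TRUE) || any(exposed$workers < 0, na.rm = TRUE))
    stop("negative per-capita WHL or worker counts")
  per_capita * exposed$workers
}

#' Project work hours lost for a scenario ensemble
#'
#' Runs the full per-member chain: daily WBGT from meteorology, "4+4+4"
#' work-hour disaggregation (indoor fields for manufacturing and service,
#' outdoor for agriculture and construction), loss fractions through the
#' exposure-response function at each sector's intensity, annual per-capita
#' sums, and multiplication by the exposed working population.
#'
#' @param ens a `climate_ensemble` from [generate_climate()].
#' @param exposed an `exposed_population` on the same grid and years.
#' @param params an [erf_params()].
#' @param workday a [workday_def()].
#' @return object of class `whl_result`: arrays `whl` and `per_capita`
#'   `[gcm x year x cell x sector]`, plus `years`, `grid`, `sectors`,
#'   `scenario`.
#' @export
project_whl <- function(ens, exposed, params, workday = workday_def()) {
  stopifnot(inherits(ens, "climate_ensemble"),
            inherits(exposed, "sector_population"))
  years <- ens$cfg$years
  if (!identical(years, exposed$years))
    stop("climate and population years do not align")
  grid <- ens$cfg$grid
  ncell <- grid$rows * grid$cols
  st <- exposed$sectors
  ng <- length(ens$members)
  whl <- array(0, c(ng, length(years), ncell, nrow(st)),
               dimnames = list(NULL, NULL, NULL, st$sector))
  pc <- whl
  for (g in seq_len(ng)) {
    wb <- climate_to_wbgt(ens$members[[g]])
    for (s in seq_len(nrow(st))) {
      setting <- if (st$indoor[s]) "indoor" else "outdoor"
      wh <- disaggregate_444(wb[[paste0("mean_", setting)]],
                             wb[[paste0("max_", setting)]], workday)
      daily <- per_capita_whl(wh, st$intensity_w[s], params)
      pc[g, , , s] <- annual_sum(daily, wb$year, years)
    }
    whl[g, , , ] <- pc[g, , , , drop = FALSE] *
      array(exposed$workers, c(1, dim(exposed$workers)))
  }
  structure(list(whl = whl, per_capita = pc, years = years, grid = grid,
                 sectors = st, scenario = ens$cfg$scenario),
            class = "whl_result")
}

#' @export
print.whl_result <- function(x, ...) {
  cat(sprintf("<whl_result> %s: %d member(s) x %d years x %d cells x %d sectors\n",
              x$scenario, dim(x$whl)[1], dim(x$whl)[2], dim(x$whl)[3],
              dim(x$whl)[4]))
  invisible(x)
}

# ensemble interval: with a handful of members the 95% interval is reported
# as the ensemble min-max; "normal" gives mean +/- 1.96 sd instead
.ens_interval <- function(x, interval) {
  if (interval == "minmax") c(min(x), max(x))
  else stats::qnorm(c(0.025, 0.975), mean(x), stats::sd(x))
}

#' Aggregate gridded WHL to provinces or the nation, by period
#'
#' Annual-mean WHL per period and unit, summed over cells and sectors,
#' with the ensemble mean and 95% interval across pseudo-GCM members
#' (min-max by default) and each province's proportion of the national
#' total (from ensemble means).
#'
#' @param res a `whl_result`.
#' @param level `"province"` or `"national"`.
#' @param periods list of [period_def()]s; default [standard_periods()]
#'   restricted to the simulated years.
#' @param interval `"minmax"` (default) or `"normal"`.
#' @return data frame with columns `scenario`, `unit`, `period`,
#'   `whl_mean`, `whl_lo`, `whl_hi` and (province level) `proportion` (%).
#' @export
aggregate_whl <- function(res, level = c("province", "national"),
                          periods = NULL, interval = c("minmax", "normal")) {
  stopifnot(inherits(res, "whl_result"))
  level <- match.arg(level)
  interval <- match.arg(interval)
  if (is.null(periods)) {
    periods <- Filter(function(p) any(res$years >= p$start_year &
                                        res$years <= p$end_year),
                      standard_periods())
  }
  units <- if (level == "province") res$grid$province_names else "national"
  rows <- list()
  for (p in periods) {
    yr <- res$years >= p$start_year & res$years <= p$end_year
    if (!any(yr)) stop("period ", p$label, " outside the simulated years")
    # per-member annual-mean national/provincial totals
    per_unit <- vapply(units, function(u) {
      cells <- if (level == "province") res$grid$province == u
               else rep(TRUE, dim(res$whl)[3])
      vapply(seq_len(dim(res$whl)[1]), function(g) {
        mean(apply(res$whl[g, yr, cells, , drop = FALSE], 2, sum))
      }, 0)
    }, numeric(dim(res$whl)[1]))
    per_unit <- matrix(per_unit, nrow = dim(res$whl)[1])
    means <- colMeans(per_unit)
    prop <- if (level == "province") 100 * means / sum(means) else NA_real_
    for (k in seq_along(units)) {
      ci <- .ens_interval(per_unit[, k], interval)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = res$scenario, unit = units[k], period = p$label,
        whl_mean = means[k], whl_lo = ci[1], whl_hi = ci[2],
        proportion = prop[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' National annual WHL time series
#'
#' @param res a `whl_result`.
#' @return data frame with `year`, per-member columns and `ens_mean`.
#' @export
national_whl_series <- function(res) {
  stopifnot(inherits(res, "whl_result"))
  ng <- dim(res$whl)[1]
  m <- vapply(seq_len(ng), function(g)
    apply(res$whl[g, , , , drop = FALSE], 2, sum), numeric(dim(res$whl)[2]))
  m <- matrix(m, ncol = ng)
  out <- data.frame(year = res$years, m)
  names(out)[-1] <- paste0("gcm", seq_len(ng))
  out$ens_mean <- rowMeans(m)
  out
}

#' Convert work hours lost to full-time job equivalents
#'
#' One full-time job is 8 h/day over 365 days = 2920 h/year, matching the
#' pipeline's every-day work-year convention.
#'
#' @param whl_hours annual WHL in hours (>= 0).
#' @param millions if `TRUE`, return millions of jobs rounded to the
#'   nearest million (the display convention).
#' @return jobs (or millions of jobs).
#' @export
fulltime_job_equivalents <- function(whl_hours, millions = FALSE) {
  if (any(whl_hours < 0)) stop("whl_hours must be >= 0")
  jobs <- whl_hours / (8 * 365)
  if (millions) round(jobs / 1e6) else jobs
}
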