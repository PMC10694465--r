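#' Gridded working population by sector
#'
#' Splits the gridded total population into the four employed sectors
#' using per-province, per-year rates:
#' agriculture = total x rural_rate x agriculture_rate (rural employment),
#' non-agriculture = total x urban_rate x non_agriculture_rate (urban
#' employment), the latter divided into construction, manufacturing and
#' service by the province's sector split. Every cell must belong to
#' exactly one province and every simulated year must appear in the rates
#' table.
#'
#' @param pop a `population_raster` (matrix `[year x cell]` with `years`
#'   and `grid`), e.g. from [generate_population_inputs()].
#' @param rates province-year rates data frame with columns `province`,
#'   `year`, `urban_rate`, `rural_rate`, `agriculture_rate`,
#'   `non_agriculture_rate`, `construction_share`, `manufacturing_share`,
#'   `service_share`.
#' @param fertility_multiplier optional numeric scalar or per-year vector
#'   scaling the total population (fertility-scenario path).
#' @return object of class `sector_population`: array `workers`
#'   `[year x cell x sector]` (sectors agriculture, construction,
#'   manufacturing, service), plus `years`, `grid`, `sectors` (the
#'   sector/intensity/indoor mapping).
#' @export
working_population <- function(pop, rates, fertility_multiplier = 1) {
  stopifnot(inherits(pop, "population_raster"))
  grid <- pop$grid
  ncell <- grid$rows * grid$cols
  years <- pop$years
  if (!all(years %in% rates$year))
    stop("rates table does not cover all population years")
  if (!all(grid$province %in% rates$province))
    stop("cells mapped to provinces absent from the rates table")
  if (length(fertility_multiplier) == 1L)
    fertility_multiplier <- rep(fertility_multiplier, length(years))
  stopifnot(length(fertility_multiplier) == length(years))

  st <- sector_table()
  workers <- array(0, c(length(years), ncell, 4),
                   dimnames = list(NULL, NULL, st$sector))
  for (i in seq_along(years)) {
    ri <- rates[rates$year == years[i], , drop = FALSE]
    k <- match(grid$province, ri$province)
    tot <- pop$pop[i, ] * fertility_multiplier[i]
    ag <- tot * ri$rural_rate[k] * ri$agriculture_rate[k]
    nonag <- tot * ri$urban_rate[k] * ri$non_agriculture_rate[k]
    workers[i, , "agriculture"] <- ag
    workers[i, , "construction"] <- nonag * ri$construction_share[k]
    workers[i, , "manufacturing"] <- nonag * ri$manufacturing_share[k]
    workers[i, , "service"] <- nonag * ri$service_share[k]
  }
  structure(list(workers = workers, years = years, grid = grid, sectors = st),
            class = "sector_population")
}

#' Exclude air-conditioned indoor workers from exposure
#'
#' Indoor sectors (manufacturing and service) are scaled by
#' `1 - ac_rate`, removing workers protected by air conditioning; outdoor
#' sectors are unchanged. The rate may be a scalar or a per-year vector
#' (e.g. a future penetration ramp from [ac_rate_path()]).
#'
#' @param workers a `sector_population` from [working_population()].
#' @param ac_rate AC penetration rate(s) in [0, 1]; scalar or one value
#'   per year.
#' @return a `sector_population` of truly exposed workers (class gains
#'   `exposed_population`).
#' @export
apply_ac_adjustment <- function(workers, ac_rate = 0.6) {
  stopifnot(inherits(workers, "sector_population"))
  if (any(ac_rate < 0 | ac_rate > 1)) stop("ac_rate must be within [0, 1]")
  ny <- length(workers$years)
  if (length(ac_rate) == 1L) ac_rate <- rep(ac_rate, ny)
  stopifnot(length(ac_rate) == ny)
  out <- workers
  for (s in workers$sectors$sector[workers$sectors$indoor])
    out$workers[, , s] <- out$workers[, , s] * (1 - ac_rate)
  class(out) <- unique(c("exposed_population", class(out)))
  out
}

#' Linear future AC penetration ramp
#'
#' The future penetration rate rises linearly from the current rate to an
#' end-of-century target (e.g. +10/+20/+30 percentage points reaching
#' 70/80/90%); before `start_year` it stays at `current`.
#'
#' @param years years to evaluate.
#' @param current current penetration rate (default 0.6).
#' @param target end-of-century rate; `current` (default) gives a constant
#'   path.
#' @param start_year year the ramp starts (default 2021).
#' @param end_year year the target is reached (default 2100).
#' @return numeric vector of rates per year.
#' @export
ac_rate_path <- function(years, current = 0.6, target = current,
                         start_year = 2021, end_year = 2100) {
  stopifnot(current >= 0, current <= 1, target >= 0, target <= 1,
            end_year > start_year)
  frac <- pmax(0, pmin(1, (years - start_year) / (end_year - start_year)))
  current + (target - current) * frac
}

#' Block-aggregate a gridded field to a coarser nesting resolution
#'
#' Aggregates `factor x factor` blocks of cells by sum (mass-conserving,
#' for population) or area-weighted mean (for WBGT; cells are equal-area
#' so this is the plain mean). The grid dimensions must be divisible by
#' `factor`; general resampling between non-nesting grids is out of scope.
#'
#' @param field matrix `[slice x cell]` (e.g. day x cell or year x cell) or
#'   a plain per-cell vector.
#' @param grid the `whl_grid` the cells live on.
#' @param factor integer block edge (e.g. 2 aggregates 25 km cells to 50 km).
#' @param mode `"sum"` or `"mean"`.
#' @return list with the aggregated `field` (same slice dimension) and the
#'   coarse `rows`, `cols`.
#' @export
regrid <- function(field, grid, factor, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "whl_grid"), factor >= 1)
  if (grid$rows %% factor != 0 || grid$cols %% factor != 0)
    stop("grid (", grid$rows, " x ", grid$cols,
         ") does not nest in blocks of ", factor)
  vec_in <- is.null(dim(field))
  if (vec_in) field <- matrix(field, nrow = 1)
  r2 <- grid$rows %/% factor; c2 <- grid$cols %/% factor
  # coarse cell index for each fine cell (column-major on both grids)
  row_f <- rep(seq_len(grid$rows), times = grid$cols)
  col_f <- rep(seq_len(grid$cols), each = grid$rows)
  coarse <- ((col_f - 1) %/% factor) * r2 + ((row_f - 1) %/% factor) + 1
  out <- matrix(0, nrow(field), r2 * c2)
  for (k in seq_len(r2 * c2)) {
    block <- field[, coarse == k, drop = FALSE]
    out[, k] <- if (mode == "sum") rowSums(block) else rowMeans(block)
  }
  list(field = if (vec_in) out[1, ] else out, rows = r2, cols = c2)
}
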