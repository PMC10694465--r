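#' Factor-separation decomposition of a WHL change
#'
#' Separates the change in an outcome between two states into climate,
#' population and interaction effects by evaluating the outcome at all
#' four corner combinations of the factor states:
#' total = W(C1,P1) - W(C0,P0); climate = W(C1,P0) - W(C0,P0);
#' population = W(C0,P1) - W(C0,P0); interaction = total - climate -
#' population. The decomposition is additive by construction, to machine
#' precision, and interaction is exactly zero for additively separable
#' evaluators.
#'
#' @param whl_fn evaluator `function(climate, pop)` returning a numeric
#'   outcome (scalar or vector).
#' @param climate0,climate1 climate states (reference and comparison).
#' @param pop0,pop1 population states.
#' @return object of class `driver_decomposition`: list with
#'   `total_change`, `climate_effect`, `population_effect`,
#'   `interaction_effect` and the corner values.
#' @export
factor_separation <- function(whl_fn, climate0, climate1, pop0, pop1) {
  w00 <- whl_fn(climate0, pop0)
  w10 <- whl_fn(climate1, pop0)
  w01 <- whl_fn(climate0, pop1)
  w11 <- whl_fn(climate1, pop1)
  if (any(!is.finite(c(w00, w10, w01, w11))))
    stop("evaluator returned non-finite values at a corner state")
  total <- w11 - w00
  climate <- w10 - w00
  population <- w01 - w00
  structure(list(total_change = total, climate_effect = climate,
                 population_effect = population,
                 interaction_effect = total - climate - population,
                 corners = list(w00 = w00, w10 = w10, w01 = w01, w11 = w11)),
            class = "driver_decomposition")
}

#' @export
print.driver_decomposition <- function(x, ...) {
  cat("<driver_decomposition>\n")
  cat(sprintf("  total:       %g\n", sum(x$total_change)))
  cat(sprintf("  climate:     %g\n", sum(x$climate_effect)))
  cat(sprintf("  population:  %g\n", sum(x$population_effect)))
  cat(sprintf("  interaction: %g\n", sum(x$interaction_effect)))
  invisible(x)
}

# annual-mean per-capita WHL [cell x sector] over a period for one
# wbgt_daily object
.period_percap <- function(wb, params, workday, period, sectors) {
  keep <- wb$year >= period$start_year & wb$year <= period$end_year
  if (!any(keep)) stop("WBGT data do not cover period ", period$label)
  nyears <- length(unique(wb$year[keep]))
  out <- matrix(0, ncol(wb$mean_indoor), nrow(sectors),
                dimnames = list(NULL, sectors$sector))
  for (s in seq_len(nrow(sectors))) {
    setting <- if (sectors$indoor[s]) "indoor" else "outdoor"
    wh <- disaggregate_444(wb[[paste0("mean_", setting)]][keep, , drop = FALSE],
                           wb[[paste0("max_", setting)]][keep, , drop = FALSE],
                           workday)
    out[, s] <- colSums(per_capita_whl(wh, sectors$intensity_w[s], params)) / nyears
  }
  out
}

#' Avoided WHL from limiting warming to 1.5 degrees
#'
#' Holding population fixed at its period average, substitutes the WBGT
#' difference between an RCP scenario and the 1.5-degree analogue into the
#' exposure-response function: avoided WHL = (annual per-capita WHL under
#' the RCP WBGT minus under the 1.5-degree WBGT) times the average exposed
#' population, per cell and sector, aggregated to provinces and the
#' nation. Cells where the RCP is locally cooler give negative
#' contributions; they are kept (and counted) unless
#' `truncate_negative = TRUE`.
#'
#' @param wbgt_rcp,wbgt_15 `wbgt_daily` objects (one ensemble member each)
#'   covering the comparison period under the RCP and 1.5-degree climates.
#' @param exposed an `exposed_population` whose years cover the period;
#'   averaged over the period.
#' @param params an [erf_params()].
#' @param period a [period_def()]; default the middle future 2051-2070.
#' @param workday a [workday_def()].
#' @param truncate_negative zero negative cell-sector contributions before
#'   aggregation.
#' @return object of class `benefit_result`: `avoided_cell_sector` matrix,
#'   `by_province` data frame, `national` total (hours/year),
#'   `per_capita` (hours/worker/year over exposed workers),
#'   `n_negative_cells` count of flagged negative cell-sector entries.
#' @export
avoided_whl_15C <- function(wbgt_rcp, wbgt_15, exposed, params,
                            period = period_def("middle", 2051, 2070),
                            workday = workday_def(),
                            truncate_negative = FALSE) {
  stopifnot(inherits(wbgt_rcp, "wbgt_daily"), inherits(wbgt_15, "wbgt_daily"),
            inherits(exposed, "sector_population"))
  st <- exposed$sectors
  pc_rcp <- .period_percap(wbgt_rcp, params, workday, period, st)
  pc_15 <- .period_percap(wbgt_15, params, workday, period, st)
  yr <- exposed$years >= period$start_year & exposed$years <= period$end_year
  if (!any(yr)) stop("exposed population does not cover period ", period$label)
  avg_pop <- apply(exposed$workers[yr, , , drop = FALSE], c(2, 3), mean)
  avoided <- (pc_rcp - pc_15) * avg_pop
  n_neg <- sum(avoided < 0)
  if (truncate_negative) avoided[avoided < 0] <- 0
  prov <- vapply(exposed$grid$province_names, function(p)
    sum(avoided[exposed$grid$province == p, ]), 0)
  total_pop <- sum(avg_pop)
  structure(list(
    avoided_cell_sector = avoided,
    by_province = data.frame(province = exposed$grid$province_names,
                             avoided_whl = unname(prov)),
    national = sum(avoided),
    per_capita = if (total_pop > 0) sum(avoided) / total_pop else 0,
    n_negative_cells = n_neg, period = period
  ), class = "benefit_result")
}

#' Economic value of avoided WHL (human-capital method)
#'
#' The economic cost avoided is the exact product of avoided work hours
#' and the unit value of a work hour; with per-province unit values the
#' products are summed.
#'
#' @param avoided_whl hours (scalar, or per-province vector).
#' @param unit_value USD per hour (scalar, or per-province vector matching
#'   `avoided_whl`), >= 0.
#' @return total USD.
#' @export
economic_cost_hc <- function(avoided_whl, unit_value) {
  if (any(unit_value < 0)) stop("unit_value must be >= 0")
  if (length(unit_value) > 1 && length(unit_value) != length(avoided_whl))
    stop("per-province unit values must match avoided_whl length")
  sum(avoided_whl * unit_value)
}
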