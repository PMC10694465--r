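test_that("factor separation reproduces hand arithmetic on a toy evaluator", {
  # W(C, P) = c * p with c in {1, 2}, p in {10, 5}
  d <- factor_separation(function(cl, p) cl * p, 1, 2, 10, 5)
  expect_equal(d$total_change, 0)
  expect_equal(d$climate_effect, 10)
  expect_equal(d$population_effect, -5)
  expect_equal(d$interaction_effect, -5)
  # no climate change -> no climate effect
  d0 <- factor_separation(function(cl, p) cl * p, 1, 1, 10, 5)
  expect_equal(d0$climate_effect, 0)
  expect_equal(d0$interaction_effect, 0)
  # additively separable evaluator -> interaction exactly 0
  dsep <- factor_separation(function(cl, p) exp(cl) + 3 * p, 0.3, 1.7, 10, 5)
  expect_lt(abs(dsep$interaction_effect), 1e-12)
})

test_that("decomposition is additive at machine precision and corner-consistent", {
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(4); b <- rnorm(1)
    f <- function(cl, p) a[1] * cl + a[2] * p + a[3] * cl * p + a[4] +
      b * cl^2 * sqrt(abs(p))
    c0 <- rnorm(1); c1 <- rnorm(1); p0 <- abs(rnorm(1)); p1 <- abs(rnorm(1))
    d <- factor_separation(f, c0, c1, p0, p1)
    expect_equal(d$climate_effect + d$population_effect +
                   d$interaction_effect, d$total_change, tolerance = 1e-13)
    # swapping the roles of the states negates the total change
    dr <- factor_separation(f, c1, c0, p1, p0)
    expect_equal(dr$total_change, -d$total_change, tolerance = 1e-12)
  }
})

test_that("climate drives WHL up and population down on a warming rcp85 domain", {
  res <- run_scenario_whl("rcp85", years = c(2021, 2030, 2090, 2096),
                          grid = c(4, 4), gcms = 1, seed = 1)
  cfg <- tiny_cfg("rcp85", years = c(2021, 2030, 2090, 2096), seed = 1)
  pin <- generate_population_inputs(cfg, peak_year = 2030)
  ex <- apply_ac_adjustment(working_population(pin$pop, pin$rates), 0.6)
  pc <- function(yrs) apply(res$per_capita[1, res$years %in% yrs, , ,
                                           drop = FALSE], c(3, 4), mean)
  pop <- function(yrs) apply(ex$workers[ex$years %in% yrs, , , drop = FALSE],
                             c(2, 3), mean)
  d <- factor_separation(function(cl, p) sum(cl * p),
                         pc(c(2021, 2030)), pc(c(2090, 2096)),
                         pop(c(2021, 2030)), pop(c(2090, 2096)))
  expect_gt(d$climate_effect, 0)
  expect_lt(d$population_effect, 0)
  expect_gt(d$total_change, 0)
})

test_that("avoided WHL vanishes for identical climates and is positive under warming", {
  grid <- make_grid(2, 2)
  ex <- toy_exposed(rep(250, 4), years = 2060, grid = grid)
  p <- tiny_erf()
  wb <- constant_wbgt_daily(30, ndays = 200, year = 2060, grid = grid)
  b0 <- avoided_whl_15C(wb, wb, ex, p)
  expect_equal(b0$national, 0)
  expect_equal(b0$by_province$avoided_whl, rep(0, nrow(b0$by_province)))
  wb2 <- constant_wbgt_daily(32, ndays = 200, year = 2060, grid = grid)
  b2 <- avoided_whl_15C(wb2, wb, ex, p)
  expect_gt(b2$national, 0)
  expect_true(all(b2$avoided_cell_sector[, "agriculture"] > 0))
  expect_equal(b2$n_negative_cells, 0)
})

test_that("one-cell avoided WHL matches the closed-form CDF difference", {
  p <- flat_erf(33, 4)
  ex <- toy_exposed(1000, years = 2060)
  wb_rcp <- constant_wbgt_daily(33, ndays = 100, year = 2060)
  wb_15 <- constant_wbgt_daily(31, ndays = 100, year = 2060)
  b <- avoided_whl_15C(wb_rcp, wb_15, ex, p)
  want <- (pnorm(0) - pnorm(-0.5)) * 8 * 100 * 1000
  expect_equal(b$national, want, tolerance = 1e-9)
})

test_that("negative avoided cells are flagged and optionally truncated", {
  ex <- toy_exposed(1000, years = 2060)
  p <- flat_erf(33, 4)
  wb_warm <- constant_wbgt_daily(33, ndays = 50, year = 2060)
  wb_cool <- constant_wbgt_daily(31, ndays = 50, year = 2060)
  b <- avoided_whl_15C(wb_cool, wb_warm, ex, p)   # RCP locally cooler
  expect_lt(b$national, 0)
  expect_gt(b$n_negative_cells, 0)
  bt <- avoided_whl_15C(wb_cool, wb_warm, ex, p, truncate_negative = TRUE)
  expect_equal(bt$national, 0)
})

test_that("human-capital costing is an exact product with province support", {
  expect_equal(economic_cost_hc(1e9, 5), 5e9)
  expect_equal(economic_cost_hc(0, 7), 0)
  avoided <- c(1e8, 2e8, 3e8)
  uv <- c(4, 5, 6)
  expect_equal(economic_cost_hc(avoided, uv), sum(avoided * uv))
  expect_error(economic_cost_hc(1e9, -2), ">= 0")
  expect_error(economic_cost_hc(avoided, c(1, 2)), "match")
})
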