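test_that("per-capita WHL sums loss fractions over the 8 work hours", {
  p <- flat_erf(33, 4)
  # all work hours at the curve midpoint: 8 x 0.5 = 4 h/day
  wh <- disaggregate_444(33, 33)
  expect_equal(per_capita_whl(wh, 300, p), 4)
  # far below the curve: no losses
  expect_lt(per_capita_whl(disaggregate_444(33 - 40, 33 - 40), 300, p), 1e-12)
  # levels (28, 31, 34) with the default hour multiset (1 mean, 4 mid, 3 max)
  wh <- disaggregate_444(28, 34)
  want <- 1 * pnorm(28, 33, 4) + 4 * pnorm(31, 33, 4) + 3 * pnorm(34, 33, 4)
  expect_equal(per_capita_whl(wh, 300, p), want)
})

test_that("total WHL is per-capita times workers and zero without workers", {
  # 4 h/day over 100 days, 1000 workers -> 400,000 h
  p <- flat_erf(33, 4)
  wb <- constant_wbgt_daily(33, ndays = 100)
  wh <- disaggregate_444(wb$mean_outdoor, wb$max_outdoor)
  annual <- colSums(per_capita_whl(wh, 400, p))         # one year of days
  ex <- toy_exposed(1000)
  whl <- total_whl(array(annual, c(1, 1, 4),
                         dimnames = list(NULL, NULL, ex$sectors$sector)),
                   ex)
  expect_equal(sum(whl), 400000)
  expect_equal(sum(total_whl(array(annual, c(1, 1, 4)), toy_exposed(0))), 0)
  expect_error(total_whl(array(-1, c(1, 1, 4)), toy_exposed(10)), "negative")
})

test_that("toy projection equals a brute-force loop recomputation", {
  cfg <- tiny_cfg(grid = c(2, 2), years = c(2030, 2031), seed = 5)
  ens <- generate_climate(cfg)
  pin <- generate_population_inputs(cfg, peak_year = 2030)
  ex <- apply_ac_adjustment(working_population(pin$pop, pin$rates), 0.6)
  p <- tiny_erf()
  res <- project_whl(ens, ex, p)
  # independent loop over cells/sectors/days using materialized hour values
  f <- ens$members[[1]]
  wb <- climate_to_wbgt(f)
  st <- ex$sectors
  for (cell in 1:4) {
    for (s in 1:4) {
      setting <- if (st$indoor[s]) "indoor" else "outdoor"
      hv <- workhour_values(disaggregate_444(wb[[paste0("mean_", setting)]],
                                             wb[[paste0("max_", setting)]]))
      loss <- apply(hv[, cell, ], 1, function(h)
        sum(loss_fraction(h, st$intensity_w[s], p)))
      for (yi in 1:2) {
        want <- sum(loss[f$year == cfg$years[yi]]) * ex$workers[yi, cell, s]
        expect_equal(res$whl[1, yi, cell, s], want, tolerance = 1e-10)
      }
    }
  }
})

test_that("aggregation is additive and proportions normalize", {
  res <- run_scenario_whl("rcp45", years = c(1990, 2000), grid = c(4, 4),
                          gcms = 2, seed = 3)
  agg_p <- aggregate_whl(res, "province",
                         periods = list(period_def("baseline", 1986, 2005)))
  agg_n <- aggregate_whl(res, "national",
                         periods = list(period_def("baseline", 1986, 2005)))
  expect_equal(sum(agg_p$whl_mean), agg_n$whl_mean, tolerance = 1e-9)
  expect_equal(sum(agg_p$proportion), 100, tolerance = 1e-9)
  # single province covering the whole grid: province total = national
  layout <- data.frame(name = "All", row_min = 1, row_max = 4,
                       col_min = 1, col_max = 4)
  res1 <- run_scenario_whl("rcp45", years = c(1990, 2000), grid = c(4, 4),
                           gcms = 1, seed = 3)
  res1$grid <- make_grid(4, 4, province_layout = layout)
  agg1 <- aggregate_whl(res1, "province",
                        periods = list(period_def("baseline", 1986, 2005)))
  expect_equal(agg1$whl_mean,
               aggregate_whl(res1, "national",
                             periods = list(period_def("baseline", 1986,
                                                       2005)))$whl_mean)
  # mask-based manual sums for a two-province split
  g <- res$grid
  for (p in g$province_names) {
    manual <- mean(vapply(1:2, function(gg)
      sum(res$whl[gg, , g$province == p, ]) / 2, 0))
    expect_equal(agg_p$whl_mean[agg_p$unit == p], manual, tolerance = 1e-9)
  }
  expect_error(aggregate_whl(res, periods = list(period_def("x", 2050, 2060))),
               "outside the simulated years")
})

test_that("a uniform warming shift never decreases any cell's WHL", {
  cfg <- tiny_cfg(grid = c(3, 3), years = 2030)
  f <- generate_climate(cfg)$members[[1]]
  wb <- climate_to_wbgt(f)
  p <- tiny_erf()
  wh0 <- disaggregate_444(wb$mean_outdoor, wb$max_outdoor)
  wh1 <- disaggregate_444(wb$mean_outdoor + 1, wb$max_outdoor + 1)
  expect_true(all(per_capita_whl(wh1, 400, p) >= per_capita_whl(wh0, 400, p)))
})

test_that("outdoor heavy work loses more hours than indoor light work overall", {
  p <- tiny_erf()
  for (seed in c(1, 2)) {
    f <- generate_climate(tiny_cfg(grid = c(4, 4), years = c(2030, 2090),
                                   seed = seed))$members[[1]]
    wb <- climate_to_wbgt(f)
    pc4 <- per_capita_whl(disaggregate_444(wb$mean_outdoor, wb$max_outdoor),
                          400, p)
    pc2 <- per_capita_whl(disaggregate_444(wb$mean_indoor, wb$max_indoor),
                          200, p)
    # grid-total annual per-capita WHL: heavy outdoor dominates light indoor
    expect_gt(sum(pc4[f$year == 2030, ]), sum(pc2[f$year == 2030, ]))
    expect_gt(sum(pc4[f$year == 2090, ]), sum(pc2[f$year == 2090, ]))
  }
})

test_that("full-time job equivalents use the 2920-hour work year", {
  expect_equal(fulltime_job_equivalents(2920), 1)
  expect_equal(fulltime_job_equivalents(0, millions = TRUE), 0)
  expect_equal(fulltime_job_equivalents(32.1e9, millions = TRUE), 11)
  expect_equal(fulltime_job_equivalents(8.5e9, millions = TRUE), 3)
  expect_error(fulltime_job_equivalents(-1), ">= 0")
})
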