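test_that("indoor WBGT matches the regression hand-computed via Magnus", {
  expect_equal(indoor_wbgt(30, 0), 0.567 * 30 + 3.94)   # zero humidity
  # independent hand computation: e = 0.6 * 6.105 * exp(17.27*30/267.7)
  e <- 0.6 * 6.105 * exp(17.27 * 30 / (237.7 + 30))
  expect_equal(indoor_wbgt(30, 60), 0.567 * 30 + 0.393 * e + 3.94,
               tolerance = 1e-12)
  expect_equal(indoor_wbgt(30, 60), 30.92, tolerance = 0.1)
  expect_gt(indoor_wbgt(31, 60), indoor_wbgt(30, 60))   # monotone in ta
  expect_error(indoor_wbgt(30, 120), "\\[0, 100\\]")
})

test_that("outdoor WBGT responds correctly to radiation and wind", {
  # more sun -> hotter
  expect_gt(outdoor_wbgt(32, 50, 2, 800), outdoor_wbgt(32, 50, 2, 200))
  # more wind cools when the sun is up
  expect_gt(outdoor_wbgt(32, 50, 0.5, 600), outdoor_wbgt(32, 50, 4, 600))
  # with no radiation the wind dependence vanishes (globe -> air temp)
  w_lo <- outdoor_wbgt(30, 60, 0.5, 0)
  w_hi <- outdoor_wbgt(30, 60, 8, 0)
  expect_equal(w_lo, w_hi, tolerance = 1e-8)
  # at high wind the globe temperature approaches air temperature
  d <- abs(outdoor_wbgt(30, 60, c(1, 4, 16), 600) - outdoor_wbgt(30, 60, 64, 600))
  expect_true(all(diff(d) < 0))
  expect_error(outdoor_wbgt(30, 60, -1, 100), "wind")
  expect_error(outdoor_wbgt(30, 60, 1, -5), "rsds")
})

test_that("outdoor WBGT matches an independent re-implementation of its equations", {
  # straight-line oracle: same published equations, coded independently
  # (Stull wet-bulb regression; spherical energy balance solved by uniroot;
  # 0.7/0.2/0.1 composition with Tnwb = Tpwb + 0.25 (Tg - Ta))
  oracle <- function(ta, rh, u, S) {
    tw <- ta * atan(0.151977 * sqrt(rh + 8.313659)) + atan(ta + rh) -
      atan(rh - 1.676331) + 0.00391838 * rh^1.5 * atan(0.023101 * rh) -
      4.686035
    bal <- function(tg) {
      6.3 * max(u, 0.1)^0.6 * (tg - ta) +
        0.95 * 5.670374419e-8 * ((tg + 273.15)^4 - (ta + 273.15)^4) -
        0.25 * 0.95 * S
    }
    tg <- uniroot(bal, c(ta - 1, ta + 60), tol = 1e-10)$root
    0.7 * (tw + 0.25 * (tg - ta)) + 0.2 * tg + 0.1 * ta
  }
  cases <- data.frame(ta = c(25, 30, 33, 37, 40),
                      rh = c(30, 50, 60, 70, 80),
                      u = c(0.5, 1, 2, 3, 4),
                      S = c(100, 300, 500, 700, 900))
  for (i in seq_len(nrow(cases))) {
    got <- outdoor_wbgt(cases$ta[i], cases$rh[i], cases$u[i], cases$S[i])
    want <- oracle(cases$ta[i], cases$rh[i], cases$u[i], cases$S[i])
    expect_equal(got, want, tolerance = 0.2)
  }
})

test_that("4+4+4 disaggregation assigns the documented hour levels", {
  # degenerate day: one value everywhere
  wh <- disaggregate_444(28, 28)
  expect_equal(as.vector(workhour_values(wh)), rep(28, 8))
  # level arithmetic: mid = (28 + 34) / 2
  wh <- disaggregate_444(28, 34)
  vals <- as.vector(workhour_values(wh))
  expect_true(all(vals %in% c(28, 31, 34)))
  # hand enumeration of the default layout: working hours 8-11 and 13-16;
  # 11,13,14 carry max, 9,10,15,16 carry the midpoint, 8 carries the mean
  expect_equal(sort(vals), sort(c(28, rep(31, 4), rep(34, 3))))
  # delayed workday shifts the window
  wh2 <- disaggregate_444(28, 34, workday_def(delay = 2))
  expect_equal(unname(wh2$counts), c(2, 3, 3))   # mean, mid, max
  expect_error(disaggregate_444(30, 28), "wbgt_max")
  expect_error(workday_def(morning_end = 13), "8 working hours")
})

test_that("work-hour values are bracketed by the daily mean and max", {
  f <- generate_climate(tiny_cfg())$members[[1]]
  wb <- climate_to_wbgt(f)
  expect_true(all(wb$max_indoor >= wb$mean_indoor))
  expect_true(all(wb$max_outdoor >= wb$mean_outdoor))
  wh <- disaggregate_444(wb$mean_outdoor, wb$max_outdoor)
  hv <- workhour_values(wh)
  lo <- array(wb$mean_outdoor, dim(hv))
  hi <- array(wb$max_outdoor, dim(hv))
  expect_true(all(hv >= lo & hv <= hi))
})

test_that("threshold-day counts match closed-form crossing points", {
  grid <- make_grid(1, 1)
  ndays <- 365
  vals <- 25 + 5 * cos(2 * pi * (1:365 - 196) / 365)
  wb <- constant_wbgt_daily(0, ndays = ndays, year = 2000, grid = grid)
  wb$mean_indoor <- matrix(vals, ndays, 1)
  expect_equal(count_threshold_days(constant_wbgt_daily(30, 365), 25), 365)
  expect_equal(count_threshold_days(constant_wbgt_daily(20, 365), 25), 0)
  # sinusoid >= 25 iff cos >= 0: day in [196 - 365/4, 196 + 365/4];
  # integer days in [104.75, 287.25] -> 105..287
  expected <- floor(196 + 365 / 4) - ceiling(196 - 365 / 4) + 1
  expect_equal(count_threshold_days(wb, 25), expected)
  expect_error(count_threshold_days(wb, 25, period = period_def("x", 2050, 2060)),
               "no simulated days")
})
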