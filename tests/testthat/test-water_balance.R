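test_that("day length: equator, equinox, polar clamps, antisymmetry", {
  expect_equal(day_length(0, 1), 12, tolerance = 1e-6)
  expect_equal(day_length(0, 172), 12, tolerance = 1e-6)
  expect_equal(day_length(70, 172), 24)
  expect_equal(day_length(70, 355), 0)
  # equinox: declination zero day -> 12 h at any latitude
  d_eq <- which.min(abs(23.44 * sin(2 * pi * (284 + 1:365) / 365)))
  expect_equal(day_length(45, d_eq), 12, tolerance = 0.05)
  # antisymmetry: N + S day lengths sum to 24
  set.seed(9)
  lats <- runif(25, -89, 89); days <- sample(365, 25, replace = TRUE)
  expect_equal(day_length(lats, days) + day_length(-lats, days),
               rep(24, 25), tolerance = 1e-6)
  expect_error(day_length(95, 10), "latitude")
  expect_error(day_length(10, 400), "day_of_year")
})

test_that("day length table: equator row ~12 h, values clamped to [0, 24]", {
  tab <- day_length_table(seq(-90, 90, 15))
  eq <- tab$hours[tab$latitudes == 0, ]
  expect_true(all(abs(eq - 12) < 0.2))
  expect_true(all(tab$hours >= 0 & tab$hours <= 24))
  expect_true(any(tab$hours == 24) && any(tab$hours == 0))  # polar day/night
})

test_that("Thornthwaite PET reproduces the closed-form oracle", {
  g0 <- latlon_grid(0.25, 0.25, 0.5)    # snaps to latitude 0
  p <- thornthwaite_pet(pentad_clim(g0, rep(10, 12)))
  # independent evaluation of the heat index, exponent and PET equations
  I <- 12 * (10 / 5)^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  expect_equal(p$heat_index[1, 1], I, tolerance = 1e-12)
  expect_equal(p$exponent[1, 1], a, tolerance = 1e-12)
  L_jan <- mean(day_length(0, 1:31))
  expect_equal(p$pet[1, 1, 1],
               16 * (L_jan / 12) * (31 / 30) * (10 * 10 / I)^a,
               tolerance = 1e-9)
  # the canonical L = 12 h, N = 30 d case evaluates to ~48.9 mm
  expect_equal(16 * (10 * 10 / I)^a, 48.9, tolerance = 1e-3)

  # I = 12 exactly for constant 5 degC
  expect_equal(thornthwaite_pet(pentad_clim(g0, rep(5, 12)))$heat_index[1, 1], 12)
  # cold cutoff and I = 0 guard
  expect_equal(thornthwaite_pet(pentad_clim(g0, rep(-3, 12)))$pet,
               array(0, c(12, 1, 1)))
  expect_error(thornthwaite_pet(pentad_clim(g0, rep(1, 12), "precipitation")),
               "temperature")
})

test_that("PET uses 5-degree snapped day lengths and scales linearly in L", {
  g <- latlon_grid(c(56.25, 57.25, 58.25), 0.25, 1)    # snap: 55, 55, 60
  p <- thornthwaite_pet(pentad_clim(g, rep(10, 12)))
  expect_equal(p$pet[7, 1, 1], p$pet[7, 2, 1])   # same 55-degree band
  expect_false(isTRUE(all.equal(p$pet[7, 1, 1], p$pet[7, 3, 1])))
  pe <- thornthwaite_pet(pentad_clim(g, rep(10, 12)), snap = FALSE)
  expect_false(isTRUE(all.equal(pe$pet[7, 1, 1], pe$pet[7, 2, 1])))
  # July PET ratio equals the July day-length ratio (linear L/12 factor)
  mo <- rep(1:12, days_per_month())
  L55 <- mean(day_length(55, which(mo == 7)))
  L60 <- mean(day_length(60, which(mo == 7)))
  expect_equal(p$pet[7, 3, 1] / p$pet[7, 1, 1], L60 / L55, tolerance = 1e-9)
})

test_that("PET monotone in temperature near and above zero", {
  g0 <- latlon_grid(50.25, 0.25, 0.5)
  temps <- seq(0.5, 25, by = 0.5)
  jul <- sapply(temps, function(Tm) {
    tm <- rep(10, 12); tm[7] <- Tm
    thornthwaite_pet(pentad_clim(g0, tm))$pet[7, 1, 1]
  })
  expect_true(all(diff(jul) > 0))
  # continuity at T -> 0+
  tiny <- thornthwaite_pet(pentad_clim(g0, c(1e-6, rep(10, 11))))$pet[1, 1, 1]
  expect_lt(tiny, 0.01)
})

test_that("seasonal water balance: identity, arithmetic, guards, linearity", {
  g <- small_grid(2, 2, lat0 = 50.25)
  tcl <- pentad_clim(g, rep(12, 12))
  pet <- thornthwaite_pet(tcl)
  # P = PET every month -> balance 0, aridity 1
  pm <- array(NA_real_, c(12, 2, 2)); pm[] <- pet$pet
  pcl <- pentad_clim(g, pm, "precipitation")
  wb <- seasonal_water_balance(pcl, pet)
  expect_equal(wb$balance, matrix(0, 2, 2), tolerance = 1e-9)
  expect_equal(wb$aridity, matrix(1, 2, 2), tolerance = 1e-9)

  # hand arithmetic: P 50, PET 100 over 6 months
  fake_pet <- pet; fake_pet$pet[] <- 100
  wb2 <- seasonal_water_balance(pentad_clim(g, rep(50, 12), "precipitation"),
                                fake_pet)
  expect_equal(wb2$balance[1, 1], -300)
  expect_equal(wb2$aridity[1, 1], 0.5)
  expect_equal(wb2$precip[1, 1] - wb2$pet[1, 1], wb2$balance[1, 1])

  # PET = 0 all season -> aridity missing, balance = seasonal precip
  zero_pet <- pet; zero_pet$pet[] <- 0
  wb3 <- seasonal_water_balance(pentad_clim(g, rep(50, 12), "precipitation"),
                                zero_pet)
  expect_true(all(is.na(wb3$aridity)))
  expect_equal(wb3$balance, wb3$precip)

  # linearity: +c on each of the 6 season months shifts balance by 6c
  wb4 <- seasonal_water_balance(pentad_clim(g, rep(50 + 7, 12), "precipitation"),
                                fake_pet)
  expect_equal(wb4$balance, wb2$balance + 6 * 7)

  expect_error(seasonal_water_balance(pcl, pet, months = integer(0)), "empty")
  expect_error(seasonal_water_balance(tcl, pet), "precipitation")
})

test_that("aridity classification uses a strict < threshold and keeps NA", {
  g <- small_grid(1, 3)
  wb <- structure(list(aridity = matrix(c(0.65, 0.64, NA), 1, 3)),
                  class = "water_balance")
  cls <- classify_aridity(wb)
  expect_equal(cls[1, ], c(FALSE, TRUE, NA))
})

test_that("photoperiod profile over May-September", {
  prof <- photoperiod_profile(c(0, 45, 55, 65, 70))
  eq <- prof[prof$lat == 0, ]
  expect_equal(eq$min_h, 12, tolerance = 0.01)
  expect_equal(eq$max_h, 12, tolerance = 0.01)
  expect_equal(prof$max_h[prof$lat == 70], 24)
  # mean day length increases monotonically with latitude in this window
  dense <- photoperiod_profile(seq(0, 70, 5))
  expect_true(all(diff(dense$mean_h) > 0))
})
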