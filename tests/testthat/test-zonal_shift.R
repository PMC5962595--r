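make_mask <- function(grid, feasible) {
  structure(list(grid = grid, label_year = 2004L, threshold = 1200,
                 feasible = feasible,
                 missing = matrix(FALSE, length(grid$lat), length(grid$lon))),
            class = "feas_mask")
}

test_that("zonal summary arithmetic from masks and saturation cases", {
  g <- latlon_grid(seq(50.5, 69.5, 1), seq(0.5, 19.5, 1), 1)
  areas <- cell_areas(g)
  region <- region_mask("r", g, matrix(TRUE, 20, 20))
  feas <- matrix(FALSE, 20, 20); feas[1:10, ] <- TRUE    # southern half
  zs <- zonal_summary(make_mask(g, feas), region, areas, "p1")
  expect_equal(zs$feasible_area,
               sum(areas$area[1:10, ]) / 1e6, tolerance = 1e-12)
  expect_equal(zs$feasible_pct,
               100 * sum(areas$area[1:10, ]) / sum(areas$area), tolerance = 1e-12)
  # all-false and saturated masks
  expect_equal(zonal_summary(make_mask(g, feas & FALSE), region, areas)$feasible_pct, 0)
  expect_equal(zonal_summary(make_mask(g, !feas | TRUE), region, areas)$feasible_pct, 100)
  empty <- region_mask("none", g, matrix(FALSE, 20, 20))
  expect_error(zonal_summary(make_mask(g, feas), empty, areas), "empty")
})

test_that("gain summary arithmetic and zero-baseline flag", {
  b <- zonal_summary_from_areas("X", "cur", 10, 2)
  f <- zonal_summary_from_areas("X", "fut", 10, 5)
  gs <- gain_summary(b, f)
  expect_equal(gs$area_gain, 3)
  expect_equal(gs$pct_increase, 150)
  same <- gain_summary(b, b)
  expect_equal(same$area_gain, 0)
  expect_equal(same$pct_increase, 0)
  z <- gain_summary(zonal_summary_from_areas("X", "cur", 10, 0), f)
  expect_true(z$undefined_pct)
  expect_true(is.na(z$pct_increase))
  expect_error(gain_summary(b, zonal_summary_from_areas("Y", "fut", 10, 5)),
               "same region")
  expect_error(zonal_summary_from_areas("X", "p", 10, 11), "feasible area")
})

test_that("round_half_up matches printed-table rounding", {
  expect_equal(round_half_up(31.845), 32)
  expect_equal(round_half_up(0.5), 1)       # R's round() would give 0
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(68.306, 1), 68.3)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("latitude bands conserve region totals and partition cleanly", {
  g <- latlon_grid(seq(50.5, 69.5, 1), seq(-39.5, 39.5, 1), 1)
  areas <- cell_areas(g)
  set.seed(8)
  masks <- lapply(1:3, function(i)
    make_mask(g, matrix(runif(20 * 80) < 0.5, 20, 80)))
  west <- region_mask("west", g, matrix(rep(g$lon < 0, each = 20), 20, 80))
  east <- region_mask("east", g, matrix(rep(g$lon >= 0, each = 20), 20, 80))
  tab <- latitude_band_summary(masks, list(west, east), areas)
  for (k in 1:3) {
    tot <- sum(tab$feasible_area[tab$model == sprintf("model_%02d", k)])
    direct <- sum(areas$area[masks[[k]]$feasible]) / 1e6
    expect_equal(tot, direct, tolerance = 1e-9)
  }
  # half-open band labels
  expect_true("65-69N" %in% tab$band)
  # overlapping continents rejected
  expect_error(latitude_band_summary(masks, list(west, west), areas), "overlap")
  # changes vs baseline
  tab2 <- latitude_band_summary(masks, list(west, east), areas,
                                baseline_masks = masks)
  expect_true(all(tab2$change_vs_baseline == 0))
})

test_that("leading edge: read-off, absent columns, contiguity filter", {
  g <- latlon_grid(seq(50.5, 79.5, 1), c(0.5, 1.5, 2.5), 1)
  feas <- matrix(FALSE, 30, 3)
  feas[g$lat <= 55, 1] <- TRUE                 # solid block up to 54.5+
  feas[g$lat <= 60, 3] <- TRUE
  feas[g$lat == 75.5, 3] <- TRUE               # isolated single cell
  edge <- leading_edge(make_mask(g, feas))
  expect_equal(edge$edge_lat[1], 54.5)
  expect_true(is.na(edge$edge_lat[2]))
  expect_equal(edge$edge_lat[3], 75.5)         # raw maximum keeps the outlier
  edge2 <- leading_edge(make_mask(g, feas), min_contiguous = 2)
  expect_equal(edge2$edge_lat[3], 59.5)        # outlier suppressed
})

test_that("edge shift arithmetic and policy statuses", {
  base <- data.frame(lon = c(0.5, 1.5, 2.5, 3.5),
                     edge_lat = c(55, 60, NA, NA))
  futr <- data.frame(lon = c(0.5, 1.5, 2.5, 3.5),
                     edge_lat = c(60, 60, 62, NA))
  sh <- edge_shift(base, futr)
  expect_equal(sh$profile$shift_km[1], 5 * pi / 180 * 6371, tolerance = 1e-9)
  expect_equal(round(sh$profile$shift_km[1], 1), 556.0)
  expect_equal(sh$profile$shift_km[2], 0)
  expect_equal(sh$profile$status, c("ok", "ok", "new_colonization", "absent"))
  expect_true(is.na(sh$profile$shift_km[3]))
  expect_equal(sh$max_shift_km, sh$profile$shift_km[1])
  expect_error(edge_shift(base, futr[1:3, ]), "longitude axis")
})
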