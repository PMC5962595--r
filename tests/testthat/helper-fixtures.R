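# Shared builders for small in-code fixtures. All grids are tiny so the
# whole suite stays fast; nothing is read from disk except I/O round-trips
# into tempfiles.

small_grid <- function(nlat = 4, nlon = 3, lat0 = 40.25, lon0 = 10.25,
                       res = 0.5) {
  latlon_grid(seq(lat0, by = res, length.out = nlat),
              seq(lon0, by = res, length.out = nlon), res)
}

# mid-latitude band grid used for edge-shift experiments: 25.25..44.75 N
band_grid <- function(nlon = 10, res = 0.5) {
  latlon_grid(seq(25 + res / 2, 45 - res / 2, by = res),
              seq(0 + res / 2, by = res, length.out = nlon), res)
}

# noise-free single-model scenario used by analytic tests
quiet_spec <- function(grid, g = -0.6, A = 15, w = 0, base = 27, seed = 7L) {
  scenario_spec(grid, baseline_mean_at_equator = base, lat_gradient = g,
                seasonal_amplitude = A, warming_rate = w,
                model_offsets = 0, model_trend_factors = 1,
                noise_sd = 0, seed = seed)
}

# five identical years -> pentad equals any single year's monthly values
pentad_from_spec <- function(spec, label_year = 2004L, model = 1L) {
  ser <- generate_temperature_series(spec, model, label_year - 4L, label_year)
  pentad_average(ser, label_year)
}

# constant-climate monthly series over a year range
constant_series <- function(grid, value, years = 2000:2004,
                            variable = "temperature") {
  nt <- length(years) * 12L
  monthly_series(grid, variable,
                 data.frame(year = rep(years, each = 12),
                            month = rep(1:12, length(years))),
                 array(value, c(nt, length(grid$lat), length(grid$lon))))
}
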