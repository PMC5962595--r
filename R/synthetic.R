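#' Synthetic pseudo-GCM scenario specification
#'
#' Describes a stylized multi-model climate world used in place of real GCM
#' output: a latitude-dependent annual-mean temperature gradient, a seasonal
#' cycle peaking in July (northern hemisphere; mirrored in the south), a
#' secular warming trend that differs between pseudo-models, mean-zero
#' inter-model offsets, independent cell-level Gaussian noise, and a
#' matching precipitation field with a latitude-dependent multiplier and a
#' seasonal modulation.
#'
#' Defaults describe a plausibly Earth-like hemisphere: ~27 degC annual mean
#' at the equator falling at 0.6 degC per degree latitude, a 15 degC seasonal
#' amplitude at all latitudes, 0.4 degC/decade warming, a seven-member
#' pseudo-ensemble with mean-zero offsets and trend multipliers spanning
#' 0.7-1.3, and 0.5 degC monthly cell noise.
#'
#' @param grid a `latlon_grid`.
#' @param baseline_mean_at_equator annual-mean temperature at the equator, degC.
#' @param lat_gradient degC per degree of |latitude| (negative poleward).
#' @param seasonal_amplitude half peak-to-trough seasonal swing, degC.
#' @param warming_rate degC per decade applied from the series start year.
#' @param model_offsets per-model additive offsets, degC; should average 0.
#' @param model_trend_factors per-model unitless multipliers on `warming_rate`.
#' @param noise_sd monthly cell-level temperature noise sd, degC.
#' @param precip_base baseline precipitation, mm/month.
#' @param precip_lat_shape c(a0, a1): latitude multiplier `a0 + a1*cos(2*phi)`
#'   (wet tropics, dry poles).
#' @param precip_season_amp unitless seasonal modulation of precipitation.
#' @param precip_noise_cv coefficient of variation of multiplicative
#'   precipitation noise (0 disables it).
#' @param seed master integer seed; per-(model, variable, year) substreams
#'   are derived from it deterministically.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(grid,
                          baseline_mean_at_equator = 27,
                          lat_gradient = -0.6,
                          seasonal_amplitude = 15,
                          warming_rate = 0.4,
                          model_offsets = c(-0.9, -0.6, -0.3, 0, 0.3, 0.6, 0.9),
                          model_trend_factors = c(0.7, 0.8, 0.9, 1, 1.1, 1.2, 1.3),
                          noise_sd = 0.5,
                          precip_base = 70,
                          precip_lat_shape = c(0.7, 0.5),
                          precip_season_amp = 0.3,
                          precip_noise_cv = 0.1,
                          seed = 1L) {
  if (length(model_offsets) != length(model_trend_factors))
    stop("model_offsets and model_trend_factors must have equal length")
  if (noise_sd < 0 || seasonal_amplitude < 0)
    stop("noise_sd and seasonal_amplitude must be >= 0")
  structure(list(grid = grid,
                 baseline_mean_at_equator = baseline_mean_at_equator,
                 lat_gradient = lat_gradient,
                 seasonal_amplitude = seasonal_amplitude,
                 warming_rate = warming_rate,
                 model_offsets = model_offsets,
                 model_trend_factors = model_trend_factors,
                 noise_sd = noise_sd,
                 precip_base = precip_base,
                 precip_lat_shape = precip_lat_shape,
                 precip_season_amp = precip_season_amp,
                 precip_noise_cv = precip_noise_cv,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

n_models <- function(spec) length(spec$model_offsets)

# deterministic 32-bit substream seed per (model, variable code, year)
substream_seed <- function(seed, model_index, var_code, year) {
  as.integer((abs(seed) %% 65011 * 19349663 + model_index * 83492791 +
                var_code * 15485863 + year * 12007) %% 2147483647)
}

# deterministic (noise-free) monthly temperature, matrix nlat x nlon
synth_temp_mean <- function(spec, model_index, year, month, start_year) {
  g <- spec$grid
  hs <- ifelse(g$lat >= 0, 1, -1)
  base <- spec$baseline_mean_at_equator + spec$lat_gradient * abs(g$lat) +
    spec$seasonal_amplitude * cos(2 * pi * (month - 7) / 12) * hs
  trend <- spec$warming_rate * spec$model_trend_factors[model_index] *
    (year - start_year) / 10 + spec$model_offsets[model_index]
  matrix(base + trend, length(g$lat), length(g$lon))
}

#' Generate a monthly temperature series for one pseudo-model
#'
#' Monthly mean temperature per cell:
#' `T = T0 + g*|lat| + A*cos(2*pi*(month - 7)/12)*hemisphere_sign
#'    + w*f_i*(year - start_year)/10 + offset_i + eps`,
#' with `eps ~ N(0, noise_sd)` independent across cells, months and models.
#' Reproducible from the spec seed, model index and time alone.
#'
#' @param spec a `scenario_spec`.
#' @param model_index 1-based pseudo-model index.
#' @param start_year,end_year inclusive year range.
#' @return a `monthly_series` (temperature).
#' @export
generate_temperature_series <- function(spec, model_index, start_year, end_year) {
  check_model_years(spec, model_index, start_year, end_year)
  g <- spec$grid
  years <- start_year:end_year
  nt <- length(years) * 12L
  vals <- array(NA_real_, c(nt, length(g$lat), length(g$lon)))
  t <- 0L
  for (y in years) {
    eps <- year_noise(spec, model_index, 1L, y, sd = spec$noise_sd)
    for (m in 1:12) {
      t <- t + 1L
      vals[t, , ] <- synth_temp_mean(spec, model_index, y, m, start_year) +
        eps[m, , ]
    }
  }
  times <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  monthly_series(g, "temperature", times, vals)
}

year_noise <- function(spec, model_index, var_code, year, sd) {
  g <- spec$grid
  d <- c(12L, length(g$lat), length(g$lon))
  if (sd <= 0) return(array(0, d))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(spec$seed, model_index, var_code, year))
  array(stats::rnorm(prod(d), 0, sd), d)
}

check_model_years <- function(spec, model_index, start_year, end_year) {
  if (model_index < 1 || model_index > n_models(spec))
    stop("model_index outside the pseudo-ensemble")
  if (end_year < start_year) stop("end_year must be >= start_year")
  invisible(TRUE)
}

#' Generate a monthly precipitation series for one pseudo-model
#'
#' `P = max(0, P0 * (a0 + a1*cos(2*phi)) *
#'            (1 + s*cos(2*pi*(month - 7)/12)*hemisphere_sign) * (1 + eta))`
#' with `eta ~ N(0, precip_noise_cv)` when temperature noise is on
#' (`noise_sd > 0`), otherwise noise-free. Values are clamped at zero.
#'
#' @inheritParams generate_temperature_series
#' @return a `monthly_series` (precipitation).
#' @export
generate_precipitation_series <- function(spec, model_index, start_year, end_year) {
  check_model_years(spec, model_index, start_year, end_year)
  g <- spec$grid
  years <- start_year:end_year
  nt <- length(years) * 12L
  vals <- array(NA_real_, c(nt, length(g$lat), length(g$lon)))
  hs <- ifelse(g$lat >= 0, 1, -1)
  latmul <- spec$precip_lat_shape[1] +
    spec$precip_lat_shape[2] * cos(2 * g$lat * pi / 180)
  cv <- if (spec$noise_sd > 0) spec$precip_noise_cv else 0
  t <- 0L
  for (y in years) {
    eta <- year_noise(spec, model_index, 2L, y, sd = cv)
    for (m in 1:12) {
      t <- t + 1L
      seas <- 1 + spec$precip_season_amp * cos(2 * pi * (m - 7) / 12) * hs
      base <- matrix(spec$precip_base * latmul * seas,
                     length(g$lat), length(g$lon))
      vals[t, , ] <- pmax(0, base * (1 + eta[m, , ]))
    }
  }
  times <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  monthly_series(g, "precipitation", times, vals)
}

#' Generate one year of daily temperatures (oracle companion)
#'
#' Daily-resolution counterpart of [generate_temperature_series()] on a
#' 365-day no-leap calendar, used as an independent oracle for the
#' monthly-multiplier GDD approximation. The seasonal sinusoid is sampled
#' daily (`A*cos(2*pi*(doy - 196)/365)`, peak July 15) and then *recentred*
#' within each calendar month so that each month's daily mean equals the
#' monthly series value exactly. With `constant_within_month = TRUE` every
#' day carries the monthly value, making the daily GDD sum identical to the
#' monthly-multiplier computation.
#'
#' @inheritParams generate_temperature_series
#' @param year calendar year to generate.
#' @param start_year trend reference year (the series start).
#' @param constant_within_month if TRUE, days are constant at the monthly mean.
#' @return list with `grid`, `year`, `values` (array `365 x nlat x nlon`),
#'   and `month_of_day` (integer 365-vector).
#' @export
generate_daily_temperature <- function(spec, model_index, year,
                                       start_year = year,
                                       constant_within_month = FALSE) {
  check_model_years(spec, model_index, year, year)
  g <- spec$grid
  mdays <- days_per_month()
  month_of_day <- rep(1:12, mdays)
  doy <- seq_len(365)
  hs <- ifelse(g$lat >= 0, 1, -1)
  eps <- year_noise(spec, model_index, 1L, year, sd = spec$noise_sd)
  vals <- array(NA_real_, c(365L, length(g$lat), length(g$lon)))
  for (m in 1:12) {
    days <- which(month_of_day == m)
    monthly <- synth_temp_mean(spec, model_index, year, m, start_year) + eps[m, , ]
    if (constant_within_month) {
      for (d in days) vals[d, , ] <- monthly
    } else {
      seas <- outer(cos(2 * pi * (doy[days] - 196) / 365),
                    hs * spec$seasonal_amplitude)      # ndays x nlat
      seas <- sweep(seas, 2, colMeans(seas))           # recentre per month
      for (k in seq_along(days))
        vals[days[k], , ] <- sweep(monthly, 1, seas[k, ], `+`)
    }
  }
  list(grid = g, year = year, values = vals, month_of_day = month_of_day)
}

#' Generate pseudo-boreal, country and continent region masks
#'
#' Builds a "boreal" mask covering `boreal_band` latitudes over a fixed
#' land-analog set of longitudes (two pseudo-continents separated by
#' ocean-analog gaps), `n_countries` disjoint longitude-sector masks that
#' partition the boreal mask (cut points drawn from `seed`), and two
#' continent masks splitting the land at the -30 degE meridian
#' (America-analog west, Eurasia-analog east).
#'
#' @param grid a `latlon_grid`.
#' @param boreal_band c(lat_min, lat_max) in degrees.
#' @param n_countries number of pseudo-countries (>= 1).
#' @param seed integer seed for the country cut points.
#' @return named list: `boreal`, `countries` (list), `continents` (list of 2).
#' @export
generate_region_masks <- function(grid, boreal_band = c(50, 70),
                                  n_countries = 5L, seed = 1L) {
  if (boreal_band[1] >= boreal_band[2]) stop("empty latitude band")
  if (n_countries < 1) stop("n_countries must be >= 1")
  lat_in <- grid$lat >= boreal_band[1] & grid$lat <= boreal_band[2]
  if (!any(lat_in)) stop("empty latitude band on this grid")
  land <- (grid$lon >= -170 & grid$lon <= -52) |
    (grid$lon >= -10 & grid$lon <= 179)
  if (!any(land)) stop("grid has no land-analog longitudes")
  member <- outer(lat_in, land, `&`)
  boreal <- region_mask("boreal", grid, member)

  land_cols <- which(land)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_countries <- min(n_countries, length(land_cols))
  cuts <- sort(sample(length(land_cols) - 1L, n_countries - 1L))
  bounds <- c(0L, cuts, length(land_cols))
  countries <- lapply(seq_len(n_countries), function(k) {
    cols <- land_cols[(bounds[k] + 1L):bounds[k + 1L]]
    m <- matrix(FALSE, length(grid$lat), length(grid$lon))
    m[lat_in, cols] <- TRUE
    region_mask(sprintf("country_%02d", k), grid, m)
  })
  west <- land & grid$lon < -30
  east <- land & grid$lon >= -30
  continents <- list(
    region_mask("america_analog", grid, outer(lat_in, west, `&`)),
    region_mask("eurasia_analog", grid, outer(lat_in, east, `&`)))
  list(boreal = boreal, countries = countries, continents = continents)
}
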