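#' Astronomical day length
#'
#' Hours of daylight from the standard solar declination / sunset hour-angle
#' closed form: `delta = 23.44 * sin(2*pi*(284 + n)/365)` degrees,
#' `omega_s = acos(clamp(-tan(phi) tan(delta), -1, 1))`,
#' `hours = (24/pi) * omega_s`. The clamp yields exactly 24 h (polar day) or
#' 0 h (polar night) poleward of the polar circles in the respective
#' seasons. Vectorized over both arguments.
#'
#' @param lat latitude in degrees, |lat| <= 90.
#' @param day_of_year integer day 1..365 (no-leap calendar).
#' @return day length in hours, in `[0, 24]`.
#' @export
day_length <- function(lat, day_of_year) {
  if (any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  if (any(day_of_year < 1 | day_of_year > 365)) stop("day_of_year out of 1..365")
  delta <- 23.44 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  x <- pmin(pmax(-tan(lat * pi / 180) * tan(delta), -1), 1)
  24 / pi * acos(x)
}

#' Day-length table at discrete latitudes
#'
#' @param latitudes latitudes (degrees); default every 5 degrees pole to pole.
#' @return object of class `day_length_table`: `latitudes`, `hours`
#'   (matrix `nlat x 365`).
#' @export
day_length_table <- function(latitudes = seq(-90, 90, by = 5)) {
  hours <- outer(latitudes, 1:365, day_length)
  structure(list(latitudes = latitudes, hours = hours),
            class = "day_length_table")
}

month_of_day_365 <- function() rep(1:12, days_per_month())

# monthly mean day length per latitude: nlat x 12
monthly_day_length <- function(latitudes) {
  tab <- outer(latitudes, 1:365, day_length)
  mo <- month_of_day_365()
  out <- matrix(0, length(latitudes), 12L)
  for (m in 1:12) out[, m] <- rowMeans(tab[, mo == m, drop = FALSE])
  out
}

#' Thornthwaite potential evapotranspiration
#'
#' Classic (uncorrected) Thornthwaite method on a monthly climatology. Per
#' cell, the annual heat index is `I = sum over months with T > 0 of
#' (T/5)^1.514` and the exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`. Monthly PET is
#' `16 * (L/12) * (N/30) * (10 T / I)^a` mm for months with `T > 0`, else 0,
#' where `N` is the no-leap month length and `L` the monthly mean day length
#' evaluated at the cell's latitude snapped to the nearest `lat_interval`
#' multiple (`snap = FALSE` uses exact latitudes). Cells with `I = 0` get
#' zero PET in all months. No hot-month (>26.5 degC) alternative expression
#' is applied.
#'
#' @param clim temperature `pentad_clim`.
#' @param lat_interval snapping interval in degrees (default 5, reproducing
#'   the discrete-latitude banding of the source analysis).
#' @param snap snap latitudes to the interval (TRUE) or use exact latitudes.
#' @return object of class `pet_field`: `grid`, `label_year`, `pet` (array
#'   `12 x nlat x nlon`, mm/month), `heat_index` and `exponent` matrices.
#' @export
thornthwaite_pet <- function(clim, lat_interval = 5, snap = TRUE) {
  if (clim$variable != "temperature")
    stop("thornthwaite_pet requires a temperature climatology")
  g <- clim$grid
  lat_eff <- if (snap) round(g$lat / lat_interval) * lat_interval else g$lat
  lat_eff <- pmin(pmax(lat_eff, -90), 90)
  ulat <- sort(unique(lat_eff))
  Lu <- monthly_day_length(ulat)              # nunique x 12
  L <- Lu[match(lat_eff, ulat), , drop = FALSE]  # nlat x 12
  nl <- length(g$lat); no <- length(g$lon)
  I <- matrix(0, nl, no)
  for (m in 1:12) {
    Tm <- clim$monthly_mean[m, , ]
    I <- I + ifelse(Tm > 0, (Tm / 5)^1.514, 0)
  }
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  d <- days_per_month()
  pet <- array(NA_real_, c(12L, nl, no))
  for (m in 1:12) {
    Tm <- clim$monthly_mean[m, , ]
    Lm <- matrix(L[, m], nl, no)
    p <- ifelse(Tm > 0 & I > 0,
                16 * (Lm / 12) * (d[m] / 30) * (10 * Tm / I)^a,
                0)
    p[is.na(Tm) | is.na(I)] <- NA_real_
    pet[m, , ] <- p
  }
  structure(list(grid = g, label_year = clim$label_year, pet = pet,
                 heat_index = I, exponent = a),
            class = "pet_field")
}

#' Growing-season climatic water balance
#'
#' Sums monthly precipitation and PET over the growing-season months
#' (May-October by default), forms the climatic water balance
#' `C = P - PET` (mm; negative = deficit) and the aridity index `p/PET`
#' (missing where seasonal PET is zero). Monthly balance fields are retained
#' for within-season analyses (e.g. dry springs vs wet falls).
#'
#' @param precip_clim precipitation `pentad_clim`.
#' @param pet a `pet_field` on the same grid and label year.
#' @param months integer months of the growing season (default 5:10).
#' @return object of class `water_balance`: seasonal `precip`, `pet`,
#'   `balance`, `aridity` matrices, `monthly_balance` array, `months`.
#' @export
seasonal_water_balance <- function(precip_clim, pet, months = 5:10) {
  if (precip_clim$variable != "precipitation")
    stop("seasonal_water_balance requires a precipitation climatology")
  stopifnot_same_grid(precip_clim$grid, pet$grid)
  if (precip_clim$label_year != pet$label_year)
    stop("label_year mismatch between precipitation and PET")
  if (length(months) == 0) stop("growing-season month list must not be empty")
  g <- precip_clim$grid
  sp <- apply(precip_clim$monthly_mean[months, , , drop = FALSE], c(2, 3), sum)
  se <- apply(pet$pet[months, , , drop = FALSE], c(2, 3), sum)
  bal <- sp - se
  ar <- ifelse(!is.na(se) & se > 0, sp / se, NA_real_)
  mb <- precip_clim$monthly_mean[months, , , drop = FALSE] -
    pet$pet[months, , , drop = FALSE]
  structure(list(grid = g, label_year = pet$label_year,
                 precip = sp, pet = se, balance = bal, aridity = ar,
                 monthly_balance = mb, months = months),
            class = "water_balance")
}

#' Aridity classification
#'
#' TRUE where the growing-season aridity index `p/PET` falls strictly below
#' the threshold (default 0.65, the proposed aridification limit); missing
#' indices stay missing.
#'
#' @param bundle a `water_balance`.
#' @param threshold unitless p/PET threshold.
#' @return logical matrix (NA preserved).
#' @export
classify_aridity <- function(bundle, threshold = 0.65) {
  bundle$aridity < threshold
}

#' Photoperiod profile across latitudes
#'
#' Minimum, maximum and mean day length over the May-September window per
#' latitude, the photoperiod context for high-latitude cropping.
#'
#' @param latitudes latitudes in degrees.
#' @param months integer months (default 5:9).
#' @return data.frame with columns `lat`, `min_h`, `max_h`, `mean_h`.
#' @export
photoperiod_profile <- function(latitudes, months = 5:9) {
  mo <- month_of_day_365()
  days <- which(mo %in% months)
  hrs <- outer(latitudes, days, day_length)
  data.frame(lat = latitudes,
             min_h = apply(hrs, 1, min),
             max_h = apply(hrs, 1, max),
             mean_h = rowMeans(hrs))
}
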