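#' Days per month, 365-day no-leap calendar
#' @return integer vector of 12 month lengths.
#' @export
days_per_month <- function() c(31L, 28L, 31L, 30L, 31L, 30L,
                               31L, 31L, 30L, 31L, 30L, 31L)

#' Pentad (five-year) climatology
#'
#' Averages each calendar month over a five-year window ending at
#' `label_year` (the labelling convention: "2049" means 2045-2049). Any
#' missing monthly value inside the window makes that (month, cell) missing
#' in the climatology - no silent partial averages.
#'
#' @param series a `monthly_series` covering all 60 months of
#'   `[label_year - 4, label_year]`.
#' @param label_year window end year.
#' @return object of class `pentad_clim`: `grid`, `variable`, `label_year`,
#'   `window`, and `monthly_mean` (array `12 x nlat x nlon`).
#' @export
pentad_average <- function(series, label_year) {
  w0 <- label_year - 4L
  want <- as.vector(outer(1:12, w0:label_year,
                          function(m, y) y * 12L + (m - 1L)))
  have <- series$times$year * 12L + (series$times$month - 1L)
  miss <- setdiff(want, have)
  if (length(miss) > 0) {
    lab <- sprintf("%d-%02d", miss %/% 12L, miss %% 12L + 1L)
    stop(sprintf("pentad window %d-%d incomplete; missing months: %s",
                 w0, label_year, paste(sort(lab), collapse = ", ")))
  }
  g <- series$grid
  mm <- array(NA_real_, c(12L, length(g$lat), length(g$lon)))
  for (m in 1:12) {
    ti <- match((w0:label_year) * 12L + (m - 1L), have)
    mm[m, , ] <- apply(series$values[ti, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(grid = g, variable = series$variable,
                 label_year = as.integer(label_year),
                 window = c(w0, as.integer(label_year)),
                 monthly_mean = mm),
            class = "pentad_clim")
}

#' Build a pentad climatology directly from 12 monthly fields
#'
#' Convenience constructor for tests and analytic scenarios.
#' @param grid a `latlon_grid`.
#' @param monthly_mean array `12 x nlat x nlon` (or a 12-vector recycled over
#'   all cells).
#' @param variable `"temperature"` or `"precipitation"`.
#' @param label_year label (window end year).
#' @return a `pentad_clim`.
#' @export
pentad_clim <- function(grid, monthly_mean,
                        variable = c("temperature", "precipitation"),
                        label_year = 2003L) {
  variable <- match.arg(variable)
  nl <- length(grid$lat); no <- length(grid$lon)
  if (is.vector(monthly_mean) && length(monthly_mean) == 12L)
    monthly_mean <- array(rep(monthly_mean, nl * no), c(12L, nl, no))
  stopifnot(all(dim(monthly_mean) == c(12L, nl, no)))
  structure(list(grid = grid, variable = variable,
                 label_year = as.integer(label_year),
                 window = c(as.integer(label_year) - 4L, as.integer(label_year)),
                 monthly_mean = monthly_mean),
            class = "pentad_clim")
}

#' Annual growing degree days from monthly means
#'
#' Since the climatology has no daily resolution, months whose mean exceeds
#' `t_base` (strictly) contribute `(mean - t_base) * days_in_month` degree
#' days; colder months contribute nothing. No upper temperature cap is
#' applied. Month lengths come from the 365-day no-leap calendar. A cell
#' with any missing month is missing in the result.
#'
#' @param clim temperature `pentad_clim`.
#' @param t_base base temperature, degC (default 5, the GDD5 convention for
#'   cold-region small cereals).
#' @return object of class `gdd_field`: `grid`, `label_year`, `t_base`,
#'   `gdd` (matrix, degC day).
#' @export
annual_gdd <- function(clim, t_base = 5) {
  if (clim$variable != "temperature")
    stop("annual_gdd requires a temperature climatology")
  d <- days_per_month()
  g <- clim$grid
  gdd <- matrix(0, length(g$lat), length(g$lon))
  for (m in 1:12) {
    Tm <- clim$monthly_mean[m, , ]
    gdd <- gdd + ifelse(Tm > t_base, (Tm - t_base) * d[m], 0)
  }
  structure(list(grid = g, label_year = clim$label_year,
                 t_base = t_base, gdd = gdd),
            class = "gdd_field")
}

#' GDD crop-feasibility mask
#'
#' Cells with annual GDD at or above `threshold` (inclusive) are feasible.
#' Missing GDD cells are not feasible and are flagged in `missing`.
#'
#' @param gdd a `gdd_field`.
#' @param threshold degC day (default 1200, the small-cereal feasibility
#'   criterion).
#' @return object of class `feas_mask`: `grid`, `label_year`, `threshold`,
#'   logical matrices `feasible` and `missing`.
#' @export
feasibility <- function(gdd, threshold = 1200) {
  miss <- is.na(gdd$gdd)
  feas <- !miss & gdd$gdd >= threshold
  structure(list(grid = gdd$grid, label_year = gdd$label_year,
                 threshold = threshold, feasible = feas, missing = miss),
            class = "feas_mask")
}

#' Difference of two GDD fields (later minus earlier)
#'
#' @param later,earlier `gdd_field`s on the same grid with
#'   `later$label_year > earlier$label_year`.
#' @return signed matrix of degC day differences; missing in either input
#'   propagates.
#' @export
gdd_difference <- function(later, earlier) {
  stopifnot_same_grid(later$grid, earlier$grid)
  if (later$label_year <= earlier$label_year)
    stop("`later` must have a later label_year than `earlier`")
  later$gdd - earlier$gdd
}

#' Daily GDD oracle
#'
#' Direct daily degree-day sum `sum(max(T_d - t_base, 0))` over a year of
#' daily values, the reference the monthly-multiplier approximation is
#' validated against.
#'
#' @param daily output of [generate_daily_temperature()].
#' @param t_base base temperature, degC.
#' @return matrix of annual degree days per cell.
#' @export
daily_gdd <- function(daily, t_base = 5) {
  apply(pmax(daily$values - t_base, 0), c(2, 3), sum)
}
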