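#' Monthly climate series
#'
#' One climate variable (monthly mean temperature in degC or precipitation in
#' mm/month) on a lat-lon grid over a contiguous (year, month) axis. Missing
#' cells are `NA` in `values`; they are carried as missing, never zero-filled.
#'
#' @param grid a `latlon_grid`.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param times data.frame with integer columns `year`, `month`, in strictly
#'   increasing contiguous calendar order.
#' @param values numeric array `ntime x nlat x nlon`.
#' @return object of class `monthly_series`.
#' @export
monthly_series <- function(grid, variable = c("temperature", "precipitation"),
                           times, values) {
  variable <- match.arg(variable)
  times <- as.data.frame(times)
  stopifnot(all(c("year", "month") %in% names(times)))
  idx <- times$year * 12L + (times$month - 1L)
  if (nrow(times) > 1L && any(diff(idx) != 1L))
    stop("times must be contiguous calendar months in increasing order")
  d <- dim(values)
  if (length(d) != 3L || d[1] != nrow(times) ||
      d[2] != length(grid$lat) || d[3] != length(grid$lon))
    stop("values must be an ntime x nlat x nlon array matching times and grid")
  if (variable == "precipitation" && any(values < 0, na.rm = TRUE))
    stop("precipitation values must be >= 0 where not missing")
  structure(list(grid = grid, variable = variable, times = times,
                 values = values),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %s, %d months (%d-%02d .. %d-%02d), grid %d x %d\n",
              x$variable, nrow(x$times),
              x$times$year[1], x$times$month[1],
              x$times$year[nrow(x$times)], x$times$month[nrow(x$times)],
              length(x$grid$lat), length(x$grid$lon)))
  invisible(x)
}

units_for <- function(variable)
  if (variable == "temperature") "degC" else "mm/month"

n_comment_lines <- function(path) {
  head <- readLines(path, n = 50)
  sum(cumprod(startsWith(head, "#")))
}

#' Read a monthly climate grid from the long CSV format
#'
#' The on-disk format is a plain-text CSV with optional `#`-prefixed metadata
#' header lines (`# variable: ...`, `# units: ...`) followed by columns
#' `year,month,lat,lon,value`. Any (year, month, lat, lon) combination absent
#' from the file (or with an empty value) is flagged missing. Axes are
#' returned ascending regardless of row order. Grid spacing must be uniform;
#' temperature series whose values are all > 150 are rejected as Kelvin.
#'
#' @param path path to the CSV file.
#' @param variable `"temperature"` or `"precipitation"`.
#' @return a `monthly_series`.
#' @export
read_monthly_grid <- function(path, variable = c("temperature", "precipitation")) {
  variable <- match.arg(variable)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          skip = n_comment_lines(path),
                          colClasses = list(numeric = "value"))
  need <- c("year", "month", "lat", "lon", "value")
  if (!all(need %in% names(dt)))
    stop("CSV must have columns year,month,lat,lon,value")
  lat <- sort(unique(dt$lat)); lon <- sort(unique(normalize_lon(dt$lon)))
  res_lat <- if (length(lat) > 1) stats::median(diff(lat)) else 0.5
  res_lon <- if (length(lon) > 1) stats::median(diff(lon)) else res_lat
  if (length(lat) > 1 && length(lon) > 1 &&
      abs(res_lat - res_lon) > 1e-6)
    stop("lat and lon axes have different spacings; non-uniform grid")
  res <- if (length(lat) > 1) res_lat else res_lon
  check_uniform(lat, res, "lat")
  check_uniform_lon(lon, res)
  grid <- latlon_grid(lat, lon, res)
  tix <- sort(unique(dt$year * 12L + (dt$month - 1L)))
  tix <- seq(min(tix), max(tix))  # contiguous axis; absent months all-missing
  times <- data.frame(year = tix %/% 12L, month = tix %% 12L + 1L)
  vals <- array(NA_real_,
                c(length(tix), length(lat), length(lon)))
  ti <- match(dt$year * 12L + (dt$month - 1L), tix)
  ai <- match(round(dt$lat, 6), round(lat, 6))
  bi <- match(round(normalize_lon(dt$lon), 6), round(lon, 6))
  vals[cbind(ti, ai, bi)] <- dt$value
  if (variable == "temperature" &&
      any(!is.na(vals)) && all(vals > 150, na.rm = TRUE))
    stop("temperature values all > 150: looks like Kelvin; convert to degC first")
  monthly_series(grid, variable, times, vals)
}

#' Write a monthly climate grid to the long CSV format
#'
#' Writes `#` metadata lines recording the variable and its units
#' (`degC` for temperature, `mm/month` for precipitation) followed by
#' `year,month,lat,lon,value` rows. Missing cells are written with an empty
#' value field so the round trip preserves missingness exactly.
#'
#' @param series a `monthly_series`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_monthly_grid <- function(series, path) {
  g <- series$grid
  nt <- nrow(series$times)
  grid_long <- expand.grid(b = seq_along(g$lon), a = seq_along(g$lat),
                           t = seq_len(nt))
  dt <- data.table::data.table(
    year = series$times$year[grid_long$t],
    month = series$times$month[grid_long$t],
    lat = g$lat[grid_long$a],
    lon = g$lon[grid_long$b],
    value = series$values[cbind(grid_long$t, grid_long$a, grid_long$b)])
  con <- file(path, open = "wt")
  ok <- FALSE
  tryCatch({
    writeLines(c(sprintf("# variable: %s", series$variable),
                 sprintf("# units: %s", units_for(series$variable)),
                 sprintf("# resolution: %g", g$res)), con)
    close(con); ok <- TRUE
  }, finally = if (!ok) close(con))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read the metadata header of a grid CSV
#' @param path CSV path written by [write_monthly_grid()].
#' @return named character vector of `#` header fields.
#' @export
read_grid_metadata <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta)
  parts <- strsplit(kv, ":\\s*")
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = ":"), ""),
                  vapply(parts, `[[`, "", 1))
}

#' Write / read a region mask as CSV
#'
#' Plain-text `lat,lon,member` rows with a `# name:` header line.
#' @param mask a `region_mask`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_region_mask <- function(mask, path) {
  g <- mask$grid
  gl <- expand.grid(b = seq_along(g$lon), a = seq_along(g$lat))
  dt <- data.table::data.table(lat = g$lat[gl$a], lon = g$lon[gl$b],
                               member = as.integer(mask$member[cbind(gl$a, gl$b)]))
  writeLines(c(sprintf("# name: %s", mask$name),
               sprintf("# resolution: %g", g$res)), path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  meta <- read_grid_metadata(path)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          skip = n_comment_lines(path))
  lat <- sort(unique(dt$lat)); lon <- sort(unique(dt$lon))
  res <- as.numeric(meta[["resolution"]])
  grid <- latlon_grid(lat, lon, res)
  m <- matrix(FALSE, length(lat), length(lon))
  m[cbind(match(round(dt$lat, 6), round(lat, 6)),
          match(round(dt$lon, 6), round(lon, 6)))] <- dt$member > 0
  region_mask(meta[["name"]], grid, m)
}
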