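#' Lat-lon grid with cell-center registration
#'
#' Constructs a regular latitude-longitude grid. Coordinates are cell
#' *centers*; a cell spans `[center - res/2, center + res/2)` in longitude and
#' the analogous closed-at-the-poles interval in latitude. Longitudes are
#' normalized to `[-180, 180)`. Both axes must be uniformly spaced at
#' `resolution` degrees and ascending (inputs are sorted if needed).
#'
#' @param lat_centers numeric, latitude cell centers in degrees north,
#'   strictly inside (-90, 90) with cell edges within `[-90, 90]`.
#' @param lon_centers numeric, longitude cell centers in degrees east; any
#'   values are normalized into `[-180, 180)`.
#' @param resolution grid spacing in degrees (default 0.5).
#' @return an object of class `latlon_grid` with elements `lat`, `lon`,
#'   `res`, and logical `lon_global` (TRUE when the longitude axis closes the
#'   full circle, enabling wrap-aware regridding).
#' @examples
#' g <- latlon_grid(seq(50.25, 69.75, 0.5), seq(-10.25, 30.25, 0.5))
#' dim_grid(g)
#' @export
latlon_grid <- function(lat_centers, lon_centers, resolution = 0.5) {
  lat <- sort(as.numeric(lat_centers))
  lon <- sort(normalize_lon(as.numeric(lon_centers)))
  if (length(lat) < 1L || length(lon) < 1L)
    stop("grid needs at least one latitude and one longitude center")
  check_uniform(lat, resolution, "lat")
  check_uniform_lon(lon, resolution)
  if (any(lat <= -90 | lat >= 90))
    stop("latitude centers must lie strictly inside (-90, 90)")
  if (min(lat) - resolution / 2 < -90 - 1e-9 || max(lat) + resolution / 2 > 90 + 1e-9)
    stop("latitude cell edges must lie within [-90, 90]")
  lon_global <- isTRUE(all.equal(length(lon) * resolution, 360,
                                 tolerance = 1e-9))
  structure(list(lat = lat, lon = lon, res = resolution,
                 lon_global = lon_global),
            class = "latlon_grid")
}

#' Global grid at a given resolution
#'
#' @param resolution grid spacing in degrees.
#' @return `latlon_grid` covering the full sphere.
#' @export
global_grid <- function(resolution = 0.5) {
  h <- resolution / 2
  latlon_grid(seq(-90 + h, 90 - h, by = resolution),
              seq(-180 + h, 180 - h, by = resolution),
              resolution)
}

#' Grid dimensions
#' @param grid a `latlon_grid`.
#' @return integer c(nlat, nlon).
#' @export
dim_grid <- function(grid) c(length(grid$lat), length(grid$lon))

normalize_lon <- function(lon) {
  x <- (lon + 180) %% 360 - 180
  # %% can return 360 - eps artifacts; fold exactly
  x[x >= 180] <- x[x >= 180] - 360
  x
}

check_uniform <- function(ax, res, name) {
  if (length(ax) > 1L) {
    d <- diff(ax)
    if (any(abs(d - res) > 1e-6))
      stop(sprintf("non-uniform spacing on the %s axis: expected %g, found %g",
                   name, res, d[which.max(abs(d - res))]))
  }
  invisible(TRUE)
}

check_uniform_lon <- function(lon, res) {
  if (length(lon) > 1L) {
    d <- diff(lon)
    if (any(abs(d - res) > 1e-6))
      stop(sprintf("non-uniform spacing on the lon axis: expected %g, found %g",
                   res, d[which.max(abs(d - res))]))
  }
  invisible(TRUE)
}

same_grid <- function(a, b, tol = 1e-6) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol) &&
    abs(a$res - b$res) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("grids do not match; regrid explicitly first")
  invisible(TRUE)
}

#' @export
print.latlon_grid <- function(x, ...) {
  cat(sprintf("<latlon_grid> %d x %d cells at %g deg, lat [%g, %g], lon [%g, %g]%s\n",
              length(x$lat), length(x$lon), x$res, min(x$lat), max(x$lat),
              min(x$lon), max(x$lon),
              if (x$lon_global) " (lon-global)" else ""))
  invisible(x)
}

#' Spherical cell areas
#'
#' Exact area of each grid cell on a sphere of radius `earth_radius_km`:
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with `phi_top`,
#' `phi_bottom` the cell edge latitudes (clamped to +-90). Summed over a full
#' global grid this telescopes to `4*pi*R^2`.
#'
#' @param grid a `latlon_grid`.
#' @param earth_radius_km sphere radius; mean Earth radius 6371 km by default.
#' @return object of class `cell_area_field`: `grid` plus `area`, an
#'   `nlat x nlon` matrix in km^2.
#' @export
cell_areas <- function(grid, earth_radius_km = 6371) {
  h <- grid$res / 2
  top <- pmin(grid$lat + h, 90) * pi / 180
  bot <- pmax(grid$lat - h, -90) * pi / 180
  dlam <- grid$res * pi / 180
  band <- earth_radius_km^2 * dlam * (sin(top) - sin(bot))  # per-lat scalar
  area <- matrix(band, nrow = length(grid$lat), ncol = length(grid$lon))
  structure(list(grid = grid, area = area), class = "cell_area_field")
}

#' Regrid a field or series onto a target grid
#'
#' Bilinear (default for continuous fields) or nearest-neighbour
#' interpolation from the source grid's cell centers to the target's. No
#' extrapolation: target cells outside the source extent become missing.
#' Longitude interpolation wraps across the dateline when the source axis is
#' lon-global. Boolean region masks must use `nearest`.
#'
#' @param x a `monthly_series`, `region_mask`, or plain `nlat x nlon` matrix
#'   paired with `grid`.
#' @param target target `latlon_grid`.
#' @param method `"bilinear"` or `"nearest"`.
#' @param grid source grid, required only when `x` is a bare matrix.
#' @return the same type of object on the target grid.
#' @export
regrid <- function(x, target, method = c("bilinear", "nearest"), grid = NULL) {
  method <- match.arg(method)
  if (inherits(x, "region_mask")) {
    if (method != "nearest")
      stop("boolean masks must be regridded with method = 'nearest'")
    m <- regrid_matrix(x$member + 0, x$grid, target, "nearest")
    m[is.na(m)] <- 0
    return(region_mask(x$name, target, m > 0.5))
  }
  if (inherits(x, "monthly_series")) {
    nt <- dim(x$values)[1]
    out <- array(NA_real_, c(nt, length(target$lat), length(target$lon)))
    for (t in seq_len(nt))
      out[t, , ] <- regrid_matrix(x$values[t, , ], x$grid, target, method)
    return(monthly_series(target, x$variable, x$times, out))
  }
  if (is.matrix(x)) {
    if (is.null(grid)) stop("supply `grid` when regridding a bare matrix")
    return(regrid_matrix(x, grid, target, method))
  }
  stop("unsupported object for regrid()")
}

regrid_matrix <- function(v, src, dst, method) {
  if (same_grid(src, dst)) return(v)
  out <- matrix(NA_real_, length(dst$lat), length(dst$lon))
  # nearest covers the full source cells (centers +- res/2); bilinear is
  # bounded by the outermost centers (no extrapolation)
  pad <- if (method == "nearest") src$res / 2 else 0
  li <- axis_locate(dst$lat, src$lat, wrap = FALSE, pad = pad)
  lo <- axis_locate(dst$lon, src$lon, wrap = src$lon_global, pad = pad)
  if (method == "nearest") {
    ri <- ifelse(li$w < 0.5, li$i0, li$i1)
    rj <- ifelse(lo$w < 0.5, lo$i0, lo$i1)
    ok_i <- !is.na(ri); ok_j <- !is.na(rj)
    out[ok_i, ok_j] <- v[ri[ok_i], rj[ok_j], drop = FALSE]
    return(out)
  }
  for (a in seq_along(dst$lat)) {
    if (is.na(li$i0[a])) next
    for (b in seq_along(dst$lon)) {
      if (is.na(lo$i0[b])) next
      wy <- li$w[a]; wx <- lo$w[b]
      out[a, b] <-
        (1 - wy) * (1 - wx) * v[li$i0[a], lo$i0[b]] +
        (1 - wy) * wx       * v[li$i0[a], lo$i1[b]] +
        wy       * (1 - wx) * v[li$i1[a], lo$i0[b]] +
        wy       * wx       * v[li$i1[a], lo$i1[b]]
    }
  }
  out
}

# Bracketing source indices and interpolation weight for each target coord.
# Outside the source center range -> NA (no extrapolation), unless wrapping.
axis_locate <- function(xout, xin, wrap = FALSE, pad = 0) {
  n <- length(xin)
  i0 <- i1 <- integer(length(xout)); w <- numeric(length(xout))
  for (k in seq_along(xout)) {
    x <- xout[k]
    x <- min(max(x, xin[1]), xin[n])  # clamp inside the padded band below
    if (xout[k] >= xin[1] - pad - 1e-9 && xout[k] <= xin[n] + pad + 1e-9) {
      j <- max(1L, min(n - 1L, findInterval(x, xin)))
      if (n == 1L) { i0[k] <- i1[k] <- 1L; w[k] <- 0 }
      else {
        i0[k] <- j; i1[k] <- j + 1L
        w[k] <- (x - xin[j]) / (xin[j + 1] - xin[j])
        w[k] <- min(max(w[k], 0), 1)
      }
    } else if (wrap && n > 1L) {
      # between last and first center across the seam
      gap <- (xin[1] + 360) - xin[n]
      dx <- (xout[k] - xin[n]) %% 360
      if (dx <= gap + 1e-9) {
        i0[k] <- n; i1[k] <- 1L; w[k] <- dx / gap
      } else { i0[k] <- NA_integer_; i1[k] <- NA_integer_; w[k] <- NA_real_ }
    } else { i0[k] <- NA_integer_; i1[k] <- NA_integer_; w[k] <- NA_real_ }
  }
  list(i0 = i0, i1 = i1, w = w)
}

#' Region mask on a grid
#'
#' @param name label for the region.
#' @param grid a `latlon_grid`.
#' @param member logical `nlat x nlon` matrix of membership.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(name, grid, member) {
  member <- matrix(as.logical(member), length(grid$lat), length(grid$lon))
  member[is.na(member)] <- FALSE
  structure(list(name = name, grid = grid, member = member),
            class = "region_mask")
}
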