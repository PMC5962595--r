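#' Round half away from zero at a printed precision
#'
#' Table-style rounding (round-half-up for positive values), as opposed to
#' R's banker's rounding, used when reproducing printed area/percentage
#' tables.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Zonal feasibility summary for a region
#'
#' Area-weighted accounting of a feasibility mask over a region:
#' `feasible_area = sum of cell areas where feasible AND in region`,
#' `total_region_area = sum of cell areas in region`, and
#' `feasible_pct = 100 * feasible / total`. Areas are reported in
#' 10^6 km^2.
#'
#' @param mask a `feas_mask`.
#' @param region a `region_mask` on the same grid (must be non-empty).
#' @param areas a `cell_area_field` on the same grid.
#' @param period character period label (e.g. `"2095-2099"`).
#' @return object of class `zonal_summary` with `region`, `period`,
#'   `total_region_area`, `feasible_area` (10^6 km^2), `feasible_pct`.
#' @export
zonal_summary <- function(mask, region, areas, period = "") {
  stopifnot_same_grid(mask$grid, region$grid)
  stopifnot_same_grid(mask$grid, areas$grid)
  if (!any(region$member)) stop("region mask is empty")
  tot <- sum(areas$area[region$member]) / 1e6
  fea <- sum(areas$area[mask$feasible & region$member]) / 1e6
  zonal_summary_from_areas(region$name, period, tot, fea)
}

#' Build a zonal summary from known areas
#'
#' Direct constructor used when the areas are given (e.g. reproducing a
#' printed table) rather than measured from masks.
#'
#' @param region region label.
#' @param period period label.
#' @param total_region_area,feasible_area areas in 10^6 km^2.
#' @return a `zonal_summary`.
#' @export
zonal_summary_from_areas <- function(region, period, total_region_area,
                                     feasible_area) {
  if (feasible_area < 0 || feasible_area > total_region_area + 1e-9)
    stop("feasible area must lie in [0, total region area]")
  structure(list(region = region, period = period,
                 total_region_area = total_region_area,
                 feasible_area = feasible_area,
                 feasible_pct = 100 * feasible_area / total_region_area),
            class = "zonal_summary")
}

#' Area gain between two periods
#'
#' `area_gain = final - baseline` feasible area (10^6 km^2) and
#' `pct_increase = 100 * gain / baseline`.
#'
#' @param baseline,final `zonal_summary` objects for the same region.
#' @return object of class `gain_summary` with `region`, `baseline_period`,
#'   `final_period`, `area_gain`, `pct_increase` (NA with
#'   `undefined_pct = TRUE` when the baseline feasible area is zero).
#' @export
gain_summary <- function(baseline, final) {
  if (!identical(baseline$region, final$region))
    stop("gain_summary requires summaries for the same region")
  gain <- final$feasible_area - baseline$feasible_area
  undef <- baseline$feasible_area == 0
  structure(list(region = baseline$region,
                 baseline_period = baseline$period,
                 final_period = final$period,
                 area_gain = gain,
                 pct_increase = if (undef) NA_real_ else
                   100 * gain / baseline$feasible_area,
                 undefined_pct = undef),
            class = "gain_summary")
}

#' Feasible area by 5-degree latitude band, continent and model
#'
#' Half-open bands `[lower, lower + width)` labelled like `"65-69N"`. Per
#' (band, continent, model) the feasible area (10^6 km^2) is summed; when
#' `baseline_masks` is supplied the change versus the same model's baseline
#' is included. Continent masks must be pairwise disjoint.
#'
#' @param masks list of per-model `feas_mask` objects.
#' @param continents list of `region_mask` objects (pairwise disjoint).
#' @param areas a `cell_area_field`.
#' @param band_width band width in degrees (default 5).
#' @param baseline_masks optional list of per-model baseline `feas_mask`s.
#' @param model_ids optional labels for the models.
#' @return data.frame with columns `band`, `band_lower`, `continent`,
#'   `model`, `feasible_area`, and `change_vs_baseline` when baselines are
#'   given.
#' @export
latitude_band_summary <- function(masks, continents, areas, band_width = 5,
                                  baseline_masks = NULL, model_ids = NULL) {
  g <- masks[[1]]$grid
  for (m in masks) stopifnot_same_grid(g, m$grid)
  for (cm in continents) stopifnot_same_grid(g, cm$grid)
  stopifnot_same_grid(g, areas$grid)
  overlap <- Reduce(`+`, lapply(continents, function(cm) cm$member + 0))
  if (any(overlap > 1)) stop("continent masks overlap")
  if (is.null(model_ids)) model_ids <- sprintf("model_%02d", seq_along(masks))
  lowers <- seq(floor(min(g$lat) / band_width) * band_width,
                max(g$lat), by = band_width)
  band_of <- findInterval(g$lat, lowers)
  rows <- list()
  for (bi in seq_along(lowers)) {
    in_band <- band_of == bi
    if (!any(in_band)) next
    lab <- sprintf("%g-%gN", lowers[bi], lowers[bi] + band_width - 1)
    for (cm in continents) for (k in seq_along(masks)) {
      sel <- masks[[k]]$feasible & cm$member
      sel[!in_band, ] <- FALSE
      fa <- sum(areas$area[sel]) / 1e6
      row <- data.frame(band = lab, band_lower = lowers[bi],
                        continent = cm$name, model = model_ids[k],
                        feasible_area = fa)
      if (!is.null(baseline_masks)) {
        sb <- baseline_masks[[k]]$feasible & cm$member
        sb[!in_band, ] <- FALSE
        row$change_vs_baseline <- fa - sum(areas$area[sb]) / 1e6
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Leading-edge latitude per longitude column
#'
#' For each longitude, the northernmost (maximum-latitude) feasible cell that
#' belongs to a run of at least `min_contiguous` consecutive feasible cells
#' along the meridian; `NA` when the column has no qualifying cell. The
#' contiguity filter suppresses isolated outlier cells when > 1.
#'
#' @param mask a `feas_mask`.
#' @param min_contiguous minimum run length (default 1 = raw maximum).
#' @return data.frame with columns `lon`, `edge_lat`.
#' @export
leading_edge <- function(mask, min_contiguous = 1L) {
  g <- mask$grid
  edge <- rep(NA_real_, length(g$lon))
  for (j in seq_along(g$lon)) {
    col <- mask$feasible[, j]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= min_contiguous)
    if (length(ok) == 0) next
    edge[j] <- g$lat[ends[max(ok)]]
  }
  data.frame(lon = g$lon, edge_lat = edge)
}

#' Northward shift of the leading edge
#'
#' Meridional great-circle displacement per longitude column:
#' `shift_km = (future - baseline) * pi/180 * R` (positive northward).
#' Columns where the edge appears (absent -> present) are flagged
#' `"new_colonization"`, disappears `"lost"`, absent in both `"absent"`;
#' shift is defined only for `"ok"` columns.
#'
#' @param baseline_edge,future_edge data.frames from [leading_edge()] on the
#'   same longitude axis.
#' @param earth_radius_km sphere radius (default 6371).
#' @return object of class `shift_profile`: data.frame `profile` with
#'   columns `lon`, `baseline_lat`, `future_lat`, `shift_km`, `status`; plus
#'   `max_shift_km`.
#' @export
edge_shift <- function(baseline_edge, future_edge, earth_radius_km = 6371) {
  if (nrow(baseline_edge) != nrow(future_edge) ||
      any(abs(baseline_edge$lon - future_edge$lon) > 1e-6))
    stop("edge profiles must share the longitude axis")
  b <- baseline_edge$edge_lat; f <- future_edge$edge_lat
  status <- ifelse(is.na(b) & is.na(f), "absent",
            ifelse(is.na(b), "new_colonization",
            ifelse(is.na(f), "lost", "ok")))
  shift <- ifelse(status == "ok", (f - b) * pi / 180 * earth_radius_km,
                  NA_real_)
  prof <- data.frame(lon = baseline_edge$lon, baseline_lat = b,
                     future_lat = f, shift_km = shift, status = status)
  structure(list(profile = prof,
                 max_shift_km = if (any(status == "ok"))
                   max(shift, na.rm = TRUE) else NA_real_),
            class = "shift_profile")
}

#' @export
print.zonal_summary <- function(x, ...) {
  cat(sprintf("<zonal_summary> %s %s: feasible %.2f of %.2f x10^6 km^2 (%.1f%%)\n",
              x$region, x$period, x$feasible_area, x$total_region_area,
              x$feasible_pct))
  invisible(x)
}

#' @export
print.gain_summary <- function(x, ...) {
  cat(sprintf("<gain_summary> %s %s -> %s: gain %.2f x10^6 km^2 (%s%% increase)\n",
              x$region, x$baseline_period, x$final_period, x$area_gain,
              if (x$undefined_pct) "undefined" else
                format(round_half_up(x$pct_increase))))
  invisible(x)
}
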