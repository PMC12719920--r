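# Exclusion masking: water/crop land cover, category-buffered road corridors,
# and sub-acre urban parcels, combined into the layer inside which no
# classification is attempted.

#' Water/cropland exclusion mask from categorical land-cover grids
#'
#' Pixels whose land-cover code falls in the excluded set of any supplied
#' grid are masked (union across products, to capture the widest extent of
#' water and cropland), carried to the working lattice by nearest-neighbour
#' resampling, then buffered.
#'
#' @param lulc_grids List of categorical `wep_grid` (any resolution).
#' @param excluded_codes List (same length) of numeric code vectors to
#'   exclude per grid.
#' @param template Working-resolution `wep_grid`.
#' @param buffer_m Collar distance in meters (default 15).
#' @return Binary `wep_grid`.
#' @export
landcover_mask <- function(lulc_grids, excluded_codes, template,
                           buffer_m = 15) {
  stopifnot(length(lulc_grids) == length(excluded_codes))
  acc <- grid_like(template, 0)
  for (i in seq_along(lulc_grids)) {
    codes <- excluded_codes[[i]]
    if (!length(codes))
      stop(sprintf("empty excluded-code set for land-cover grid %d", i))
    g <- lulc_grids[[i]]
    m <- grid_like(g, as.numeric(g$values %in% codes))
    acc <- mask_union(acc, resample_to(m, template))
  }
  if (buffer_m > 0 && any(mask_values(acc) == 1))
    acc <- distance_buffer(acc, buffer_m)
  acc
}

#' Default road corridor half-widths in feet by category
#' @export
default_road_widths <- c(local = 25, turnpike = 250, ramp_frontage = 30)

#' Road corridor exclusion mask
#'
#' Each road segment is buffered by a per-category width: fixed table widths
#' for local / turnpike / ramp-frontage roads, the segment's reported width
#' for the generic `roadway` category, and a default when none is reported.
#' Widths are given in feet and applied per-side from the centerline.
#'
#' @param roads A `wep_features` of line geometries with a `category` column
#'   (`local`, `turnpike`, `ramp_frontage`, `roadway`) and an optional
#'   `width_ft` column for `roadway` segments.
#' @param template Working-resolution `wep_grid`.
#' @param width_table Named feet-per-category vector for the fixed classes.
#' @param default_width_ft Fallback width for `roadway` segments without a
#'   reported width (default 30 ft).
#' @return Binary `wep_grid`.
#' @export
road_mask <- function(roads, template, width_table = default_road_widths,
                      default_width_ft = 30) {
  out <- grid_like(template, 0)
  if (!length(roads$geoms)) return(out)
  cats <- roads$props$category
  widths <- if (!is.null(roads$props$width_ft)) roads$props$width_ft else
    rep(NA_real_, length(roads$geoms))
  for (i in seq_along(roads$geoms)) {
    cat_i <- cats[i]
    w_ft <- if (cat_i %in% names(width_table)) {
      width_table[[cat_i]]
    } else if (identical(cat_i, "roadway")) {
      if (!is.na(widths[i]) && widths[i] > 0) widths[i] else default_width_ft
    } else {
      stop(sprintf("unknown road category '%s' (segment %d)", cat_i, i))
    }
    out <- mask_union(out, rasterize(list(roads$geoms[[i]]), template,
                                     buffer_m = w_ft * M_PER_FT))
  }
  out
}

#' Urban exclusion mask from sub-acre municipal parcels
#'
#' Parcels strictly smaller than `max_acres` whose geometry intersects a
#' municipal boundary are treated as urban, rasterized and buffered.
#'
#' @param parcels `wep_features` of polygons; parcel area is taken from an
#'   `area_acres` property when present, else computed from the geometry.
#' @param municipal `wep_features` of municipal boundary polygons.
#' @param template Working-resolution `wep_grid`.
#' @param max_acres Strict upper size bound in acres (default 1).
#' @param buffer_m Collar distance in meters (default 30).
#' @return Binary `wep_grid`.
#' @export
urban_mask <- function(parcels, municipal, template, max_acres = 1,
                       buffer_m = 30) {
  out <- grid_like(template, 0)
  if (!length(parcels$geoms) || !length(municipal$geoms)) return(out)
  acres <- if (!is.null(parcels$props$area_acres)) parcels$props$area_acres
    else vapply(parcels$geoms, polygon_area_m2, 0) / M2_PER_ACRE
  urban <- list()
  for (i in seq_along(parcels$geoms)) {
    if (acres[i] >= max_acres) next
    touches <- any(vapply(municipal$geoms, polygons_intersect, TRUE,
                          b = parcels$geoms[[i]]))
    if (touches) urban[[length(urban) + 1]] <- parcels$geoms[[i]]
  }
  if (!length(urban)) return(out)
  m <- rasterize(urban, template)
  if (buffer_m > 0 && any(mask_values(m) == 1))
    m <- distance_buffer(m, buffer_m)
  m
}

#' Combine the exclusion components into one bundle
#'
#' @param water_crop,roads,urban Binary `wep_grid` on one shared geometry.
#' @return A list of class `wep_exclusions` with elements `water_crop`,
#'   `roads_urban` (roads union urban), and `combined`.
#' @export
combine_exclusions <- function(water_crop, roads, urban) {
  stop_geometry(water_crop, roads, "exclusion layers")
  stop_geometry(water_crop, urban, "exclusion layers")
  roads_urban <- mask_union(roads, urban)
  structure(list(water_crop = water_crop, roads_urban = roads_urban,
                 combined = mask_union(water_crop, roads_urban)),
            class = "wep_exclusions")
}
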