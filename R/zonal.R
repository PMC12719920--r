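# Zonal summaries: per-mapping-unit attribute records (parcels, watersheds,
# counties, whole territory) over the stage raster and companion layers.

FT_PER_M <- 1 / M_PER_FT

#' Terrain slope in percent (Horn 3x3)
#'
#' Horn's eight-neighbour finite-difference gradient on a meter-unit DEM;
#' slope = 100 * sqrt(gx^2 + gy^2). Border pixels are nodata.
#'
#' @param dem `wep_grid` of elevations in meters on a meter lattice.
#' @return `wep_grid` of slope percent.
#' @export
slope_percent <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  if (nr >= 3 && nc >= 3) {
    s <- dem$cell_size
    i <- 2:(nr - 1); j <- 2:(nc - 1)
    gx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
             (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * s)
    gy <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
             (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * s)
    out[i, j] <- 100 * sqrt(gx^2 + gy^2)
  }
  grid_like(dem, out)
}

#' Table-style cover percentages for one mapping unit
#'
#' The display arithmetic used in parcel attribute tables: percentages of
#' tree cover within the unit, juniper within tree cover, and juniper within
#' the unit, rounded to the nearest integer.
#'
#' @param unit_acres Unit area in acres.
#' @param tree_acres Tree-cover acres within the unit.
#' @param juniper_acres Juniper (woodland-transition) acres within the unit.
#' @return Named list: `tree_pct`, `juniper_share_of_tree_pct`,
#'   `juniper_pct`.
#' @export
parcel_cover_summary <- function(unit_acres, tree_acres, juniper_acres) {
  pct <- function(num, den) if (den > 0) round(100 * num / den) else 0
  list(tree_pct = pct(tree_acres, unit_acres),
       juniper_share_of_tree_pct = pct(juniper_acres, tree_acres),
       juniper_pct = pct(juniper_acres, unit_acres))
}

# zone raster: pixel-center containment, first unit wins on shared edges
zone_raster <- function(units, template) {
  zones <- matrix(0L, nrow(template$values), ncol(template$values))
  for (i in seq_along(units$geoms)) {
    m <- rasterize(list(units$geoms[[i]]), template)$values
    zones[m == 1 & zones == 0L] <- i
  }
  zones
}

#' Summarize stage, tree, terrain and height attributes per mapping unit
#'
#' One attribute record per unit polygon. Pixels are assigned to units by
#' pixel-center containment and clipped to the study boundary (nodata pixels
#' of the stage raster are not counted). Percentages are relative to the
#' unit's in-boundary area; height statistics are taken over the unit's
#' woodland-transition pixels and reported in feet, as is mean elevation.
#'
#' @param stages Stage raster from [stage_vulnerability()].
#' @param tree Binary `wep_grid` tree-cover mask.
#' @param chm `wep_grid` canopy-height model in meters.
#' @param units `wep_features` of unit polygons.
#' @param dem Optional `wep_grid` elevation in meters.
#' @param exclusions Optional `wep_exclusions` bundle; when given, the
#'   crops/water vs urban/roads split is reported, else those columns are NA.
#' @param id_field Name of the unit-id property (default `"unit_id"`; falls
#'   back to the row index).
#' @return A data.frame with one row per unit and the attribute columns
#'   (areas in acres, percentages unrounded in [0, 100]).
#' @export
summarize_units <- function(stages, tree, chm, units, dem = NULL,
                            exclusions = NULL, id_field = "unit_id") {
  stop_geometry(stages, tree, "zonal layers")
  stop_geometry(stages, chm, "zonal layers")
  if (!is.null(dem)) stop_geometry(stages, dem, "zonal layers")
  px_acre <- stages$cell_size^2 / M2_PER_ACRE
  zones <- zone_raster(units, stages)
  sv <- stages$values
  tv <- mask_values(tree)
  slope <- if (!is.null(dem)) slope_percent(dem)$values else NULL
  wc <- if (!is.null(exclusions)) mask_values(exclusions$water_crop) else NULL
  ru <- if (!is.null(exclusions)) mask_values(exclusions$roads_urban) else NULL
  ids <- if (id_field %in% names(units$props)) units$props[[id_field]] else
    as.character(seq_along(units$geoms))

  rows <- lapply(seq_along(units$geoms), function(i) {
    in_unit <- zones == i & !is.na(sv)
    n <- sum(in_unit)
    if (n == 0) {
      warning(sprintf("unit %s has no in-boundary pixels", ids[i]))
    }
    unit_acres <- n * px_acre
    pct <- function(a) if (unit_acres > 0) 100 * a / unit_acres else 0
    s_acres <- vapply(stage_codes, function(code)
      sum(sv[in_unit] == code) * px_acre, 0)
    tree_acres <- sum(tv[in_unit] == 1) * px_acre
    jun_acres <- s_acres[["woodland_transition"]]
    jun_px <- in_unit & sv == stage_codes[["woodland_transition"]]
    heights_ft <- chm$values[jun_px] * FT_PER_M
    heights_ft <- heights_ft[!is.na(heights_ft)]
    excl_acres <- s_acres[["excluded"]]
    data.frame(
      unit_id = ids[i],
      unit_area_acres = unit_acres,
      woodland_transition_acres = jun_acres,
      woodland_transition_pct = pct(jun_acres),
      encroachment_acres = s_acres[["encroachment"]],
      encroachment_pct = pct(s_acres[["encroachment"]]),
      dispersal_recruitment_acres = s_acres[["dispersal_recruitment"]],
      dispersal_recruitment_pct = pct(s_acres[["dispersal_recruitment"]]),
      intact_acres = s_acres[["intact"]],
      intact_pct = pct(s_acres[["intact"]]),
      tree_cover_acres = tree_acres,
      tree_cover_pct = pct(tree_acres),
      juniper_pct_of_tree_cover =
        if (tree_acres > 0) 100 * jun_acres / tree_acres else 0,
      mean_elevation_ft = if (!is.null(dem) && n > 0)
        mean(dem$values[in_unit], na.rm = TRUE) * FT_PER_M else NA_real_,
      mean_slope_pct = if (!is.null(slope) && n > 0)
        mean(slope[in_unit], na.rm = TRUE) else NA_real_,
      mean_juniper_height_ft = if (length(heights_ft))
        mean(heights_ft) else NA_real_,
      median_juniper_height_ft = if (length(heights_ft))
        stats::median(heights_ft) else NA_real_,
      crops_water_acres = if (!is.null(wc))
        sum(wc[in_unit] == 1) * px_acre else NA_real_,
      crops_water_pct = if (!is.null(wc))
        pct(sum(wc[in_unit] == 1) * px_acre) else NA_real_,
      urban_roads_acres = if (!is.null(ru))
        sum(ru[in_unit] == 1 & wc[in_unit] == 0) * px_acre else NA_real_,
      urban_roads_pct = if (!is.null(ru))
        pct(sum(ru[in_unit] == 1 & wc[in_unit] == 0) * px_acre) else
          NA_real_,
      exclusion_acres = excl_acres,
      exclusion_pct = pct(excl_acres),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write attribute records to CSV (and optionally GeoJSON)
#'
#' @param records Data frame from [summarize_units()].
#' @param path CSV output path.
#' @param units Optional `wep_features` whose geometries are joined to the
#'   records and written as GeoJSON.
#' @param geojson_path GeoJSON output path (required when `units` given).
#' @export
write_attributes <- function(records, path, units = NULL,
                             geojson_path = NULL) {
  utils::write.csv(records, path, row.names = FALSE)
  if (!is.null(units)) {
    if (is.null(geojson_path))
      geojson_path <- sub("\\.csv$", ".geojson", path)
    write_features(features_create(units$geoms, records, units$crs_id),
                   geojson_path)
  }
  invisible(path)
}

#' Read attribute records back from CSV
#' @param path CSV path written by [write_attributes()].
#' @export
read_attributes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
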