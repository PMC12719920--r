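# Canopy-height surface: tile mosaicking and the height-threshold canopy mask.

#' Merge canopy-height tiles onto a template lattice
#'
#' Tiles are resampled to the template (nearest-neighbour) and combined by
#' per-pixel maximum, so overlapping LiDAR collections keep the tallest
#' return. Pixels covered by no tile stay nodata. Negative heights (LiDAR
#' artifacts) clamp to zero.
#'
#' @param tiles List of `wep_grid` height tiles (meters above ground).
#' @param template Working-resolution `wep_grid`.
#' @return A `wep_grid` canopy-height model.
#' @export
merge_chm <- function(tiles, template) {
  if (!length(tiles)) stop("merge_chm needs at least one tile")
  acc <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  for (tile in tiles) {
    v <- resample_to(tile, template)$values
    take <- !is.na(v) & (is.na(acc) | v > acc)
    acc[take] <- v[take]
  }
  acc[!is.na(acc) & acc < 0] <- 0
  grid_like(template, acc)
}

#' Canopy mask from a canopy-height model
#'
#' Thresholds the height surface at `min_height_m` (inclusive; the default is
#' one foot, the floor below which returns are treated as ground/flat), then
#' smooths with [clean_mask()]. Nodata heights count as no canopy.
#'
#' @param chm `wep_grid` of heights in meters.
#' @param min_height_m Inclusive height threshold (default 0.3048 m = 1 ft).
#' @param open_radius_px Opening radius passed to [clean_mask()].
#' @param min_island_px Island floor passed to [clean_mask()].
#' @return Binary `wep_grid`.
#' @export
canopy_mask <- function(chm, min_height_m = M_PER_FT, open_radius_px = 1L,
                        min_island_px = 10L) {
  stopifnot(min_height_m > 0)
  v <- chm$values
  m <- grid_like(chm, as.numeric(!is.na(v) & v >= min_height_m))
  clean_mask(m, open_radius_px, min_island_px)
}
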