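# Spectral classification: vegetation indices, the summer NDVI+EVI tree
# filter, winter scene selection and compositing, and the leaf-off NDVI
# juniper filter.

#' Classifier thresholds
#'
#' Bundles the spectral and temporal gates of the stepwise classifier. The
#' index thresholds are interpreted on whatever radiometric scale the input
#' images are declared in (the EVI threshold of 1.8 presumes digital-number
#' inputs; EVI is scale-dependent).
#'
#' @param ndvi_tree Inclusive summer NDVI floor for tree cover (default 0.1).
#' @param evi_tree Inclusive summer EVI floor for tree cover (default 1.8).
#' @param ndvi_juniper Strict winter NDVI floor for juniper (default 0.35).
#' @param cloud_max Strict scene-level cloud fraction cap (default 0.10).
#' @param window_start,window_end Leaf-off window, `"MM-DD"` (defaults
#'   Jan 1 - Feb 14), applied per calendar year.
#' @return An object of class `wep_thresholds`.
#' @export
classifier_thresholds <- function(ndvi_tree = 0.1, evi_tree = 1.8,
                                  ndvi_juniper = 0.35, cloud_max = 0.10,
                                  window_start = "01-01",
                                  window_end = "02-14") {
  stopifnot(is.finite(ndvi_tree), is.finite(evi_tree), is.finite(ndvi_juniper),
            cloud_max >= 0, window_start <= window_end)
  structure(list(ndvi_tree = ndvi_tree, evi_tree = evi_tree,
                 ndvi_juniper = ndvi_juniper, cloud_max = cloud_max,
                 window_start = window_start, window_end = window_end),
            class = "wep_thresholds")
}

#' Dated multiband scene record
#'
#' @param blue,green,red,nir `wep_grid` bands sharing one geometry.
#' @param date Acquisition date (`Date` or ISO-8601 string).
#' @param cloud_fraction Scene cloud fraction in [0, 1].
#' @return An object of class `wep_scene`.
#' @export
scene_record <- function(blue, green, red, nir, date, cloud_fraction) {
  for (b in list(green, red, nir)) stop_geometry(blue, b, "scene bands")
  stopifnot(cloud_fraction >= 0, cloud_fraction <= 1)
  structure(list(blue = blue, green = green, red = red, nir = nir,
                 date = as.Date(date),
                 cloud_fraction = as.numeric(cloud_fraction)),
            class = "wep_scene")
}

#' Normalized difference vegetation index
#'
#' `(NIR - R) / (NIR + R)`; pixels with a zero denominator become nodata.
#'
#' @param nir,red `wep_grid` bands sharing geometry.
#' @return A `wep_grid` of index values.
#' @export
ndvi <- function(nir, red) {
  stop_geometry(nir, red, "index bands")
  den <- nir$values + red$values
  out <- (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA_real_
  grid_like(nir, out)
}

#' Enhanced vegetation index
#'
#' `G (NIR - R) / (NIR + C1 R - C2 B + L)` with the standard constant set
#' G = 2.5, C1 = 6, C2 = 7.5, L = 1. Note EVI is not scale-free: thresholds
#' must be stated on the same radiometric scale as the bands.
#'
#' @param nir,red,blue `wep_grid` bands sharing geometry.
#' @param G,C1,C2,L Index constants.
#' @return A `wep_grid` of index values.
#' @export
evi <- function(nir, red, blue, G = 2.5, C1 = 6, C2 = 7.5, L = 1) {
  stop_geometry(nir, red, "index bands")
  stop_geometry(nir, blue, "index bands")
  den <- nir$values + C1 * red$values - C2 * blue$values + L
  out <- G * (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA_real_
  grid_like(nir, out)
}

#' Summer tree-cover filter
#'
#' A pixel is tree cover when it has canopy (height mask), passes both the
#' NDVI and EVI summer greenness gates (inclusive), and is not excluded.
#'
#' @param canopy Binary `wep_grid` canopy mask.
#' @param ndvi_summer,evi_summer `wep_grid` summer index layers.
#' @param exclusion Binary `wep_grid` combined exclusion layer.
#' @param th A [classifier_thresholds()] object.
#' @return Binary `wep_grid`.
#' @export
tree_cover <- function(canopy, ndvi_summer, evi_summer, exclusion,
                       th = classifier_thresholds()) {
  stop_geometry(canopy, ndvi_summer, "tree-cover layers")
  stop_geometry(canopy, evi_summer, "tree-cover layers")
  stop_geometry(canopy, exclusion, "tree-cover layers")
  nv <- ndvi_summer$values; ev <- evi_summer$values
  keep <- mask_values(canopy) == 1 &
    !is.na(nv) & nv >= th$ndvi_tree &
    !is.na(ev) & ev >= th$evi_tree &
    mask_values(exclusion) == 0
  grid_like(canopy, as.numeric(keep))
}

#' Filter a scene catalog to usable leaf-off acquisitions
#'
#' Keeps scenes with cloud fraction strictly below `th$cloud_max` whose date
#' falls inside the leaf-off window of its calendar year.
#'
#' @param catalog List of [scene_record()] objects.
#' @param th A [classifier_thresholds()] object.
#' @return Filtered list of scenes.
#' @export
filter_scenes <- function(catalog, th = classifier_thresholds()) {
  keep <- vapply(catalog, function(sc) {
    md <- format(sc$date, "%m-%d")
    sc$cloud_fraction < th$cloud_max &&
      md >= th$window_start && md <= th$window_end
  }, TRUE)
  catalog[keep]
}

#' Mean winter composite of a scene list
#'
#' Per-band, per-pixel arithmetic mean over the scenes in which the pixel is
#' valid; pixels invalid in every scene stay nodata. The composite carries
#' the latest scene date and zero cloud fraction.
#'
#' @param scenes Non-empty list of [scene_record()] sharing geometry.
#' @return A [scene_record()].
#' @export
winter_composite <- function(scenes) {
  if (!length(scenes)) stop("winter_composite needs at least one scene")
  band_mean <- function(name) {
    acc <- matrix(0, nrow(scenes[[1]][[name]]$values),
                  ncol(scenes[[1]][[name]]$values))
    n <- acc
    for (sc in scenes) {
      stop_geometry(scenes[[1]][[name]], sc[[name]], "composite scenes")
      v <- sc[[name]]$values
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      n[ok] <- n[ok] + 1
    }
    out <- acc / n
    out[n == 0] <- NA_real_
    grid_like(scenes[[1]][[name]], out)
  }
  scene_record(band_mean("blue"), band_mean("green"), band_mean("red"),
               band_mean("nir"),
               date = max(as.Date(vapply(scenes, function(s)
                 format(s$date), ""))),
               cloud_fraction = 0)
}

#' Leaf-off juniper filter
#'
#' Restricts the tree-cover mask to pixels whose winter composite NDVI is
#' strictly greater than the juniper threshold (evergreens keep their green
#' signal in winter), then smooths with [clean_mask()]. The output is a
#' subset of the tree mask by construction.
#'
#' @param tree Binary `wep_grid` tree-cover mask (working resolution).
#' @param winter_ndvi_1m Winter NDVI `wep_grid` on the same lattice (coarser
#'   satellite NDVI resampled beforehand).
#' @param th A [classifier_thresholds()] object.
#' @param open_radius_px,min_island_px Passed to [clean_mask()].
#' @return Binary `wep_grid`.
#' @export
juniper_cover <- function(tree, winter_ndvi_1m, th = classifier_thresholds(),
                          open_radius_px = 1L, min_island_px = 10L) {
  stop_geometry(tree, winter_ndvi_1m, "juniper layers")
  wv <- winter_ndvi_1m$values
  keep <- mask_values(tree) == 1 & !is.na(wv) & wv > th$ndvi_juniper
  m <- clean_mask(grid_like(tree, as.numeric(keep)), open_radius_px,
                  min_island_px)
  # cleaning dilates back from the eroded core; never exceed the tree mask
  mask_intersect(m, tree)
}
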