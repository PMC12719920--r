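# Woody-encroachment vulnerability staging: distance rings around the
# modeled juniper (woodland-transition) mask.

#' Stage codes used by the vulnerability raster
#'
#' 0 excluded, 1 woodland transition, 2 encroachment, 3
#' dispersal/recruitment, 4 intact.
#' @export
stage_codes <- c(excluded = 0, woodland_transition = 1, encroachment = 2,
                 dispersal_recruitment = 3, intact = 4)

#' Stage the landscape by distance from the juniper mask
#'
#' Codes each pixel by Euclidean distance `d` to the nearest juniper pixel:
#' woodland transition where juniper itself; encroachment where
#' `0 < d <= encroach_buffer_m`; dispersal/recruitment in the further annulus
#' out to `encroach_buffer_m + dispersal_buffer_m`; intact beyond. Exclusion
#' pixels overwrite to code 0 as a final overlay (rings propagate across
#' excluded ground: a road does not shield the far side from seed). Nodata
#' pixels of the juniper mask (outside the study boundary) stay nodata.
#'
#' @param juniper Binary `wep_grid` juniper mask.
#' @param exclusion Binary `wep_grid` combined exclusion mask.
#' @param encroach_buffer_m Encroachment ring width in meters (default 50).
#' @param dispersal_buffer_m Additional dispersal/recruitment ring width in
#'   meters (default 200).
#' @return A `wep_grid` of stage codes (class `wep_stages` prepended).
#' @export
stage_vulnerability <- function(juniper, exclusion, encroach_buffer_m = 50,
                                dispersal_buffer_m = 200) {
  stop_geometry(juniper, exclusion, "staging layers")
  stopifnot(encroach_buffer_m > 0, dispersal_buffer_m > 0)
  d <- distance_to_mask(juniper)
  out <- matrix(stage_codes[["intact"]], nrow(d), ncol(d))
  out[d <= encroach_buffer_m + dispersal_buffer_m] <-
    stage_codes[["dispersal_recruitment"]]
  out[d <= encroach_buffer_m] <- stage_codes[["encroachment"]]
  out[mask_values(juniper) == 1] <- stage_codes[["woodland_transition"]]
  out[mask_values(exclusion) == 1] <- stage_codes[["excluded"]]
  out[is.na(juniper$values)] <- NA_real_
  g <- grid_like(juniper, out)
  class(g) <- c("wep_stages", class(g))
  g
}

#' Acreage per vulnerability stage
#'
#' @param stages A stage raster from [stage_vulnerability()].
#' @return Named numeric vector of acres for the five codes; sums to the
#'   in-boundary area.
#' @export
stage_areas <- function(stages) {
  px_acre <- stages$cell_size^2 / M2_PER_ACRE
  vapply(stage_codes, function(code)
    sum(stages$values == code, na.rm = TRUE) * px_acre, 0)
}
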