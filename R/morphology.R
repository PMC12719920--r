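# Binary-mask morphology and Euclidean distance buffering.
# EBImage does the heavy lifting; masks are zero-padded by the kernel radius
# first so that pixels outside the lattice behave as 0 (EBImage itself
# replicates edges, which would keep the border of an all-ones mask intact
# under erosion).

pad0 <- function(v, r) {
  out <- matrix(0, nrow(v) + 2 * r, ncol(v) + 2 * r)
  out[(r + 1):(r + nrow(v)), (r + 1):(r + ncol(v))] <- v
  out
}

unpad <- function(v, r, nr, nc) v[(r + 1):(r + nr), (r + 1):(r + nc)]

morph <- function(mask, radius_px, op) {
  stopifnot(radius_px >= 1)
  v <- mask_values(mask)
  r <- as.integer(radius_px)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "box")
  p <- pad0(v, r)
  out <- if (op == "erode") EBImage::erode(p, brush) else
    EBImage::dilate(p, brush)
  grid_like(mask, unpad(out, r, nrow(v), ncol(v)))
}

#' Morphological erosion of a binary mask
#'
#' Square structuring element of side `2 * radius_px + 1`; pixels outside the
#' lattice and nodata pixels count as 0.
#'
#' @param mask Binary `wep_grid`.
#' @param radius_px Kernel radius in pixels (>= 1).
#' @return Binary `wep_grid`.
#' @export
erode <- function(mask, radius_px) morph(mask, radius_px, "erode")

#' Morphological dilation of a binary mask
#'
#' @inheritParams erode
#' @export
dilate <- function(mask, radius_px) morph(mask, radius_px, "dilate")

# 4-connected component labels; 0 = background
label_components <- function(v) {
  EBImage::bwlabel(v)
}

#' Clean a binary mask: opening plus small-island removal
#'
#' Applies a morphological opening (erode then dilate) of the given radius,
#' then removes 4-connected components smaller than `min_island_px`. This is
#' the smoothing step applied to the canopy and juniper layers to drop
#' speckle and fill pinholes.
#'
#' @param mask Binary `wep_grid`.
#' @param open_radius_px Opening radius in pixels; 0 skips the opening.
#' @param min_island_px Minimum surviving component size in pixels; 0 keeps
#'   everything.
#' @return Binary `wep_grid`.
#' @export
clean_mask <- function(mask, open_radius_px = 1L, min_island_px = 10L) {
  stopifnot(open_radius_px >= 0, min_island_px >= 0)
  out <- mask
  if (open_radius_px >= 1)
    out <- dilate(erode(out, open_radius_px), open_radius_px)
  if (min_island_px > 0) {
    v <- mask_values(out)
    if (any(v == 1)) {
      lab <- label_components(v)
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < min_island_px)
      if (length(drop)) v[lab %in% drop] <- 0
    }
    out <- grid_like(out, v)
  }
  out
}

# distance (meters, center-to-center) from every pixel to the nearest 1-pixel;
# Inf when the mask is empty
distance_to_mask <- function(mask) {
  v <- mask_values(mask)
  if (!any(v == 1)) return(matrix(Inf, nrow(v), ncol(v)))
  d <- EBImage::distmap(1 - v, metric = "euclidean")
  matrix(d, nrow(v), ncol(v)) * mask$cell_size
}

#' Euclidean distance buffer around a binary mask
#'
#' Marks every pixel whose center lies within `distance_m` of the center of
#' some 1-pixel (exact Euclidean distance transform). Always a superset of
#' the input.
#'
#' @param mask Binary `wep_grid`.
#' @param distance_m Buffer distance in meters (>= 0).
#' @return Binary `wep_grid`.
#' @export
distance_buffer <- function(mask, distance_m) {
  stopifnot(distance_m >= 0)
  d <- distance_to_mask(mask)
  grid_like(mask, as.numeric(d <= distance_m))
}
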