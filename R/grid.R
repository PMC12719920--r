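# Grid: the in-memory raster carrier used by every pipeline stage.
# Row-major matrix, top-left origin, square cells in projected meters.
# nodata is represented internally as NA; the sentinel is only used on disk.

M_PER_FT <- 0.3048
M2_PER_ACRE <- 4046.8564224

#' Create a raster grid
#'
#' The universal raster container of the pipeline: a numeric matrix on a
#' uniform square lattice in a projected (meter-unit) coordinate system.
#' Pixel `(r, c)` (1-based) covers the half-open square
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]` where `s` is the
#' cell size and `(x0, y0)` the top-left corner.
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2: projected x, y of the top-left corner.
#' @param crs_id Coordinate reference system identifier, e.g. `"EPSG:32614"`.
#'   Must be a projected system with meter linear units.
#' @param nodata Sentinel written to disk for `NA` cells.
#' @return An object of class `wep_grid`.
#' @export
grid_create <- function(values, cell_size, origin = c(0, 0),
                        crs_id = "EPSG:32614", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(cell_size > 0, length(origin) == 2, nrow(values) >= 1,
            ncol(values) >= 1)
  if (any(is.infinite(values), na.rm = TRUE))
    stop("grid values must be finite or nodata")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), crs_id = crs_id,
                 nodata = nodata),
            class = "wep_grid")
}

#' @export
print.wep_grid <- function(x, ...) {
  cat(sprintf("<wep_grid %d x %d @ %g m, origin (%g, %g), %s>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs_id))
  invisible(x)
}

#' @export
dim.wep_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "wep_grid")

#' Test whether two grids share geometry
#'
#' Same dimensions, cell size, origin and CRS (values may differ).
#' @param a,b `wep_grid` objects.
#' @param tol Tolerance in meters for origin/cell-size comparison.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol) &&
    identical(a$crs_id, b$crs_id)
}

stop_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("%s do not share geometry (%dx%d @%gm vs %dx%d @%gm)",
                 what, nrow(a$values), ncol(a$values), a$cell_size,
                 nrow(b$values), ncol(b$values), b$cell_size))
  invisible(TRUE)
}

# same values matrix shape/geometry, new values
grid_like <- function(template, values) {
  g <- template
  g$values <- matrix(as.numeric(values), nrow(template$values),
                     ncol(template$values))
  g
}

#' Build an empty grid template
#'
#' @param nrow,ncol Lattice dimensions.
#' @param cell_size Cell edge in meters.
#' @param origin Top-left corner (x, y).
#' @param crs_id CRS identifier.
#' @param fill Initial value (default 0).
#' @export
grid_template <- function(nrow, ncol, cell_size = 1, origin = c(0, nrow * cell_size),
                          crs_id = "EPSG:32614", fill = 0) {
  grid_create(matrix(fill, nrow, ncol), cell_size, origin, crs_id)
}

# x/y coordinates of pixel centers
grid_col_x <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
grid_row_y <- function(g) g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * g$cell_size

# point -> (row, col), or NA outside; half-open square containment
grid_rowcol <- function(g, x, y) {
  col <- floor((x - g$origin[1]) / g$cell_size) + 1L
  row <- floor((g$origin[2] - y) / g$cell_size) + 1L
  # top edge (y == y0) belongs to row 1; left edge to col 1 by the floor;
  # the half-open convention puts y exactly on an interior horizontal edge
  # into the pixel below-left pattern: x in [x_l, x_r), y in (y_b, y_t]
  at_edge <- (g$origin[2] - y) / g$cell_size
  on_line <- abs(at_edge - round(at_edge)) < 1e-12 & round(at_edge) >= 1
  row[on_line] <- round(at_edge[on_line])
  bad <- row < 1 | row > nrow(g$values) | col < 1 | col > ncol(g$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Resample a grid onto a template lattice
#'
#' Nearest-neighbour assignment: each output pixel takes the value of the
#' source pixel that contains the output pixel's center. Used to carry 10 m
#' satellite products onto the 1 m working lattice.
#'
#' @param src Source `wep_grid`.
#' @param template `wep_grid` defining the output geometry.
#' @param method Only `"nearest"` is supported.
#' @return A `wep_grid` with the template's geometry.
#' @export
resample_to <- function(src, template, method = c("nearest")) {
  method <- match.arg(method)
  if (!identical(src$crs_id, template$crs_id))
    stop(sprintf("CRS mismatch: %s vs %s", src$crs_id, template$crs_id))
  if (same_geometry(src, template)) return(grid_like(template, src$values))
  xs <- grid_col_x(template)
  ys <- grid_row_y(template)
  sc <- floor((xs - src$origin[1]) / src$cell_size) + 1L
  sr <- floor((src$origin[2] - ys) / src$cell_size) + 1L
  sc[sc < 1 | sc > ncol(src$values)] <- NA_integer_
  sr[sr < 1 | sr > nrow(src$values)] <- NA_integer_
  out <- matrix(NA_real_, length(ys), length(xs))
  ok_r <- which(!is.na(sr)); ok_c <- which(!is.na(sc))
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c] <- src$values[sr[ok_r], sc[ok_c], drop = FALSE]
  grid_like(template, out)
}

#' Area of a binary mask in acres
#'
#' @param mask A `wep_grid` with values in `{0, 1, NA}`.
#' @return Acres covered by 1-pixels (1 acre = 4046.8564224 m^2).
#' @export
area_acres <- function(mask) {
  n1 <- sum(mask$values == 1, na.rm = TRUE)
  n1 * mask$cell_size^2 / M2_PER_ACRE
}

# coerce any grid to a strict {0,1} matrix, NA -> 0
mask_values <- function(mask) {
  v <- mask$values
  v[is.na(v)] <- 0
  v[v != 0] <- 1
  v
}

check_binary <- function(mask) {
  v <- mask$values
  if (!all(v %in% c(0, 1) | is.na(v)))
    stop("mask values must be in {0, 1, nodata}")
  invisible(TRUE)
}

# pixelwise union/intersection preserving geometry of a
mask_union <- function(a, b) {
  stop_geometry(a, b, "masks")
  grid_like(a, pmax(mask_values(a), mask_values(b)))
}

mask_intersect <- function(a, b) {
  stop_geometry(a, b, "masks")
  grid_like(a, mask_values(a) * mask_values(b))
}
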