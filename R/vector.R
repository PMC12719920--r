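# Lightweight vector layer model: a feature collection holds a list of
# geometries (point / line / polygon-with-holes) plus a properties data frame
# and a CRS id. GeoJSON is the on-disk format (via jsonlite).

#' Create a feature collection
#'
#' @param geoms List of geometries. Each geometry is a list with `type`
#'   (`"point"`, `"line"` or `"polygon"`) and either `coords` (numeric x,y
#'   vector for points, N x 2 matrix for lines) or `rings` (list of N x 2
#'   matrices, exterior first, holes after) for polygons.
#' @param props Data frame of per-feature attributes (one row per geometry).
#' @param crs_id CRS identifier shared by all coordinates.
#' @return An object of class `wep_features`.
#' @export
features_create <- function(geoms, props = NULL, crs_id = "EPSG:32614") {
  if (is.null(props)) props <- data.frame(row.names = seq_along(geoms))
  stopifnot(nrow(props) == length(geoms))
  structure(list(geoms = geoms, props = props, crs_id = crs_id),
            class = "wep_features")
}

#' @export
print.wep_features <- function(x, ...) {
  cat(sprintf("<wep_features: %d features [%s], %s>\n", length(x$geoms),
              paste(unique(vapply(x$geoms, `[[`, "", "type")), collapse = ","),
              x$crs_id))
  invisible(x)
}

#' @export
length.wep_features <- function(x) length(x$geoms)

#' Subset a feature collection
#' @param x A `wep_features`.
#' @param i Index vector.
#' @param ... Unused.
#' @export
`[.wep_features` <- function(x, i, ...) {
  features_create(x$geoms[i], x$props[i, , drop = FALSE], x$crs_id)
}

# --- geometry constructors used throughout the package and the generator ---

#' Rectangle polygon from corner coordinates
#' @param xmin,ymin,xmax,ymax Corner coordinates (meters).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  list(type = "polygon",
       rings = list(cbind(c(xmin, xmax, xmax, xmin, xmin),
                          c(ymin, ymin, ymax, ymax, ymin))))
}

#' Regular-polygon approximation of a circle
#' @param cx,cy Center (meters).
#' @param r Radius (meters).
#' @param n Number of vertices.
#' @export
circle_polygon <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  list(type = "polygon", rings = list(cbind(cx + r * cos(th),
                                            cy + r * sin(th))))
}

line_geom <- function(coords) list(type = "line", coords = coords)
point_geom <- function(x, y) list(type = "point", coords = c(x, y))

# --- planar predicates ---------------------------------------------------

# even-odd point-in-ring test, vectorized over points
points_in_ring <- function(px, py, ring) {
  inside <- rep(FALSE, length(px))
  n <- nrow(ring)
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

# min distance from each point to a polyline given as an N x 2 matrix
points_seg_dist <- function(px, py, coords) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1)) {
    ax <- coords[i, 1]; ay <- coords[i, 2]
    bx <- coords[i + 1, 1]; by <- coords[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- pmin(d, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
  }
  d
}

geom_coords <- function(geom) {
  switch(geom$type,
         point = matrix(geom$coords, 1, 2),
         line = geom$coords,
         polygon = do.call(rbind, geom$rings))
}

geom_bbox <- function(geom) {
  xy <- geom_coords(geom)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# segment-pair intersection test (proper or touching)
segs_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) ||
    (d1 == 0 || d2 == 0 || d3 == 0 || d4 == 0)
}

#' Do two polygons intersect?
#'
#' True when any vertex of one lies inside the other or any boundary edges
#' cross. Sufficient for the convex-ish administrative and parcel polygons
#' the pipeline deals in.
#' @param a,b Polygon geometries (`rings` lists).
#' @export
polygons_intersect <- function(a, b) {
  ea <- a$rings[[1]]; eb <- b$rings[[1]]
  ba <- geom_bbox(a); bb <- geom_bbox(b)
  if (ba["xmin"] > bb["xmax"] || bb["xmin"] > ba["xmax"] ||
      ba["ymin"] > bb["ymax"] || bb["ymin"] > ba["ymax"]) return(FALSE)
  if (any(points_in_polygon(ea[, 1], ea[, 2], b$rings))) return(TRUE)
  if (any(points_in_polygon(eb[, 1], eb[, 2], a$rings))) return(TRUE)
  for (i in seq_len(nrow(ea) - 1)) for (j in seq_len(nrow(eb) - 1)) {
    if (segs_intersect(ea[i, ], ea[i + 1, ], eb[j, ], eb[j + 1, ]))
      return(TRUE)
  }
  FALSE
}

#' Planar polygon area in square meters (shoelace; holes subtracted)
#' @param geom A polygon geometry.
#' @export
polygon_area_m2 <- function(geom) {
  shoelace <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  areas <- vapply(geom$rings, shoelace, 0)
  areas[1] - sum(areas[-1])
}

# --- rasterization --------------------------------------------------------

#' Rasterize geometries onto a template lattice
#'
#' A pixel is set when its center lies inside a polygon, inside the buffer_m
#' neighbourhood of a polygon boundary or polyline, or within buffer_m of a
#' point. Lines with `buffer_m = 0` therefore have measure zero and rasterize
#' to nothing: give lines their corridor half-width through `buffer_m`.
#'
#' @param geoms A `wep_features` collection (or list of geometries).
#' @param template `wep_grid` defining the output lattice.
#' @param buffer_m Buffer distance in meters applied to every geometry.
#' @return Binary `wep_grid` on the template geometry.
#' @export
rasterize <- function(geoms, template, buffer_m = 0) {
  if (inherits(geoms, "wep_features")) {
    if (!identical(geoms$crs_id, template$crs_id))
      stop(sprintf("CRS mismatch: %s vs %s", geoms$crs_id, template$crs_id))
    geoms <- geoms$geoms
  }
  out <- matrix(0, nrow(template$values), ncol(template$values))
  xs <- grid_col_x(template); ys <- grid_row_y(template)
  s <- template$cell_size
  for (geom in geoms) {
    bb <- geom_bbox(geom)
    cols <- which(xs >= bb["xmin"] - buffer_m - s &
                    xs <= bb["xmax"] + buffer_m + s)
    rows <- which(ys >= bb["ymin"] - buffer_m - s &
                    ys <= bb["ymax"] + buffer_m + s)
    if (!length(cols) || !length(rows)) next
    px <- rep(xs[cols], each = length(rows))
    py <- rep(ys[rows], times = length(cols))
    hit <- rep(FALSE, length(px))
    if (geom$type == "polygon") {
      hit <- points_in_polygon(px, py, geom$rings)
      if (buffer_m > 0) {
        for (ring in geom$rings)
          hit <- hit | points_seg_dist(px, py, ring) <= buffer_m
      }
    } else if (geom$type == "line") {
      if (buffer_m > 0)
        hit <- points_seg_dist(px, py, geom$coords) <= buffer_m
    } else if (geom$type == "point") {
      hit <- sqrt((px - geom$coords[1])^2 + (py - geom$coords[2])^2) <=
        buffer_m
    }
    if (any(hit))
      out[rows, cols] <- pmax(out[rows, cols],
                              matrix(as.numeric(hit), length(rows),
                                     length(cols)))
  }
  grid_like(template, out)
}

# --- GeoJSON I/O ----------------------------------------------------------

geom_to_geojson <- function(geom) {
  switch(geom$type,
    point = list(type = "Point", coordinates = as.numeric(geom$coords)),
    line = list(type = "LineString",
                coordinates = lapply(seq_len(nrow(geom$coords)), function(i)
                  as.numeric(geom$coords[i, ]))),
    polygon = list(type = "Polygon",
                   coordinates = lapply(geom$rings, function(r)
                     lapply(seq_len(nrow(r)), function(i)
                       as.numeric(r[i, ])))))
}

geojson_to_geom <- function(gj) {
  ring_mat <- function(rg) do.call(rbind, lapply(rg, function(p)
    c(p[[1]], p[[2]])))
  switch(gj$type,
    Point = point_geom(gj$coordinates[[1]], gj$coordinates[[2]]),
    LineString = line_geom(ring_mat(gj$coordinates)),
    Polygon = list(type = "polygon",
                   rings = lapply(gj$coordinates, ring_mat)),
    MultiPolygon = list(type = "polygon",   # first shell only
                        rings = lapply(gj$coordinates[[1]], ring_mat)),
    stop(sprintf("unsupported GeoJSON geometry: %s", gj$type)))
}

#' Write a feature collection to GeoJSON
#' @param feats A `wep_features`.
#' @param path Output path.
#' @export
write_features <- function(feats, path) {
  fl <- lapply(seq_along(feats$geoms), function(i) {
    pr <- as.list(feats$props[i, , drop = FALSE])
    list(type = "Feature",
         properties = if (length(pr)) pr else structure(list(), names = character()),
         geometry = geom_to_geojson(feats$geoms[[i]]))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = feats$crs_id)),
              features = fl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a GeoJSON feature collection
#' @param path GeoJSON path.
#' @param crs_id CRS to assume when the file declares none.
#' @export
read_features <- function(path, crs_id = "EPSG:32614") {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop(sprintf("%s is not a GeoJSON FeatureCollection", path))
  if (!is.null(obj$crs$properties$name)) crs_id <- obj$crs$properties$name
  geoms <- lapply(obj$features, function(f) geojson_to_geom(f$geometry))
  prop_list <- lapply(obj$features, function(f) {
    p <- f$properties
    if (is.null(p) || !length(p)) list(.dummy = NA) else
      lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(prop_list, names)))
  props <- as.data.frame(lapply(keys, function(k)
    unlist(lapply(prop_list, function(p) if (is.null(p[[k]])) NA else p[[k]]))),
    col.names = keys, stringsAsFactors = FALSE, optional = TRUE)
  names(props) <- keys
  props$.dummy <- NULL
  features_create(geoms, props, crs_id)
}
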