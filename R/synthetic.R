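# Synthetic landscape generator: co-registered vector and raster inputs with
# known ground truth. Emulates the statistical structure the classifier
# assumes -- evergreen vs deciduous winter greenness, the 1 m vs 10 m
# resolution mismatch (winter bands are exact 10x10 block means of a latent
# 1 m radiance field, the mixed-pixel mechanism), scene-level cloud
# fractions, and the four juniper spatial configurations (lone, edge, group,
# stand).

#' Synthetic landscape configuration
#'
#' All randomness flows from `seed`; identical configs give bit-identical
#' bundles. Radiometry is Gaussian per cover type on a 0-255 digital-number
#' scale, chosen so that (i) summer NDVI/EVI separate trees from grass,
#' (ii) 1 m winter NDVI separates evergreen (about 0.78) from leaf-off
#' deciduous and dormant grass (about 0.11-0.13) across the juniper
#' threshold 0.35, and (iii) after 10 m block averaging a satellite cell
#' crosses the 0.35 threshold near 21% evergreen coverage -- so lone crowns
#' (at most about 20 sq m per 100 sq m cell) stay undetectable while stand
#' interiors and most stand boundary cells are detected.
#'
#' @param extent_m Square landscape edge in meters (multiple of 10).
#' @param cell_size Working cell size in meters (1).
#' @param seed Integer seed fixing all randomness.
#' @param n_lone,n_edge_rows,n_group,n_stand Object counts per juniper class
#'   (an edge row holds several collinear crowns along a road).
#' @param n_deciduous Deciduous patch count.
#' @param degrade_to_10m Aggregate winter scenes to 10 m block means (the
#'   study's satellite resolution); `FALSE` keeps the latent 1 m radiance.
#' @param scene_dates,scene_clouds Winter scene catalog: ISO dates and cloud
#'   fractions (defaults include one out-of-window and one over-cloudy scene
#'   so catalog filtering is exercised).
#' @param origin,crs_id Spatial registration of every generated layer.
#' @return A list of class `wep_landscape_config`.
#' @export
landscape_config <- function(extent_m = 1000, cell_size = 1, seed = 1,
                             n_lone = 12, n_edge_rows = 4, n_group = 10,
                             n_stand = 6, n_deciduous = 8,
                             degrade_to_10m = TRUE,
                             scene_dates = c("2021-01-05", "2021-01-20",
                                             "2021-02-10", "2021-03-01",
                                             "2022-01-15", "2022-01-25",
                                             "2022-02-01"),
                             scene_clouds = c(0.02, 0.05, 0.08, 0.02,
                                              0.03, 0.35, 0.06),
                             origin = c(600000, 3900000),
                             crs_id = "EPSG:32614") {
  stopifnot(extent_m %% 10 == 0, cell_size == 1,
            length(scene_dates) == length(scene_clouds))
  structure(list(
    extent_m = extent_m, cell_size = cell_size, seed = as.integer(seed),
    n_lone = n_lone, n_edge_rows = n_edge_rows, n_group = n_group,
    n_stand = n_stand, n_deciduous = n_deciduous,
    degrade_to_10m = degrade_to_10m,
    scene_dates = scene_dates, scene_clouds = scene_clouds,
    origin = origin, crs_id = crs_id,
    # crown geometry (meters)
    crown_r = list(lone = c(2.35, 2.5), edge = c(2.6, 3), group = c(3, 3.4),
                   stand = c(3, 4.5), deciduous = c(3, 5)),
    crowns_per = list(group = c(4, 5), stand = c(14, 20),
                      deciduous = c(4, 8), edge = c(4, 7)),
    height_m = list(juniper = c(2, 8), deciduous = c(3, 10)),
    # radiometry: per cover, band means (B, G, R, NIR) on DN 0-255
    summer_dn = list(grass = c(50, 70, 60, 90), tree = c(34, 80, 30, 150),
                     water = c(80, 70, 60, 10), crop = c(45, 75, 50, 100),
                     road = c(90, 90, 90, 95)),
    winter_dn = list(grass = c(55, 58, 42, 55), evergreen = c(20, 60, 10, 140),
                     deciduous = c(48, 50, 40, 50), water = c(80, 70, 60, 10),
                     crop = c(70, 70, 70, 80), road = c(90, 90, 90, 95)),
    band_sd = 2), class = "wep_landscape_config")
}

# 10x10 block mean of an n x n matrix (n a multiple of 10)
block_mean_10 <- function(v) {
  n <- nrow(v); r <- n %/% 10L
  g <- rep(seq_len(r), each = 10L)
  t(rowsum(t(rowsum(v, g)), g)) / 100
}

# draw crown centers for a cluster: k points within `spread` of (cx, cy)
cluster_crowns <- function(cx, cy, k, spread, r_range) {
  th <- stats::runif(k, 0, 2 * pi)
  rr <- spread * sqrt(stats::runif(k))
  data.frame(x = cx + rr * cos(th), y = cy + rr * sin(th),
             r = stats::runif(k, r_range[1], r_range[2]))
}

# stamp circular crowns into 0/1 matrix + height matrix (max rule)
stamp_crowns <- function(mask, chm, crowns, heights, origin, n) {
  for (i in seq_len(nrow(crowns))) {
    cx <- crowns$x[i] - origin[1]
    cy <- origin[2] - crowns$y[i]          # row-space y
    r <- crowns$r[i]
    rows <- max(1, floor(cy - r)):min(n, ceiling(cy + r + 1))
    cols <- max(1, floor(cx - r)):min(n, ceiling(cx + r + 1))
    px <- cols - 0.5; py <- rows - 0.5
    d2 <- outer(py - cy, px - cx, function(a, b) a^2 + b^2)
    hit <- d2 <= r^2
    mask[rows, cols][hit] <- 1
    chm[rows, cols][hit] <- pmax(chm[rows, cols][hit], heights[i])
  }
  list(mask = mask, chm = chm)
}

#' Generate a synthetic landscape with ground truth
#'
#' Builds the full co-registered input stack -- two 10 m land-cover grids
#' (different legends, slightly different water extents), road and parcel
#' vectors with a municipal boundary, two overlapping 1 m canopy-height
#' tiles, a 1 m 4-band summer image, a catalog of dated winter scenes (10 m
#' block means of the latent 1 m radiance unless degradation is disabled),
#' a gentle DEM -- plus the truth masks and an object registry.
#'
#' Junipers are never planted inside (or within a safety margin of) the
#' exclusion footprint, so truth and exclusions are disjoint by
#' construction. Lone crowns are kept isolated; edge rows run along local
#' roads just outside the corridor buffer.
#'
#' @param cfg A [landscape_config()].
#' @return A list of class `wep_landscape` (see elements in the source).
#' @export
generate_landscape <- function(cfg) {
  set.seed(cfg$seed)
  n <- as.integer(cfg$extent_m)
  org <- cfg$origin
  template <- grid_template(n, n, 1, org, cfg$crs_id)
  x0 <- org[1]; y0 <- org[2]

  # --- vectors -----------------------------------------------------------
  boundary <- features_create(list(rect_polygon(x0, y0 - n, x0 + n, y0)),
                              crs_id = cfg$crs_id)

  # water body and crop fields (placed in fixed thirds, jittered)
  water_c <- c(x0 + stats::runif(1, 0.62, 0.80) * n,
               y0 - stats::runif(1, 0.62, 0.80) * n)
  water_r <- stats::runif(1, 0.05, 0.07) * n
  water_poly <- circle_polygon(water_c[1], water_c[2], water_r)
  crop_x <- x0 + stats::runif(1, 0.03, 0.10) * n
  crop_y <- y0 - stats::runif(1, 0.55, 0.65) * n
  crop_poly <- rect_polygon(crop_x, crop_y - 0.18 * n, crop_x + 0.22 * n,
                            crop_y)

  # roads: two oblique local roads and one wider roadway; oblique courses
  # keep a roadside tree row from sharing one offset within the satellite
  # cell lattice
  road_y <- y0 - stats::runif(1, 0.30, 0.40) * n
  road_x <- x0 + stats::runif(1, 0.55, 0.65) * n
  tilt1 <- stats::runif(1, 0.06, 0.14) * n
  tilt2 <- stats::runif(1, 0.06, 0.14) * n
  roads <- features_create(
    list(line_geom(cbind(c(x0, x0 + n), c(road_y, road_y - tilt1))),
         line_geom(cbind(c(road_x, road_x + tilt2), c(y0 - n, y0))),
         line_geom(cbind(c(x0, x0 + n),
                         c(y0 - 0.9 * n, y0 - 0.84 * n)))),
    data.frame(category = c("local", "local", "roadway"),
               width_ft = c(NA, NA, 40)),
    crs_id = cfg$crs_id)

  # municipal square in the NW corner with a few sub-acre parcels inside
  muni_s <- 0.15 * n
  municipal <- features_create(
    list(rect_polygon(x0 + 0.02 * n, y0 - 0.02 * n - muni_s,
                      x0 + 0.02 * n + muni_s, y0 - 0.02 * n)),
    crs_id = cfg$crs_id)
  urb <- list(); k <- 0
  for (i in 0:1) for (j in 0:2) {
    k <- k + 1
    ux <- x0 + 0.03 * n + j * 45; uy <- y0 - 0.03 * n - i * 45
    urb[[k]] <- rect_polygon(ux, uy - 40, ux + 40, uy)  # 0.395 acre
  }
  # rural parcels: a coarse grid over the landscape
  rural <- list()
  np <- 4L; ps <- n / np
  for (i in 0:(np - 1)) for (j in 0:(np - 1))
    rural[[length(rural) + 1]] <-
      rect_polygon(x0 + j * ps, y0 - (i + 1) * ps, x0 + (j + 1) * ps,
                   y0 - i * ps)
  parcel_geoms <- c(urb, rural)
  parcels <- features_create(
    parcel_geoms,
    data.frame(parcel_id = sprintf("P%03d", seq_along(parcel_geoms)),
               area_acres = vapply(parcel_geoms, polygon_area_m2, 0) /
                 M2_PER_ACRE),
    crs_id = cfg$crs_id)

  # --- 10 m land-cover products (two legends, union disagreement) --------
  t10 <- grid_template(n %/% 10L, n %/% 10L, 10, org, cfg$crs_id)
  water10 <- rasterize(list(water_poly), t10)
  crop10 <- rasterize(list(crop_poly), t10)
  lulc_a <- grid_like(t10, 71 + (water10$values * (11 - 71)) +
                        (crop10$values * (82 - 71) * (1 - water10$values)))
  # product B sees a slightly larger lake (one extra 10 m ring), no crop code
  water10b <- distance_buffer(water10, 10)
  lulc_b <- grid_like(t10, 2 + water10b$values * (1 - 2) +
                        crop10$values * (1 - water10b$values) * (5 - 2))
  lulc_codes <- list(a = c(11, 82), b = c(1, 5))

  # --- exclusion footprint used for placement ----------------------------
  excl_water_crop <- landcover_mask(list(lulc_a, lulc_b), lulc_codes,
                                    template, buffer_m = 15)
  excl_roads <- road_mask(roads, template)
  excl_urban <- urban_mask(parcels, municipal, template)
  exclusions <- combine_exclusions(excl_water_crop, excl_roads, excl_urban)
  dist_forbidden <- distance_to_mask(exclusions$combined)

  # --- object placement --------------------------------------------------
  registry <- data.frame()
  crown_table <- data.frame()
  placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  juniper_m <- matrix(0, n, n); decid_m <- matrix(0, n, n)
  chm_m <- matrix(0, n, n)

  free_at <- function(x, y, clear_m) {
    rc <- grid_rowcol(template, x, y)
    if (anyNA(rc)) return(FALSE)
    dist_forbidden[rc[1], rc[2]] >= clear_m
  }
  sep_ok <- function(x, y, need) {
    if (!nrow(placed)) return(TRUE)
    min(sqrt((placed$x - x)^2 + (placed$y - y)^2) - placed$r) >= need
  }
  draw_center <- function(clear_m, sep_m, tries = 400) {
    for (i in seq_len(tries)) {
      x <- x0 + stats::runif(1, 0.02, 0.98) * n
      y <- y0 - stats::runif(1, 0.02, 0.98) * n
      if (free_at(x, y, clear_m) && sep_ok(x, y, sep_m))
        return(c(x, y))
    }
    stop("could not place object without violating isolation constraints")
  }
  add_object <- function(class, crowns, height_range) {
    hs <- stats::runif(nrow(crowns), height_range[1], height_range[2])
    is_juniper <- class %in% JUNIPER_CLASSES
    st <- stamp_crowns(if (is_juniper) juniper_m else decid_m, chm_m,
                       crowns, hs, org, n)
    if (is_juniper) juniper_m <<- st$mask else decid_m <<- st$mask
    chm_m <<- st$chm
    placed <<- rbind(placed, crowns[, c("x", "y", "r")])
    # representative point: crown center nearest the object centroid
    cx <- mean(crowns$x); cy <- mean(crowns$y)
    i <- which.min((crowns$x - cx)^2 + (crowns$y - cy)^2)
    oid <- nrow(registry) + 1L
    registry <<- rbind(registry, data.frame(
      id = oid, class = class,
      x = crowns$x[i], y = crowns$y[i], centroid_x = cx, centroid_y = cy,
      radius = max(sqrt((crowns$x - cx)^2 + (crowns$y - cy)^2) + crowns$r),
      n_crowns = nrow(crowns)))
    crown_table <<- rbind(crown_table, data.frame(
      object_id = oid, class = class, x = crowns$x, y = crowns$y,
      r = crowns$r))
  }

  for (i in seq_len(cfg$n_stand)) {
    c0 <- draw_center(clear_m = 22, sep_m = 45)
    k <- sample(cfg$crowns_per$stand[1]:cfg$crowns_per$stand[2], 1)
    # tight spread so crowns coalesce into a closed-canopy blob
    add_object("stand", cluster_crowns(c0[1], c0[2], k, 9,
                                       cfg$crown_r$stand),
               cfg$height_m$juniper)
  }
  for (i in seq_len(cfg$n_group)) {
    c0 <- draw_center(clear_m = 12, sep_m = 40)
    k <- sample(cfg$crowns_per$group[1]:cfg$crowns_per$group[2], 1)
    add_object("group", cluster_crowns(c0[1], c0[2], k, 3.5,
                                       cfg$crown_r$group),
               cfg$height_m$juniper)
  }
  for (i in seq_len(cfg$n_deciduous)) {
    c0 <- draw_center(clear_m = 14, sep_m = 35)
    k <- sample(cfg$crowns_per$deciduous[1]:cfg$crowns_per$deciduous[2], 1)
    add_object("deciduous", cluster_crowns(c0[1], c0[2], k, 8,
                                           cfg$crown_r$deciduous),
               cfg$height_m$deciduous)
  }
  for (i in seq_len(cfg$n_lone)) {
    c0 <- draw_center(clear_m = 6, sep_m = 40)
    r <- stats::runif(1, cfg$crown_r$lone[1], cfg$crown_r$lone[2])
    add_object("lone", data.frame(x = c0[1], y = c0[2], r = r),
               cfg$height_m$juniper)
  }
  # edge rows along the local roads, just outside the corridor buffer
  local_roads <- roads[roads$props$category == "local"]
  for (i in seq_len(cfg$n_edge_rows)) {
    ln <- local_roads$geoms[[1 + (i - 1) %% length(local_roads$geoms)]]
    a <- ln$coords[1, ]; b <- ln$coords[2, ]
    u <- (b - a) / sqrt(sum((b - a)^2))
    nv <- c(-u[2], u[1]) * sample(c(-1, 1), 1)
    k <- sample(cfg$crowns_per$edge[1]:cfg$crowns_per$edge[2], 1)
    spacing <- stats::runif(1, 5.5, 8)
    placed_row <- NULL
    for (try in seq_len(200)) {
      t0 <- stats::runif(1, 0.08, 0.85)
      rr <- stats::runif(k, cfg$crown_r$edge[1], cfg$crown_r$edge[2])
      off <- 25 * M_PER_FT + 2 + rr          # corridor half-width + margin
      px <- a[1] + (t0 * sqrt(sum((b - a)^2)) + (seq_len(k) - 1) * spacing) *
        u[1] + nv[1] * off
      py <- a[2] + (t0 * sqrt(sum((b - a)^2)) + (seq_len(k) - 1) * spacing) *
        u[2] + nv[2] * off
      ok <- all(vapply(seq_len(k), function(j)
        free_at(px[j], py[j], rr[j] + 0.5), TRUE)) &&
        all(vapply(seq_len(k), function(j)
          sep_ok(px[j], py[j], 12), TRUE))
      if (ok) { placed_row <- data.frame(x = px, y = py, r = rr); break }
    }
    if (is.null(placed_row))
      stop("could not place edge row without violating constraints")
    add_object("edge", placed_row, cfg$height_m$juniper)
  }

  truth_juniper <- grid_like(template, juniper_m)
  truth_tree <- grid_like(template, pmax(juniper_m, decid_m))

  # --- cover code raster (1 m) for radiometry ----------------------------
  # 1 grass, 2 water, 3 crop, 4 road, 5 deciduous, 6 juniper
  cover <- matrix(1, n, n)
  cover[rasterize(list(water_poly), template)$values == 1] <- 2
  cover[rasterize(list(crop_poly), template)$values == 1] <- 3
  cover[mask_values(excl_roads) == 1] <- 4
  cover[decid_m == 1] <- 5
  cover[juniper_m == 1] <- 6

  band_field <- function(means_by_cover, sd) {
    lapply(1:4, function(b) {
      v <- matrix(0, n, n)
      for (ci in seq_along(means_by_cover))
        v[cover == ci] <- means_by_cover[[ci]][b]
      v <- v + stats::rnorm(n * n, 0, sd)
      pmin(pmax(v, 0), 255)  # pmax/pmin keep dims of their first argument
    })
  }

  summer_means <- with(cfg$summer_dn,
    list(grass, water, crop, road, tree, tree))
  summer_bands <- band_field(summer_means, cfg$band_sd)
  summer <- scene_record(grid_like(template, summer_bands[[1]]),
                         grid_like(template, summer_bands[[2]]),
                         grid_like(template, summer_bands[[3]]),
                         grid_like(template, summer_bands[[4]]),
                         date = "2021-07-01", cloud_fraction = 0)

  winter_means <- with(cfg$winter_dn,
    list(grass, water, crop, road, deciduous, evergreen))
  t10s <- grid_template(n %/% 10L, n %/% 10L, 10, org, cfg$crs_id)
  scenes <- lapply(seq_along(cfg$scene_dates), function(si) {
    bands <- band_field(winter_means, cfg$band_sd)
    gb <- lapply(bands, function(v) {
      if (cfg$degrade_to_10m) grid_like(t10s, block_mean_10(v)) else
        grid_like(template, v)
    })
    scene_record(gb[[1]], gb[[2]], gb[[3]], gb[[4]],
                 date = cfg$scene_dates[si],
                 cloud_fraction = cfg$scene_clouds[si])
  })

  # --- CHM tiles (two overlapping halves) and DEM ------------------------
  half <- n %/% 2L
  tile1 <- grid_create(chm_m[, 1:(half + 20)], 1, org, cfg$crs_id)
  tile2 <- grid_create(chm_m[, (half - 19):n], 1,
                       c(x0 + half - 20, y0), cfg$crs_id)
  xs <- grid_col_x(template); ys <- grid_row_y(template)
  dem <- grid_like(template,
                   300 + 0.02 * outer(rep(1, n), xs - x0) +
                     8 * sin(outer(ys - y0, rep(1, n)) / 300) +
                     0.01 * outer(y0 - ys, rep(1, n)))

  structure(list(
    config = cfg, template = template, boundary = boundary,
    lulc_grids = list(lulc_a, lulc_b), lulc_codes = lulc_codes,
    roads = roads, municipal = municipal, parcels = parcels,
    chm_tiles = list(tile1, tile2), summer = summer, scenes = scenes,
    dem = dem, exclusions = exclusions,
    truth_juniper = truth_juniper, truth_tree = truth_tree,
    registry = registry, crowns = crown_table), class = "wep_landscape")
}

#' Draw labeled validation points from a generated landscape
#'
#' Juniper-class points sit on crown centers drawn from the registered
#' objects of that class (with replacement when a class has fewer crowns
#' than requested); `other` points are drawn uniformly over unexcluded
#' ground at least 3 m from any tree crown.
#'
#' @param truth A `wep_landscape` bundle.
#' @param n_per_class Points per class (4 juniper classes + other).
#' @param seed Integer seed.
#' @return A [validation_points()] data frame with
#'   `4 * n_per_class + n_per_class` rows.
#' @export
generate_validation_points <- function(truth, n_per_class = 25, seed = 1) {
  set.seed(seed)
  crowns <- truth$crowns
  xs <- c(); ys <- c(); ls <- c()
  for (cls in JUNIPER_CLASSES) {
    rows <- crowns[crowns$class == cls, ]
    if (!nrow(rows)) stop(sprintf("no generated objects of class '%s'", cls))
    pick <- sample(seq_len(nrow(rows)), n_per_class,
                   replace = n_per_class > nrow(rows))
    xs <- c(xs, rows$x[pick]); ys <- c(ys, rows$y[pick])
    ls <- c(ls, rep(cls, n_per_class))
  }
  tree_dist <- distance_to_mask(truth$truth_tree)
  excl <- mask_values(truth$exclusions$combined)
  open_px <- which(tree_dist >= 3 & excl == 0, arr.ind = TRUE)
  pick <- open_px[sample(nrow(open_px), n_per_class), , drop = FALSE]
  t <- truth$template
  xs <- c(xs, t$origin[1] + (pick[, 2] - 0.5) * t$cell_size)
  ys <- c(ys, t$origin[2] - (pick[, 1] - 0.5) * t$cell_size)
  ls <- c(ls, rep("other", n_per_class))
  validation_points(xs, ys, ls)
}

#' Run the full pipeline on a generated landscape and score it
#'
#' Exclusions, canopy, tree cover, juniper, staging, and the segmented
#' accuracy assessment against generated validation points, all in memory.
#'
#' @param cfg A [landscape_config()] (or an already generated
#'   `wep_landscape`).
#' @param th A [classifier_thresholds()].
#' @param n_points_per_class Validation points per class.
#' @return List with the classified masks, stage raster, per-segment
#'   [accuracy_report()]s, stage acreages, and the planted-vs-recovered
#'   stand area summary.
#' @export
run_recovery_experiment <- function(cfg, th = classifier_thresholds(),
                                    n_points_per_class = 25) {
  bundle <- if (inherits(cfg, "wep_landscape")) cfg else
    generate_landscape(cfg)
  cfg <- bundle$config
  template <- bundle$template

  excl <- bundle$exclusions
  chm <- merge_chm(bundle$chm_tiles, template)
  canopy <- canopy_mask(chm)
  nd_s <- ndvi(bundle$summer$nir, bundle$summer$red)
  ev_s <- evi(bundle$summer$nir, bundle$summer$red, bundle$summer$blue)
  tree <- tree_cover(canopy, nd_s, ev_s, excl$combined, th)
  kept <- filter_scenes(bundle$scenes, th)
  comp <- winter_composite(kept)
  wn <- ndvi(comp$nir, comp$red)
  wn1 <- resample_to(wn, template)
  juniper <- juniper_cover(tree, wn1, th)
  stages <- stage_vulnerability(juniper, excl$combined)

  pts <- generate_validation_points(bundle, n_points_per_class,
                                    seed = cfg$seed + 1000L)
  pts <- classify_points(juniper, excl$combined, pts)
  segs <- c(as.list(JUNIPER_CLASSES), list("combined"))
  names(segs) <- c(JUNIPER_CLASSES, "combined")
  reports <- lapply(segs, function(s)
    accuracy_report(segmented_matrix(pts, s)))

  # stand recovery: modeled juniper within 20 m of planted stand crowns
  reg <- bundle$registry
  stand_truth <- grid_like(template, 0)
  jt <- mask_values(bundle$truth_juniper)
  for (i in which(reg$class == "stand")) {
    # re-mask truth pixels within the stand's bounding circle
    d <- sqrt(outer((grid_row_y(template) - reg$centroid_y[i])^2,
                    (grid_col_x(template) - reg$centroid_x[i])^2, "+"))
    stand_truth$values[d <= reg$radius[i] & jt == 1] <- 1
  }
  near_stand <- distance_buffer(stand_truth, 20)
  recovered <- area_acres(mask_intersect(juniper, near_stand))
  planted <- area_acres(stand_truth)

  list(bundle = bundle, chm = chm, canopy = canopy, tree = tree,
       juniper = juniper, stages = stages, points = pts,
       reports = reports, stage_acres = stage_areas(stages),
       stand_area = list(planted_acres = planted,
                         recovered_acres = recovered,
                         recovery_ratio = recovered / planted))
}
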