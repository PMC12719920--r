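# Configuration, orchestration and the end-to-end pipeline: exclusions ->
# canopy -> tree cover -> juniper -> vulnerability staging -> zonal
# summaries -> accuracy assessment, from files on disk to files on disk.

pipeline_defaults <- function() {
  list(
    cell_size = 1,
    thresholds = list(ndvi_tree = 0.1, evi_tree = 1.8, ndvi_juniper = 0.35,
                      cloud_max = 0.10, window_start = "01-01",
                      window_end = "02-14"),
    buffers = list(landcover_m = 15, urban_m = 30, encroach_m = 50,
                   dispersal_m = 200),
    morphology = list(open_radius_px = 1, min_island_px = 10),
    roads = list(default_width_ft = 30,
                 widths = list(local = 25, turnpike = 250,
                               ramp_frontage = 30)),
    canopy = list(min_height_m = 0.3048),
    urban = list(max_acres = 1),
    unit_id_field = "parcel_id",
    seed = 1)
}

deep_merge <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      deep_merge(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Validate and load a pipeline configuration
#'
#' Parses a YAML config, fills defaults (spectral thresholds 0.1 / 1.8 /
#' 0.35, cloud cap 10%, leaf-off window Jan 1 - Feb 14, buffers 15 / 30 /
#' 50 / 200 m, 1 ft canopy floor, 30 ft default road width), and
#' schema-checks it. All problems are reported together, not first-failure;
#' unknown keys warn but do not fail.
#'
#' @param path YAML config path.
#' @return A validated config list of class `wep_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("inputs", "output_dir", names(pipeline_defaults()))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning(sprintf("unknown config keys ignored: %s",
                    paste(unknown, collapse = ", ")))
  cfg <- deep_merge(pipeline_defaults(), raw[names(raw) %in% known])

  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  ins <- cfg$inputs
  need(!is.null(ins), "missing required key: inputs")
  if (!is.null(ins)) {
    for (k in c("landcover", "roads", "municipal", "parcels", "chm_tiles",
                "summer", "scene_catalog"))
      need(!is.null(ins[[k]]), sprintf("missing required key: inputs.%s", k))
    paths <- c(unlist(lapply(ins$landcover, `[[`, "path")),
               ins$roads, ins$municipal, ins$parcels,
               unlist(ins$chm_tiles), ins$summer, ins$scene_catalog,
               ins$dem, ins$points, ins$boundary)
    for (p in paths)
      need(file.exists(p), sprintf("input path does not exist: %s", p))
    if (!is.null(ins$landcover))
      for (i in seq_along(ins$landcover))
        need(length(ins$landcover[[i]]$codes) > 0,
             sprintf("inputs.landcover[%d] has no excluded codes", i))
  }
  need(!is.null(cfg$output_dir), "missing required key: output_dir")
  th <- cfg$thresholds
  need(th$cloud_max >= 0 && th$cloud_max <= 1,
       "thresholds.cloud_max must be in [0, 1]")
  if (length(errs))
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"))
  class(cfg) <- "wep_config"
  cfg
}

# read a scene catalog CSV (scene_id, date, cloud_fraction, path) into
# scene records; band order in each file is B, G, R, NIR
read_scene_catalog <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, tab$path[i])
    b <- read_grid_bands(p)
    scene_record(b[[1]], b[[2]], b[[3]], b[[4]], date = tab$date[i],
                 cloud_fraction = tab$cloud_fraction[i])
  })
}

#' Run the full pipeline from a validated configuration
#'
#' Executes the stepwise model in order (exclusions, canopy, tree cover,
#' winter compositing and juniper filtering, vulnerability staging, zonal
#' attribute summaries, and -- when validation points are supplied -- the
#' segmented accuracy assessment), writing GeoTIFF, CSV/GeoJSON and JSON
#' products plus a run manifest of input/output checksums into
#' `cfg$output_dir`.
#'
#' @param cfg A `wep_config` from [validate_config()], or a path to one.
#' @param quiet Suppress per-stage log lines on stderr.
#' @return Invisibly, a list with the in-memory products and output paths.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf(fmt, ...))
  }
  ins <- cfg$inputs
  th <- do.call(classifier_thresholds, cfg$thresholds)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # working template comes from the summer image (1 m lattice)
  summer_bands <- stage("read summer image",
                        read_grid_bands(ins$summer))
  template <- grid_like(summer_bands[[1]], 0)
  log_stage("template: %d x %d @ %g m", nrow(template$values),
            ncol(template$values), template$cell_size)

  excl <- stage("exclusion masking", {
    lulc <- lapply(ins$landcover, function(l) read_grid(l$path))
    codes <- lapply(ins$landcover, function(l) as.numeric(unlist(l$codes)))
    wc <- landcover_mask(lulc, codes, template,
                         buffer_m = cfg$buffers$landcover_m)
    roads <- read_features(ins$roads)
    rm_ <- road_mask(roads, template,
                     width_table = unlist(cfg$roads$widths),
                     default_width_ft = cfg$roads$default_width_ft)
    um <- urban_mask(read_features(ins$parcels),
                     read_features(ins$municipal), template,
                     max_acres = cfg$urban$max_acres,
                     buffer_m = cfg$buffers$urban_m)
    combine_exclusions(wc, rm_, um)
  })
  log_stage("exclusion: %d px", sum(mask_values(excl$combined)))

  chm <- stage("canopy height merge",
               merge_chm(lapply(unlist(ins$chm_tiles), read_grid), template))
  canopy <- stage("canopy mask",
                  canopy_mask(chm, cfg$canopy$min_height_m,
                              cfg$morphology$open_radius_px,
                              cfg$morphology$min_island_px))
  log_stage("canopy: %d px", sum(mask_values(canopy)))

  tree <- stage("tree cover", {
    nd <- ndvi(summer_bands[[4]], summer_bands[[3]])
    ev <- evi(summer_bands[[4]], summer_bands[[3]], summer_bands[[1]])
    tree_cover(canopy, nd, ev, excl$combined, th)
  })
  log_stage("tree cover: %d px", sum(mask_values(tree)))

  juniper <- stage("juniper filter", {
    scenes <- read_scene_catalog(ins$scene_catalog)
    kept <- filter_scenes(scenes, th)
    if (!length(kept)) stop("no scenes pass the cloud/date filters")
    log_stage("scenes: %d of %d kept", length(kept), length(scenes))
    comp <- winter_composite(kept)
    wn <- resample_to(ndvi(comp$nir, comp$red), template)
    juniper_cover(tree, wn, th, cfg$morphology$open_radius_px,
                  cfg$morphology$min_island_px)
  })
  log_stage("juniper: %d px", sum(mask_values(juniper)))

  # clip to study boundary (outside -> nodata) before staging
  if (!is.null(ins$boundary)) {
    b <- rasterize(read_features(ins$boundary), template)
    juniper$values[mask_values(b) == 0] <- NA_real_
  }
  stages <- stage("vulnerability staging",
                  stage_vulnerability(juniper, excl$combined,
                                      cfg$buffers$encroach_m,
                                      cfg$buffers$dispersal_m))

  dem <- if (!is.null(ins$dem)) read_grid(ins$dem) else NULL
  units <- read_features(ins$parcels)
  attrs <- stage("zonal summary",
                 summarize_units(stages, tree, chm, units, dem = dem,
                                 exclusions = excl,
                                 id_field = cfg$unit_id_field))

  acc <- NULL
  if (!is.null(ins$points)) {
    acc <- stage("accuracy assessment", {
      pts <- utils::read.csv(ins$points, stringsAsFactors = FALSE)
      pts <- classify_points(juniper, excl$combined,
                             validation_points(pts$x, pts$y, pts$label))
      segs <- stats::setNames(c(as.list(JUNIPER_CLASSES), list("combined")),
                              c(JUNIPER_CLASSES, "combined"))
      lapply(segs, function(s) {
        m <- segmented_matrix(pts, s)
        c(accuracy_report(m), list(matrix = unclass(m)))
      })
    })
  }

  out <- function(f) file.path(cfg$output_dir, f)
  write_grid(tree, out("tree_cover.tif"))
  write_grid(juniper, out("juniper_cover.tif"))
  sgrid <- stages; class(sgrid) <- "wep_grid"
  write_grid(sgrid, out("vulnerability_stages.tif"))
  write_attributes(attrs, out("attributes.csv"), units,
                   out("attributes.geojson"))
  if (!is.null(acc))
    jsonlite::write_json(acc, out("accuracy.json"), auto_unbox = TRUE,
                         digits = NA)

  outputs <- c("tree_cover.tif", "juniper_cover.tif",
               "vulnerability_stages.tif", "attributes.csv",
               "attributes.geojson",
               if (!is.null(acc)) "accuracy.json")
  manifest <- list(
    config = unclass(cfg),
    stage_acres = as.list(stage_areas(stages)),
    input_md5 = as.list(tools::md5sum(Filter(file.exists, unlist(
      c(lapply(ins$landcover, `[[`, "path"), ins$roads, ins$municipal,
        ins$parcels, ins$chm_tiles, ins$summer, ins$scene_catalog,
        ins$dem, ins$points, ins$boundary))))),
    output_md5 = as.list(tools::md5sum(vapply(outputs, out, ""))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(tree = tree, juniper = juniper, stages = stages,
                 attributes = attrs, accuracy = acc, exclusions = excl,
                 manifest = manifest, output_dir = cfg$output_dir))
}

#' Write a generated landscape to disk as a pipeline-ready input stack
#'
#' Produces the GeoTIFFs, GeoJSON vectors, scene catalog CSV, validation
#' point CSV and a ready-to-run `config.yml` in `dir`, so that
#' `run_pipeline(file.path(dir, "config.yml"))` consumes the stack
#' unchanged. Truth layers are written alongside for scoring.
#'
#' @param bundle A `wep_landscape` from [generate_landscape()].
#' @param dir Output directory (created if needed).
#' @param n_points_per_class Validation points per class.
#' @return The config path, invisibly.
#' @export
write_landscape <- function(bundle, dir, n_points_per_class = 25) {
  dir.create(file.path(dir, "scenes"), showWarnings = FALSE,
             recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_grid(bundle$lulc_grids[[1]], p("landcover_a.tif"))
  write_grid(bundle$lulc_grids[[2]], p("landcover_b.tif"))
  write_features(bundle$boundary, p("boundary.geojson"))
  write_features(bundle$roads, p("roads.geojson"))
  write_features(bundle$municipal, p("municipal.geojson"))
  write_features(bundle$parcels, p("parcels.geojson"))
  write_grid(bundle$chm_tiles[[1]], p("chm_tile_1.tif"))
  write_grid(bundle$chm_tiles[[2]], p("chm_tile_2.tif"))
  write_bands(list(bundle$summer$blue, bundle$summer$green,
                   bundle$summer$red, bundle$summer$nir), p("summer.tif"))
  cat_rows <- lapply(seq_along(bundle$scenes), function(i) {
    sc <- bundle$scenes[[i]]
    f <- sprintf("scenes/scene_%02d.tif", i)
    write_bands(list(sc$blue, sc$green, sc$red, sc$nir), p(f))
    data.frame(scene_id = sprintf("S%02d", i), date = format(sc$date),
               cloud_fraction = sc$cloud_fraction, path = f)
  })
  utils::write.csv(do.call(rbind, cat_rows), p("scenes.csv"),
                   row.names = FALSE)
  write_grid(bundle$dem, p("dem.tif"))
  write_grid(bundle$truth_juniper, p("truth_juniper.tif"))
  write_grid(bundle$truth_tree, p("truth_tree.tif"))
  utils::write.csv(bundle$registry, p("truth_registry.csv"),
                   row.names = FALSE)
  pts <- generate_validation_points(bundle, n_points_per_class,
                                    seed = bundle$config$seed + 1000L)
  utils::write.csv(pts, p("points.csv"), row.names = FALSE)

  cfg <- list(
    inputs = list(
      boundary = p("boundary.geojson"),
      landcover = list(
        list(path = p("landcover_a.tif"),
             codes = as.list(bundle$lulc_codes$a)),
        list(path = p("landcover_b.tif"),
             codes = as.list(bundle$lulc_codes$b))),
      roads = p("roads.geojson"), municipal = p("municipal.geojson"),
      parcels = p("parcels.geojson"),
      chm_tiles = list(p("chm_tile_1.tif"), p("chm_tile_2.tif")),
      summer = p("summer.tif"), scene_catalog = p("scenes.csv"),
      dem = p("dem.tif"), points = p("points.csv")),
    output_dir = file.path(dir, "out"),
    seed = bundle$config$seed)
  yaml::write_yaml(cfg, p("config.yml"))
  invisible(p("config.yml"))
}
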