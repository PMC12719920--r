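# Slope, parcel cover arithmetic and per-unit attribute summaries.

test_that("slope_percent is exact on inclined planes", {
  n <- 20
  xcoord <- matrix(rep((1:n) - 0.5, each = n), n, n)  # x along columns
  ycoord <- matrix(rep(n - (1:n) + 0.5, n), n, n)     # y up along rows
  mkdem <- function(z) grid_create(z, 1, c(0, n))
  s1 <- slope_percent(mkdem(0.1 * xcoord))
  expect_equal(s1$values[5:15, 5:15], matrix(10, 11, 11), tolerance = 1e-9)
  s0 <- slope_percent(mkdem(matrix(3, n, n)))
  expect_equal(s0$values[5:15, 5:15], matrix(0, 11, 11))
  s2 <- slope_percent(mkdem(0.3 * xcoord + 0.4 * ycoord))
  expect_equal(s2$values[5:15, 5:15], matrix(50, 11, 11), tolerance = 1e-9)
  expect_true(all(is.na(s1$values[1, ])))   # border is nodata
})

test_that("parcel cover percentages round like the published tables", {
  out <- parcel_cover_summary(146, 113, 66)
  expect_equal(out$tree_pct, 77)
  expect_equal(out$juniper_share_of_tree_pct, 58)
  expect_equal(out$juniper_pct, 45)
  z <- parcel_cover_summary(100, 0, 0)
  expect_equal(z$juniper_share_of_tree_pct, 0)
})

make_zonal_scene <- function() {
  n <- 200
  tmpl <- grid_create(matrix(0, n, n), 1, c(0, n))
  jun <- grid_like(tmpl, 0); jun$values[20:39, 20:39] <- 1
  excl <- grid_like(tmpl, 0); excl$values[, 181:200] <- 1
  st <- stage_vulnerability(jun, excl)
  tree <- grid_like(tmpl, 0); tree$values[20:59, 20:59] <- 1
  tree$values[excl$values == 1] <- 0
  chm <- grid_like(tmpl, 0)
  chm$values[jun$values == 1] <- 6      # 6 m junipers
  dem <- grid_like(tmpl, 300)
  units <- features_create(
    list(rect_polygon(0, 100, 200, 200), rect_polygon(0, 0, 200, 100)),
    data.frame(unit_id = c("north", "south")))
  bundle <- combine_exclusions(grid_like(tmpl, 0), excl, grid_like(tmpl, 0))
  list(st = st, tree = tree, chm = chm, dem = dem, units = units,
       excl = bundle)
}

test_that("summarize_units partitions area and nests juniper in tree", {
  sc <- make_zonal_scene()
  recs <- summarize_units(sc$st, sc$tree, sc$chm, sc$units, dem = sc$dem,
                          exclusions = sc$excl)
  expect_equal(nrow(recs), 2)
  # stage pcts + exclusion pct == 100 per unit
  stage_pct <- recs$woodland_transition_pct + recs$encroachment_pct +
    recs$dispersal_recruitment_pct + recs$intact_pct + recs$exclusion_pct
  expect_equal(stage_pct, c(100, 100), tolerance = 0.1)
  expect_true(all(recs$woodland_transition_acres <= recs$tree_cover_acres))
  # the juniper block sits in the north unit (rows 20-39 = y 160-180)
  north <- recs[recs$unit_id == "north", ]
  expect_equal(north$woodland_transition_acres, 400 / 4046.8564224)
  expect_equal(north$mean_juniper_height_ft, 6 / 0.3048)
  expect_equal(north$median_juniper_height_ft, 6 / 0.3048)
  expect_equal(north$mean_elevation_ft, 300 / 0.3048)
  south <- recs[recs$unit_id == "south", ]
  expect_equal(south$woodland_transition_acres, 0)
  # exclusion split: all exclusion is roads/urban here
  expect_equal(north$crops_water_acres, 0)
  expect_equal(north$urban_roads_acres, north$exclusion_acres)
})

test_that("unit acreages aggregate consistently across unit layers", {
  sc <- make_zonal_scene()
  both <- summarize_units(sc$st, sc$tree, sc$chm, sc$units)
  whole <- summarize_units(sc$st, sc$tree, sc$chm,
                           features_create(list(rect_polygon(0, 0, 200, 200)),
                                           data.frame(unit_id = "all")))
  for (col in c("unit_area_acres", "woodland_transition_acres",
                "tree_cover_acres", "exclusion_acres"))
    expect_equal(sum(both[[col]]), whole[[col]], tolerance = 1e-9,
                 info = col)
})

test_that("attribute records round-trip through CSV and GeoJSON", {
  sc <- make_zonal_scene()
  recs <- summarize_units(sc$st, sc$tree, sc$chm, sc$units)
  f <- withr::local_tempfile(fileext = ".csv")
  fg <- withr::local_tempfile(fileext = ".geojson")
  write_attributes(recs, f, sc$units, fg)
  back <- read_attributes(f)
  expect_equal(back$unit_id, recs$unit_id)
  expect_equal(back$tree_cover_acres, recs$tree_cover_acres)
  gj <- read_features(fg)
  expect_equal(length(gj), 2)
  expect_equal(gj$props$intact_acres, recs$intact_acres)
  # empty record list -> header-only CSV
  write_attributes(recs[0, ], f)
  expect_equal(nrow(read_attributes(f)), 0)
})

test_that("units with no in-boundary pixels warn and report zeros", {
  sc <- make_zonal_scene()
  far <- features_create(list(rect_polygon(500, 500, 600, 600)),
                         data.frame(unit_id = "offmap"))
  expect_warning(recs <- summarize_units(sc$st, sc$tree, sc$chm, far),
                 "no in-boundary")
  expect_equal(recs$unit_area_acres, 0)
})
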