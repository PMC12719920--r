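# Exclusion masking: land-cover union + collar, category road corridors,
# sub-acre urban parcels, and the combined bundle.

tmpl100 <- function() grid_create(matrix(0, 100, 100), 1, c(0, 100))

test_that("landcover_mask unions products, resamples and buffers by 15 m", {
  tmpl <- tmpl100()
  # water in a 20x20 m patch of a 10 m product
  va <- matrix(0, 10, 10); va[5:6, 5:6] <- 11
  ga <- grid_create(va, 10, c(0, 100))
  out <- landcover_mask(list(ga), list(11), tmpl)
  # oracle: patch plus exact 15 m Euclidean collar around patch pixels
  patch <- matrix(0, 100, 100); patch[41:60, 41:60] <- 1
  d <- brute_distance(patch)
  expect_equal(out$values, matrix(as.numeric(d <= 15), 100, 100))

  # disagreeing products: masked where either flags water (union)
  vb <- matrix(0, 10, 10)  # product B sees nothing
  gb <- grid_create(vb, 10, c(0, 100))
  out2 <- landcover_mask(list(ga, gb), list(11, 99), tmpl)
  expect_equal(out2$values, out$values)

  # nothing excluded anywhere -> zero mask; empty code set -> error
  expect_equal(sum(landcover_mask(list(gb), list(42), tmpl)$values), 0)
  expect_error(landcover_mask(list(ga), list(numeric(0)), tmpl),
               "empty excluded-code")
})

test_that("road corridors use category widths in feet, per side", {
  tmpl <- grid_create(matrix(0, 60, 200), 1, c(0, 60))
  mk_road <- function(cat, w = NA)
    features_create(list(list(type = "line",
                              coords = cbind(c(0, 200), c(30, 30)))),
                    data.frame(category = cat, width_ft = w))
  # local: half-width 25 ft = 7.62 m -> 15-16 rows of the corridor
  local <- road_mask(mk_road("local"), tmpl)
  col_width <- sum(local$values[, 100])
  expect_true(col_width %in% c(15, 16))
  # roadway without reported width: default 30 ft = 9.144 m
  deft <- road_mask(mk_road("roadway"), tmpl)
  expect_true(sum(deft$values[, 100]) %in% c(18, 19))
  # roadway with a reported 50 ft width: 15.24 m half-width
  rep50 <- road_mask(mk_road("roadway", 50), tmpl)
  expect_true(sum(rep50$values[, 100]) %in% c(30, 31))
  # turnpike 250 ft = 76.2 m: swallows the whole 60 m extent
  expect_equal(sum(road_mask(mk_road("turnpike"), tmpl)$values[, 100]), 60)
  expect_error(road_mask(mk_road("cowpath"), tmpl), "cowpath")
})

test_that("urban_mask keeps only sub-acre parcels touching a municipality", {
  tmpl <- grid_create(matrix(0, 200, 200), 1, c(0, 200))
  muni <- features_create(list(rect_polygon(0, 100, 120, 200)))
  small_in <- rect_polygon(40, 140, 85, 185)        # 45 m sq = 0.5 acre
  big_in <- rect_polygon(10, 105, 88, 183)          # 1.5 acres
  small_out <- rect_polygon(150, 10, 195, 55)       # 0.5 acre, rural
  parcels <- features_create(
    list(small_in, big_in, small_out),
    data.frame(parcel_id = c("s", "b", "o"),
               area_acres = c(0.5, 1.5, 0.5)))
  out <- urban_mask(parcels, muni, tmpl)
  # the small municipal parcel is masked with a 30 m collar
  patch <- rasterize(list(small_in), tmpl)$values
  d <- brute_distance(patch)
  expect_equal(out$values, matrix(as.numeric(d <= 30), 200, 200))
  # exactly-one-acre retention boundary: strict "<" keeps 1.0-acre parcels
  one_acre <- features_create(list(small_in),
                              data.frame(parcel_id = "x", area_acres = 1))
  expect_equal(sum(urban_mask(one_acre, muni, tmpl)$values), 0)
})

test_that("combine_exclusions is a monotone pixelwise union", {
  tmpl <- tmpl100()
  a <- grid_like(tmpl, 0); a$values[1:10, 1:10] <- 1
  b <- grid_like(tmpl, 0); b$values[50:60, 50:60] <- 1
  cc <- grid_like(tmpl, 0); cc$values[5:12, 5:12] <- 1
  z <- grid_like(tmpl, 0)

  expect_equal(sum(combine_exclusions(z, z, z)$combined$values), 0)
  # disjoint inputs: areas add
  bundle <- combine_exclusions(a, b, z)
  expect_equal(area_acres(bundle$combined), area_acres(a) + area_acres(b))
  # overlapping inputs: union is smaller than the sum
  bundle2 <- combine_exclusions(a, cc, z)
  expect_lt(area_acres(bundle2$combined), area_acres(a) + area_acres(cc))
  # invariant: combined = water_crop | roads_urban; adding never unmasks
  expect_equal(bundle2$combined$values,
               pmax(bundle2$water_crop$values, bundle2$roads_urban$values))
  expect_true(all(bundle2$combined$values >= bundle$water_crop$values *
                    (a$values)))
})
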