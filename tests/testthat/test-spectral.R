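# Vegetation indices, scene filtering/compositing, and the tree and juniper
# spectral gates.

gband <- function(x, n = 3) grid_create(matrix(x, n, n), 1, c(0, n))

test_that("ndvi and evi implement their formulas with nodata degeneracy", {
  expect_equal(ndvi(gband(0.5), gband(0.3))$values[1, 1], 0.25)
  expect_equal(ndvi(gband(0.4), gband(0.4))$values[1, 1], 0)
  expect_equal(ndvi(gband(0.3), gband(0))$values[1, 1], 1)
  expect_true(is.na(ndvi(gband(0), gband(0))$values[1, 1]))

  # digital-number example: G (NIR - R) / (NIR + 6R - 7.5B + 1)
  e <- evi(gband(120), gband(60), gband(50))
  expect_equal(e$values[1, 1], 2.5 * 60 / 106, tolerance = 1e-12)
  expect_equal(evi(gband(80), gband(80), gband(10))$values[1, 1], 0)
  # zero denominator: NIR + 6R - 7.5B + L = 0
  expect_true(is.na(evi(gband(74), gband(0), gband(10))$values[1, 1]))
  expect_error(ndvi(gband(1), gband(1, n = 4)), "geometry")
})

test_that("tree_cover requires canopy, both index gates, and no exclusion", {
  th <- classifier_thresholds()
  one <- gband(1); zero <- gband(0)
  case <- function(canopy, nv, ev, excl)
    tree_cover(gband(canopy), gband(nv), gband(ev), gband(excl), th)$values[1, 1]
  expect_equal(case(1, 0.4, 2.0, 0), 1)
  expect_equal(case(1, 0.4, 1.7, 0), 0)      # EVI below 1.8
  expect_equal(case(0, 0.9, 3.0, 0), 0)      # no canopy
  expect_equal(case(1, 0.05, 3.0, 0), 0)     # NDVI below 0.1
  expect_equal(case(1, 0.4, 2.0, 1), 0)      # excluded
  # inclusive thresholds at exactly 0.1 / 1.8
  expect_equal(case(1, 0.1, 1.8, 0), 1)
})

test_that("scene filtering applies the strict cloud gate and leaf-off window", {
  sc <- function(date, cloud)
    scene_record(gband(1), gband(1), gband(1), gband(1), date, cloud)
  catalog <- list(sc("2021-01-15", 0.05),  # kept
                  sc("2021-02-15", 0.05),  # outside Jan 1 - Feb 14
                  sc("2021-01-15", 0.10),  # cloud not strictly below 0.10
                  sc("2022-02-14", 0.0),   # window edge, second year
                  sc("2021-12-30", 0.0))   # December is outside the window
  kept <- filter_scenes(catalog)
  expect_equal(length(kept), 2)
  expect_equal(format(kept[[1]]$date), "2021-01-15")
  expect_equal(format(kept[[2]]$date), "2022-02-14")
})

test_that("winter_composite means valid pixels per band", {
  sc <- function(nir) {
    g <- gband(0.2)
    scene_record(g, g, g, grid_like(g, nir), "2021-01-10", 0)
  }
  a <- sc(matrix(0.2, 3, 3)); b <- sc(matrix(0.4, 3, 3))
  expect_equal(winter_composite(list(a, b))$nir$values[1, 1], 0.3)
  # identity on a single scene; permutation invariance
  expect_equal(winter_composite(list(a))$nir$values, a$nir$values)
  expect_equal(winter_composite(list(b, a))$nir$values,
               winter_composite(list(a, b))$nir$values)
  # nodata pixels are excluded from the mean, not poisoning it
  cc <- sc(matrix(c(NA, rep(0.6, 8)), 3, 3))
  out <- winter_composite(list(a, b, cc))
  expect_equal(out$nir$values[1, 1], 0.3)        # mean of 0.2, 0.4
  expect_equal(out$nir$values[2, 2], mean(c(0.2, 0.4, 0.6)))
  expect_error(winter_composite(list()), "at least one")
})

test_that("juniper gate is strictly greater than 0.35 and nested in tree", {
  tree <- gband(1, 20); tree$values[1:4, ] <- 0
  wn <- gband(0.5, 20)
  out <- juniper_cover(tree, wn, open_radius_px = 0, min_island_px = 0)
  expect_equal(out$values, tree$values)           # subset equality here
  # exactly 0.35 fails the strict gate
  expect_equal(sum(juniper_cover(tree, gband(0.35, 20), open_radius_px = 0,
                                 min_island_px = 0)$values), 0)
  expect_equal(sum(juniper_cover(gband(0, 20), gband(0.9, 20),
                                 open_radius_px = 0,
                                 min_island_px = 0)$values), 0)
})

test_that("raising thresholds never adds pixels (monotonicity)", {
  set.seed(11)
  n <- 25
  canopy <- mk_mask(matrix(rbinom(n^2, 1, 0.6), n, n))
  nv <- grid_create(matrix(runif(n^2, -0.2, 0.9), n, n), 1, c(0, n))
  ev <- grid_create(matrix(runif(n^2, 0, 4), n, n), 1, c(0, n))
  ex <- mk_mask(matrix(0, n, n))
  lo <- tree_cover(canopy, nv, ev, ex, classifier_thresholds(0.1, 1.5))
  hi <- tree_cover(canopy, nv, ev, ex, classifier_thresholds(0.3, 2.5))
  expect_true(all(hi$values <= lo$values))
  wn <- grid_create(matrix(runif(n^2, 0, 0.8), n, n), 1, c(0, n))
  j_lo <- juniper_cover(lo, wn, classifier_thresholds(ndvi_juniper = 0.3),
                        open_radius_px = 0, min_island_px = 0)
  j_hi <- juniper_cover(lo, wn, classifier_thresholds(ndvi_juniper = 0.5),
                        open_radius_px = 0, min_island_px = 0)
  expect_true(all(j_hi$values <= j_lo$values))
  # nesting: juniper subset of tree subset of canopy
  expect_true(all(j_lo$values <= lo$values))
  expect_true(all(lo$values <= canopy$values))
})
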