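# Synthetic landscape generator: determinism, truth-bundle invariants and
# validation-point construction. (Small extents keep these fast; the
# full-size pipeline recovery runs live in test-acceptance.R.)

small_cfg <- function(seed = 5, n_lone = 6, n_edge_rows = 2, n_group = 5,
                      n_stand = 3, n_deciduous = 4)
  landscape_config(extent_m = 400, seed = seed, n_lone = n_lone,
                   n_edge_rows = n_edge_rows, n_group = n_group,
                   n_stand = n_stand, n_deciduous = n_deciduous)

test_that("generation is a pure function of (config, seed)", {
  a <- generate_landscape(small_cfg())
  b <- generate_landscape(small_cfg())
  expect_identical(a$truth_juniper$values, b$truth_juniper$values)
  expect_identical(a$chm_tiles[[1]]$values, b$chm_tiles[[1]]$values)
  expect_identical(a$summer$nir$values, b$summer$nir$values)
  expect_identical(a$scenes[[3]]$red$values, b$scenes[[3]]$red$values)
  expect_identical(a$registry, b$registry)
  c <- generate_landscape(small_cfg(seed = 6))
  expect_false(identical(a$truth_juniper$values, c$truth_juniper$values))
})

test_that("truth bundle invariants hold by construction", {
  b <- generate_landscape(small_cfg())
  jt <- b$truth_juniper$values; tt <- b$truth_tree$values
  expect_true(all(jt <= tt))                       # juniper subset of tree
  expect_equal(sum(jt * b$exclusions$combined$values), 0)  # disjoint
  # every registered object contributes truth pixels
  expect_true(all(table(b$crowns$class) > 0))
  expect_setequal(unique(b$registry$class),
                  c("lone", "edge", "group", "stand", "deciduous"))
  # registry classes respect the crown-count taxonomy
  expect_true(all(b$registry$n_crowns[b$registry$class == "lone"] == 1))
  expect_true(all(b$registry$n_crowns[b$registry$class == "group"] < 6))
  expect_true(all(b$registry$n_crowns[b$registry$class == "stand"] > 6))
})

test_that("planted stand area brackets the rasterized-union oracle", {
  b <- generate_landscape(small_cfg(seed = 9))
  reg <- b$registry
  crowns <- b$crowns[b$crowns$class == "stand" &
                       b$crowns$object_id == reg$id[reg$class == "stand"][1], ]
  # rasterized union area must lie between max single crown and the sum
  tmpl <- b$template
  m <- matrix(0, 400, 400)
  for (i in seq_len(nrow(crowns))) {
    g <- rasterize(list(circle_polygon(crowns$x[i], crowns$y[i],
                                       crowns$r[i], n = 256)), tmpl)
    m <- pmax(m, g$values)
  }
  union_area <- sum(m)
  expect_gte(union_area, max(pi * crowns$r^2) * 0.8)
  expect_lte(union_area, sum(pi * crowns$r^2))
  # that union is exactly the truth pixels near this stand
  cx <- mean(crowns$x); cy <- mean(crowns$y)
  rr <- max(sqrt((crowns$x - cx)^2 + (crowns$y - cy)^2) + crowns$r) + 2
  xs <- tmpl$origin[1] + (seq_len(400) - 0.5)
  ys <- tmpl$origin[2] - (seq_len(400) - 0.5)
  near <- outer((ys - cy)^2, (xs - cx)^2, "+") <= rr^2
  expect_equal(sum(b$truth_juniper$values[near]), union_area,
               tolerance = 0.05)
})

test_that("zero-juniper config gives empty truth and an all-intact staging", {
  cfg <- small_cfg(n_lone = 0, n_edge_rows = 0, n_group = 0, n_stand = 0)
  b <- generate_landscape(cfg)
  expect_equal(sum(b$truth_juniper$values), 0)
  st <- stage_vulnerability(b$truth_juniper, b$exclusions$combined)
  expect_true(all(st$values %in% c(0, 4)))
  a <- stage_areas(st)
  expect_equal(sum(a), 400 * 400 / 4046.8564224)
  expect_equal(unname(a[["woodland_transition"]]), 0)
})

test_that("validation points land on their constructed truth", {
  b <- generate_landscape(small_cfg())
  pts <- generate_validation_points(b, n_per_class = 10, seed = 2)
  expect_equal(nrow(pts), 50)
  expect_equal(as.integer(table(pts$label)[c("lone", "edge", "group",
                                             "stand", "other")]),
               rep(10L, 5))
  rc <- wepmap:::grid_rowcol(b$template, pts$x, pts$y)
  truth <- b$truth_juniper$values[rc]
  expect_true(all(truth[pts$label != "other"] == 1))
  expect_true(all(truth[pts$label == "other"] == 0))
  excl <- b$exclusions$combined$values[rc]
  expect_true(all(excl[pts$label == "other"] == 0))
  # fixed seed -> identical point sets
  expect_identical(pts, generate_validation_points(b, 10, seed = 2))
})
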