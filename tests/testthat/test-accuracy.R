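# Error matrices, accuracy statistics, kappa and the paired comparison.

perfect <- function() {
  m <- matrix(c(50L, 0L, 0L, 30L), 2, 2,
              dimnames = list(classified = c("other", "juniper"),
                              reference = c("other", "juniper")))
  class(m) <- c("wep_error_matrix", class(m)); m
}

test_that("point classification reads the containing pixel and flags", {
  n <- 50
  jun <- mk_mask(matrix(0, n, n)); jun$values[10:20, 10:20] <- 1
  excl <- mk_mask(matrix(0, n, n)); excl$values[, 40:50] <- 1
  pts <- validation_points(x = c(15.5, 30.5, 45.5),
                           y = c(n - 15.5, n - 30.5, n - 15.5),
                           label = c("stand", "other", "other"))
  out <- classify_points(jun, excl, pts)
  expect_equal(out$predicted, c("juniper", "other", "other"))
  expect_equal(out$flag_excluded, c(FALSE, FALSE, TRUE))
  bad <- validation_points(999, 999, "other")
  expect_error(classify_points(jun, excl, bad), "outside the raster")
  expect_error(validation_points(1, 1, "shrub"), "labels")
})

test_that("segmented matrices equal a brute-force tally on random labels", {
  set.seed(21)
  n <- 400
  labels <- sample(c("other", "lone", "edge", "group", "stand"), n,
                   replace = TRUE)
  preds <- sample(c("other", "juniper"), n, replace = TRUE)
  pts <- data.frame(label = labels, predicted = preds)
  for (seg in c("lone", "edge", "group", "stand")) {
    m <- segmented_matrix(pts, seg)
    keep <- labels %in% c("other", seg)
    expect_equal(m["juniper", "juniper"],
                 sum(preds[keep] == "juniper" & labels[keep] == seg))
    expect_equal(m["other", "other"],
                 sum(preds[keep] == "other" & labels[keep] == "other"))
    expect_equal(sum(m), sum(keep))
    # every segment shares the identical "other" reference column
    expect_equal(unname(m[, "other"]),
                 unname(segmented_matrix(pts, "combined")[, "other"]))
  }
  expect_error(segmented_matrix(pts, "bush"), "unknown segment")
})

test_that("accuracy statistics hit their closed-form limits", {
  p <- perfect()
  expect_equal(producers_accuracy(p, "juniper"), 1)
  expect_equal(users_accuracy(p, "juniper"), 1)
  expect_equal(overall_accuracy(p), 1)
  expect_equal(kappa_coefficient(p), 1)

  # rows proportional to column margins -> kappa 0
  ind <- matrix(c(40L, 40L, 10L, 10L), 2, 2,
                dimnames = dimnames(perfect()))
  expect_equal(kappa_coefficient(ind), 0)

  empty_row <- matrix(c(10L, 0L, 5L, 0L), 2, 2,
                      dimnames = dimnames(perfect()))
  expect_error(users_accuracy(empty_row, "juniper"), "zero total")
  expect_error(producers_accuracy(matrix(c(1L, 0L, 0L, 0L), 2, 2,
    dimnames = dimnames(perfect())), "juniper"), "zero")
})

test_that("kappa agrees with an independent computation on random matrices", {
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(as.integer(rpois(4, 40) + 1), 2, 2,
                dimnames = dimnames(perfect()))
    n <- sum(m)
    # independent route: expected matrix from margins
    pe <- sum((rowSums(m) / n) * (colSums(m) / n))
    p0 <- sum(diag(m)) / n
    expect_equal(kappa_coefficient(m), (p0 - pe) / (1 - pe))
    expect_lte(kappa_coefficient(m), 1)
  }
})

test_that("paired t test matches hand computation and stats::t.test", {
  out <- paired_difference_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)

  set.seed(8)
  a <- rnorm(15, 10, 3); b <- rnorm(15, 11, 3)
  ours <- paired_difference_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  expect_error(paired_difference_test(c(1, 2), c(0, 1)), "zero variance")
})
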