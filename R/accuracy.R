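# Accuracy assessment: validation-point classification, segmented 2x2 error
# matrices, producer's/user's/overall accuracy, Cohen's kappa, and the paired
# map-comparison t test.

JUNIPER_CLASSES <- c("lone", "edge", "group", "stand")

#' Make a validation-point table
#'
#' @param x,y Projected coordinates (meters).
#' @param label Reference labels in `{other, lone, edge, group, stand}`.
#' @return A data.frame of validation points.
#' @export
validation_points <- function(x, y, label) {
  stopifnot(length(x) == length(y), length(x) == length(label))
  if (!all(label %in% c("other", JUNIPER_CLASSES)))
    stop("labels must be in {other, lone, edge, group, stand}")
  data.frame(x = as.numeric(x), y = as.numeric(y),
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Classify validation points against the juniper map
#'
#' Each point is predicted `juniper` when the pixel containing it is a
#' 1-pixel of the juniper mask, else `other`. Points on excluded or nodata
#' pixels predict `other` and are flagged rather than dropped.
#'
#' @param juniper Binary `wep_grid` juniper mask.
#' @param exclusion Binary `wep_grid` combined exclusion mask.
#' @param points Data frame from [validation_points()].
#' @return The points with added `predicted` and `flag_excluded` columns.
#' @export
classify_points <- function(juniper, exclusion, points) {
  stop_geometry(juniper, exclusion, "classification layers")
  rc <- grid_rowcol(juniper, points$x, points$y)
  if (anyNA(rc)) {
    bad <- which(is.na(rc[, 1]) | is.na(rc[, 2]))
    stop(sprintf("validation points outside the raster extent: %s",
                 paste(sprintf("(%g, %g)", points$x[bad], points$y[bad]),
                       collapse = ", ")))
  }
  idx <- cbind(rc[, 1], rc[, 2])
  jv <- juniper$values[idx]
  ev <- mask_values(exclusion)[idx]
  flagged <- ev == 1 | is.na(jv)
  points$predicted <- ifelse(!flagged & jv == 1, "juniper", "other")
  points$flag_excluded <- flagged
  points
}

#' Segmented 2x2 error matrix
#'
#' Builds the classified-vs-reference count table over the `other` reference
#' points plus the reference points of one juniper segment (or all four for
#' `combined`). Rows are the map classes `{other, juniper}`, columns the
#' reference classes `{other, <segment>}`.
#'
#' @param points Classified points from [classify_points()] (columns `label`
#'   and `predicted`), or supply `predictions` separately.
#' @param segment One of `"lone"`, `"edge"`, `"group"`, `"stand"`,
#'   `"combined"`, or a character vector of juniper classes to pool.
#' @param predictions Optional predicted labels overriding
#'   `points$predicted`.
#' @return Integer matrix of class `wep_error_matrix`.
#' @export
segmented_matrix <- function(points, segment = "combined",
                             predictions = NULL) {
  classes <- if (identical(segment, "combined")) JUNIPER_CLASSES else segment
  if (!all(classes %in% JUNIPER_CLASSES))
    stop(sprintf("unknown segment '%s'", paste(segment, collapse = ",")))
  pred <- if (!is.null(predictions)) predictions else points$predicted
  keep <- points$label %in% c("other", classes)
  ref <- ifelse(points$label[keep] == "other", "other", "juniper")
  prd <- pred[keep]
  if (!any(ref == "juniper")) stop("segment has no reference points")
  lv <- c("other", "juniper")
  m <- table(factor(prd, lv), factor(ref, lv))
  m <- matrix(as.integer(m), 2, 2,
              dimnames = list(classified = lv, reference = lv))
  attr(m, "segment") <- paste(classes, collapse = "+")
  class(m) <- c("wep_error_matrix", class(m))
  m
}

#' Producer's accuracy (omission-error complement)
#'
#' Fraction of reference points of a class that the map classifies
#' correctly: diagonal count over the reference-column total.
#'
#' @param m Error matrix (classified rows x reference columns).
#' @param reference_class Column name or index.
#' @export
producers_accuracy <- function(m, reference_class) {
  j <- reference_class
  tot <- sum(m[, j])
  if (tot == 0) stop("reference class has zero total")
  mm <- unclass(m)
  if (is.character(j)) mm[j, j] / tot else mm[j, j] / tot
}

#' User's accuracy (commission-error complement)
#'
#' Fraction of map pixels of a class that truly belong to it: diagonal count
#' over the classified-row total.
#'
#' @param m Error matrix.
#' @param classified_class Row name or index.
#' @export
users_accuracy <- function(m, classified_class) {
  i <- classified_class
  tot <- sum(m[i, ])
  if (tot == 0) stop("classified class has zero total")
  mm <- unclass(m)
  mm[i, i] / tot
}

#' Overall accuracy
#'
#' Matrix trace over the grand total.
#' @param m Error matrix.
#' @export
overall_accuracy <- function(m) {
  n <- sum(m)
  if (n == 0) stop("empty error matrix")
  sum(diag(unclass(m))) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` with `p0` the observed
#' agreement (trace / N) and `pe` the expected agreement from the row and
#' column margins.
#' @param m Error matrix.
#' @export
kappa_coefficient <- function(m) {
  n <- sum(m)
  if (n == 0) stop("empty error matrix")
  mm <- unclass(m)
  p0 <- sum(diag(mm)) / n
  pe <- sum(rowSums(mm) * colSums(mm)) / n^2
  if (pe >= 1) stop("degenerate matrix: expected agreement is 1")
  (p0 - pe) / (1 - pe)
}

#' Full accuracy report for one error matrix
#'
#' @param m Error matrix.
#' @return List with per-class producer's and user's accuracies, overall
#'   accuracy and kappa (all as fractions in [0, 1]).
#' @export
accuracy_report <- function(m) {
  cls <- rownames(m)
  safe <- function(f, k) tryCatch(f(m, k), error = function(e) NA_real_)
  list(producers = stats::setNames(
         vapply(cls, function(k) safe(producers_accuracy, k), 0), cls),
       users = stats::setNames(
         vapply(cls, function(k) safe(users_accuracy, k), 0), cls),
       overall = overall_accuracy(m),
       kappa = kappa_coefficient(m))
}

#' Paired-difference t test
#'
#' Two-sided paired t test on `a - b` with the sample (n - 1) standard
#' deviation; the closed form behind a paired map comparison across shared
#' reporting units.
#'
#' @param a,b Paired numeric vectors (e.g. two platforms' percent tree cover
#'   per county).
#' @return List with `t`, `df`, `p`, and `mean_difference`.
#' @export
paired_difference_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_difference = mean(d))
}
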