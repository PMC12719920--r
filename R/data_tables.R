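# Shipped reference tables from the published field campaign, used by the
# worked examples and the accuracy-math demonstrations.

#' Field-campaign validation counts
#'
#' The segmented error-matrix counts from the published juniper validation
#' campaign (1443 points: 400 `other` plus 309 / 248 / 244 / 242 lone /
#' edge / group / stand juniper points), as a classified-by-reference count
#' table.
#'
#' @return A 2 x 5 integer matrix; rows `other` / `juniper` (map classes),
#'   columns `other`, `lone`, `edge`, `group`, `stand` (reference classes).
#' @export
field_validation_counts <- function() {
  tab <- utils::read.csv(system.file("extdata",
                                     "juniper_validation_counts.csv",
                                     package = "wepmap"),
                         stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$classified
  storage.mode(m) <- "integer"
  m
}

#' Build a segmented 2x2 error matrix from the count table
#'
#' Pools the requested juniper reference classes of a classified-by-reference
#' count table (as returned by [field_validation_counts()]) against the
#' `other` column into the 2x2 layout the accuracy functions consume.
#'
#' @param counts 2 x k count matrix with an `other` column.
#' @param segment Character vector of juniper columns to pool, or
#'   `"combined"` for all non-`other` columns.
#' @return A `wep_error_matrix`.
#' @export
matrix_from_counts <- function(counts, segment = "combined") {
  jun_cols <- setdiff(colnames(counts), "other")
  cols <- if (identical(segment, "combined")) jun_cols else segment
  stopifnot(all(cols %in% jun_cols))
  m <- cbind(other = counts[, "other"],
             juniper = rowSums(counts[, cols, drop = FALSE]))
  m <- matrix(as.integer(m), 2, 2,
              dimnames = list(classified = c("other", "juniper"),
                              reference = c("other", "juniper")))
  attr(m, "segment") <- paste(cols, collapse = "+")
  class(m) <- c("wep_error_matrix", class(m))
  m
}

#' Published county tree-cover comparison
#'
#' Percent tree cover per county from two mapping platforms across the
#' thirteen counties of the study territory, the input to the paired
#' map-comparison test.
#'
#' @return Data frame with columns `county`, `rap_pct`, `stepwise_pct`.
#' @export
county_tree_cover <- function() {
  utils::read.csv(system.file("extdata",
                              "county_tree_cover_comparison.csv",
                              package = "wepmap"),
                  stringsAsFactors = FALSE)
}
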