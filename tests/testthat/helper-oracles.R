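# Independent brute-force oracles and tiny fixture builders shared across
# the suite. The oracles are deliberately naive (all-pairs loops) so they
# never share code paths with the implementation they check.

mk_mask <- function(values, cell_size = 1, origin = NULL) {
  v <- as.matrix(values)
  if (is.null(origin)) origin <- c(0, nrow(v) * cell_size)
  grid_create(v, cell_size, origin)
}

random_mask <- function(nr, nc, p = 0.1, seed = 1, cell_size = 1) {
  set.seed(seed)
  mk_mask(matrix(rbinom(nr * nc, 1, p), nr, nc), cell_size)
}

# naive morphology with square SE of radius r, zero padding
brute_morph <- function(v, r, op) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    wi <- max(1, i - r):min(nr, i + r)
    wj <- max(1, j - r):min(nc, j + r)
    w <- v[wi, wj]
    n_in <- (min(nr, i + r) - max(1, i - r) + 1) *
      (min(nc, j + r) - max(1, j - r) + 1)
    out[i, j] <- if (op == "erode") {
      as.numeric(all(w == 1) && n_in == (2 * r + 1)^2)  # 0-padding outside
    } else {
      as.numeric(any(w == 1))
    }
  }
  out
}

# naive Euclidean distance (cell units) to the nearest 1-pixel, Inf if none
brute_distance <- function(v) {
  ones <- which(v == 1, arr.ind = TRUE)
  out <- matrix(Inf, nrow(v), ncol(v))
  if (!nrow(ones)) return(out)
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    out[i, j] <- sqrt(min((ones[, 1] - i)^2 + (ones[, 2] - j)^2))
  out
}

# naive 4-connected component sizes
brute_components <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc); nextl <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (v[i, j] == 1 && lab[i, j] == 0L) {
      nextl <- nextl + 1L
      queue <- list(c(i, j)); lab[i, j] <- nextl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              v[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nextl
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

# count of integer lattice offsets with dx^2 + dy^2 <= R^2
lattice_disc_count <- function(R) {
  k <- floor(R)
  sum(outer((-k):k, (-k):k, function(a, b) a^2 + b^2) <= R^2)
}

expect_grid_equal <- function(a, b, tol = 1e-6) {
  expect_true(same_geometry(a, b))
  expect_equal(a$values, b$values, tolerance = tol)
}
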