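#' Cell indexing helpers
#'
#' Cells of the `N x N` domain are addressed externally by 1-based
#' `(row, column)` coordinates and internally by a single 1-based index in
#' column-major order (matching R's matrix layout): cell `k` has
#' `row = (k - 1) %% N + 1` and `column = (k - 1) %/% N + 1`.
#'
#' @param row,col Integer vectors of 1-based coordinates.
#' @param cell Integer vector of 1-based cell indices.
#' @param N Grid resolution.
#' @return `cell_index()` returns cell indices; `cell_coords()` returns a
#'   two-column integer matrix with columns `row` and `col`.
#' @keywords internal
#' @export
cell_index <- function(row, col, N) {
  (as.integer(col) - 1L) * as.integer(N) + as.integer(row)
}

#' @rdname cell_index
#' @export
cell_coords <- function(cell, N) {
  cell <- as.integer(cell)
  cbind(row = (cell - 1L) %% N + 1L, col = (cell - 1L) %/% N + 1L)
}

#' Inverse-distance movement kernel
#'
#' Precomputes, for every source cell `i` of the bounded `N x N` lattice, the
#' categorical destination distribution over cells `j != i` with probability
#' proportional to `1 / d_ij`, where `d_ij` is the Euclidean distance between
#' cell centres. Moving always means relocating: the source cell itself has
#' zero weight (`d_ii = 0` is excluded), and staying put happens only through
#' the per-step movement Bernoulli draw. Domain edges are physical
#' boundaries, so border cells simply have fewer nearby destinations; there
#' is no wrap-around and no reflection rule.
#'
#' The kernel depends only on `N` and is precomputed once per grid size and
#' shared across replicates; results are identical to per-step recomputation.
#'
#' @param N Grid resolution, at least 2 (with a single cell there is no
#'   destination to move to).
#' @return An object of class `sr_kernel`: a list with `N`, the row-stochastic
#'   probability matrix `prob` (row = source cell, column = destination), and
#'   the column-wise cumulative matrix `cum` used by the movement sampler
#'   (`cum[, i]` is the cumulative distribution of source cell `i`).
#' @examples
#' k <- build_distance_kernel(3)
#' rowSums(k$prob) # all 1
#' k$prob[5, 5]    # centre cell cannot be its own destination
#' @export
build_distance_kernel <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L) {
    stop("`N` must be a positive integer")
  }
  if (N == 1L) {
    stop("degenerate 1 x 1 domain: there is no destination cell to move to")
  }
  coords <- cell_coords(seq_len(N * N), N)
  d <- as.matrix(stats::dist(coords))
  w <- 1 / d
  diag(w) <- 0
  prob <- w / rowSums(w)
  # cum[, i] holds the cumulative destination distribution of source cell i
  # (apply() over rows returns results as columns, which is what the C++
  # sampler indexes).
  cum <- apply(prob, 1L, cumsum)
  structure(list(N = N, prob = prob, cum = cum), class = "sr_kernel")
}

#' @export
print.sr_kernel <- function(x, ...) {
  cat(sprintf("Inverse-distance movement kernel on a %d x %d grid (%d cells)\n",
              x$N, x$N, x$N^2))
  invisible(x)
}

#' Destination distribution of one source cell
#'
#' @param kernel An `sr_kernel`.
#' @param row,col 1-based coordinates of the source cell.
#' @return Named numeric vector of destination probabilities (length `N^2`,
#'   zero at the source cell).
#' @keywords internal
#' @export
kernel_row <- function(kernel, row, col) {
  kernel$prob[cell_index(row, col, kernel$N), ]
}
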