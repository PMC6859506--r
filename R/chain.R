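#' Cell chain state
#'
#' The discrete state of the model: an ordered vector of node positions
#' `x_0 < x_1 < ... < x_N`, with the left boundary pinned at the origin
#' (`x_0 = 0`). The `N` intervals between consecutive nodes are the cells;
#' the right-most node `x_N` is the free boundary `L`.
#'
#' @param x Numeric vector of node positions, strictly increasing, starting
#'   at exactly 0, with at least two entries (one cell).
#' @param t Time attached to the state.
#' @return An object of class `cell_chain` with fields `x`, `t` and the cell
#'   count `N = length(x) - 1`.
#' @examples
#' ch <- cell_chain(c(0, 1, 3))
#' cell_lengths(ch)
#' @export
cell_chain <- function(x, t = 0) {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)))
    stop("`x` must be a numeric vector with at least two finite entries", call. = FALSE)
  if (x[1] != 0)
    stop("the first node must be pinned at the origin (x[1] == 0)", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("node positions must be strictly increasing", call. = FALSE)
  structure(list(x = as.numeric(x), t = t, N = length(x) - 1L), class = "cell_chain")
}

#' @export
print.cell_chain <- function(x, ...) {
  cat(sprintf("<cell_chain> N = %d cells, t = %g, L = %g\n", x$N, x$t, x$x[x$N + 1]))
  invisible(x)
}

#' Cell lengths of a chain
#' @param chain A [cell_chain()].
#' @return The `N` cell lengths `x_i - x_{i-1}`.
#' @export
cell_lengths <- function(chain) diff(chain$x)

#' Uniformly compressed initial chain
#'
#' The standard initial condition: `N` cells of equal length filling the
#' interval `(0, length)`, i.e. nodes at `x_i = length * i / N`. The chain is
#' compressed whenever `length / N` is below the rest length of the force law
#' it is paired with.
#'
#' @param N Number of cells, at least 1.
#' @param length Domain length, positive.
#' @export
compressed_chain <- function(N, length = 30) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("`N` must be a positive integer", call. = FALSE)
  if (!is.numeric(length) || length <= 0)
    stop("`length` must be positive", call. = FALSE)
  cell_chain(length * (0:N) / N)
}

#' Divide a cell
#'
#' Inserts a new node at the centre of cell `i` (the interval
#' `(x_{i-1}, x_i)`), incrementing the cell count by one. All other node
#' positions, including the free boundary, are unchanged.
#'
#' @param chain A [cell_chain()].
#' @param i Cell index in `1..N`.
#' @export
divide_cell <- function(chain, i) {
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > chain$N || i != round(i))
    stop("cell index must be in 1..N", call. = FALSE)
  mid <- (chain$x[i] + chain$x[i + 1]) / 2
  cell_chain(append(chain$x, mid, after = i), t = chain$t)
}

#' Node-based cell density estimate
#'
#' Estimates the cell density (cells per unit length) at each node: at an
#' interior node the reciprocal of the mean of the two adjacent cell lengths,
#' `2 / (x_{i+1} - x_{i-1})`; at the pinned and free boundaries the
#' reciprocal of the single adjacent cell length.
#'
#' @param chain A [cell_chain()].
#' @return A list with `positions` (the node positions) and `q` (the density
#'   samples, all positive).
#' @export
node_density <- function(chain) {
  x <- chain$x
  N <- chain$N
  q <- numeric(N + 1)
  q[1] <- 1 / x[2]
  if (N > 1) q[2:N] <- 2 / (x[3:(N + 1)] - x[1:(N - 1)])
  q[N + 1] <- 1 / (x[N + 1] - x[N])
  list(positions = x, q = q)
}
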