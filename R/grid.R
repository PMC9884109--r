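#' The 5 x 5 grid space
#'
#' The navigation task takes place on a 5 x 5 grid of states. Coordinates
#' are 1-based: `(x, y)` with `x` the column and `y` the row. States are
#' also addressed by a linear index 1..25 in row-major order from the
#' bottom-left corner, so that indices 1-5 correspond to (1,1)-(5,1) and
#' indices 6-10 to (1,2)-(5,2).
#'
#' @name grid-space
#' @keywords internal
NULL

GRID_SIDE <- 5L
N_STATES <- 25L
START_STATE <- 1L # (1, 1)

#' Convert grid coordinates to the linear state index
#'
#' @param x Column, integer in 1..5. May be a vector.
#' @param y Row, integer in 1..5. Same length as `x`.
#' @return Integer state index in 1..25, `(y - 1) * 5 + x`.
#' @examples
#' state_index(1, 1) # 1
#' state_index(1, 2) # 6
#' @seealso [coord_of()] for the inverse.
#' @export
state_index <- function(x, y) {
  x <- as.integer(x)
  y <- as.integer(y)
  if (any(x < 1L | x > GRID_SIDE) || any(y < 1L | y > GRID_SIDE)) {
    stop("grid coordinates must lie in 1..", GRID_SIDE, call. = FALSE)
  }
  (y - 1L) * GRID_SIDE + x
}

#' Convert a linear state index to grid coordinates
#'
#' @param s Integer state index in 1..25. May be a vector.
#' @return A list with integer vectors `x` and `y`.
#' @export
coord_of <- function(s) {
  s <- as.integer(s)
  if (any(s < 1L | s > N_STATES)) {
    stop("state index must lie in 1..", N_STATES, call. = FALSE)
  }
  list(x = (s - 1L) %% GRID_SIDE + 1L, y = (s - 1L) %/% GRID_SIDE + 1L)
}

#' Neighbouring states of a grid state
#'
#' Returns the 4-neighbourhood (no diagonals, no self) of a state: two
#' neighbours at the corners, three at the edges, four elsewhere. The
#' order is fixed as left, right, down, up (i.e. x-1, x+1, y-1, y+1,
#' keeping only in-range cells). This ordering is part of the package's
#' reproducibility contract: action selection draws a single uniform
#' variate against the cumulative softmax probabilities in this order, so
#' the ordering determines how the random stream is consumed.
#'
#' @param s Integer state index in 1..25.
#' @return Integer vector of neighbouring state indices.
#' @examples
#' grid_neighbors(1) # corner: 2 neighbours
#' grid_neighbors(13) # centre: 4 neighbours
#' @export
grid_neighbors <- function(s) {
  co <- coord_of(s)
  x <- co$x
  y <- co$y
  nb <- integer(0)
  if (x > 1L) nb <- c(nb, s - 1L)
  if (x < GRID_SIDE) nb <- c(nb, s + 1L)
  if (y > 1L) nb <- c(nb, s - GRID_SIDE)
  if (y < GRID_SIDE) nb <- c(nb, s + GRID_SIDE)
  nb
}

# Precomputed neighbour lists, used by the pure-R engine.
neighbor_table <- function() {
  lapply(seq_len(N_STATES), grid_neighbors)
}
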