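#' Cell topology: a juxtacrine contact graph
#'
#' Delta-Notch signalling is juxtacrine: a cell's Delta ligand binds Notch
#' receptors only on cells it physically touches. The topology records, for
#' each of the `n_cells` cells, the indices of its contacting neighbours.
#' Adjacency must be symmetric and self-contact is not allowed. A cell with no
#' neighbours is permitted (all its neighbour sums are zero).
#'
#' @param neighbors A list of integer vectors; `neighbors[[i]]` are the
#'   neighbour indices of cell `i`.
#' @param n_cells Number of cells; defaults to `length(neighbors)`.
#' @return An object of class `nd_topology` with fields `n_cells` and
#'   `neighbors`.
#' @seealso [two_cell_topology()], [grid_topology()]
#' @export
nd_topology <- function(neighbors, n_cells = length(neighbors)) {
  stopifnot(is.list(neighbors), n_cells == length(neighbors), n_cells >= 1)
  neighbors <- lapply(neighbors, function(v) sort(as.integer(v)))
  for (i in seq_len(n_cells)) {
    v <- neighbors[[i]]
    if (anyDuplicated(v)) stop("duplicate neighbour entries for cell ", i)
    if (any(v < 1L | v > n_cells)) stop("neighbour index out of range for cell ", i)
    if (any(v == i)) stop("self-loop at cell ", i)
    for (j in v) {
      if (!(i %in% neighbors[[j]])) {
        stop("adjacency not symmetric: ", j, " in NG(", i, ") but not vice versa")
      }
    }
  }
  structure(list(n_cells = as.integer(n_cells), neighbors = neighbors),
            class = "nd_topology")
}

#' @export
print.nd_topology <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("<nd_topology>", x$n_cells, "cells; degree range",
      paste(range(deg), collapse = "-"), "\n")
  invisible(x)
}

#' Two mutually contacting cells
#'
#' The minimal topology for lateral inhibition: two cells in contact, each the
#' sole neighbour of the other. This is the configuration for which equilibria
#' and local stability are analysed in closed form.
#'
#' @return An `nd_topology` with 2 cells.
#' @export
two_cell_topology <- function() {
  nd_topology(list(2L, 1L))
}

#' Rectangular lattice topology
#'
#' Builds a `rows x cols` grid of cells with von Neumann (4-neighbour)
#' adjacency. Cell indices are row-major: cell `(r, c)` has index
#' `(r - 1) * cols + c`. With `periodic_cols = TRUE` the first and last column
#' are joined, turning each row into a ring - a crude model of the intestinal
#' tube's circumference.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param periodic_cols Wrap columns horizontally (default `FALSE`).
#' @return An `nd_topology` with `rows * cols` cells.
#' @examples
#' grid_topology(5, 12)
#' @export
grid_topology <- function(rows, cols, periodic_cols = FALSE) {
  stopifnot(rows >= 1, cols >= 1, rows == round(rows), cols == round(cols))
  idx <- function(r, c) (r - 1L) * cols + c
  nbr <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      v <- integer(0)
      if (r > 1L)    v <- c(v, idx(r - 1L, c))
      if (r < rows)  v <- c(v, idx(r + 1L, c))
      if (periodic_cols && cols > 2L) {
        v <- c(v, idx(r, if (c == 1L) cols else c - 1L),
                  idx(r, if (c == cols) 1L else c + 1L))
      } else {
        if (c > 1L)    v <- c(v, idx(r, c - 1L))
        if (c < cols)  v <- c(v, idx(r, c + 1L))
      }
      nbr[[idx(r, c)]] <- unique(v)
    }
  }
  nd_topology(nbr)
}

#' Initial cell state
#'
#' @param topology An [nd_topology()].
#' @param value Either a single number used for every component of every cell
#'   (default 0.5, the conventional starting concentration), a length-3 vector
#'   of per-component values `(D, N, A)`, or a full `n_cells x 3` matrix.
#' @return An `n_cells x 3` numeric matrix with columns `D`, `N`, `A`.
#' @export
initial_state <- function(topology, value = 0.5) {
  n <- topology$n_cells
  x <- if (is.matrix(value)) {
    stopifnot(nrow(value) == n, ncol(value) == 3)
    value
  } else if (length(value) == 3L) {
    matrix(rep(value, each = n), n, 3)
  } else if (length(value) == 1L) {
    matrix(value, n, 3)
  } else {
    stop("`value` must be a scalar, a length-3 vector or an n_cells x 3 matrix")
  }
  colnames(x) <- c("D", "N", "A")
  x
}
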