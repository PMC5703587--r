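#' Hexagonal-offset electrode layout
#'
#' Builds a rows-by-cols multi-electrode array with odd rows offset by half a
#' pitch (hexagonal packing). Electrodes are numbered row-major; the center
#' electrode is the middle grid cell, used as the reference position when
#' translating traces from different stimulating electrodes onto a common
#' frame.
#'
#' @param rows,cols grid dimensions (`rows * cols >= 2`).
#' @param pitch nearest-neighbour electrode spacing (um).
#' @return object of class `mea_layout` with electrode positions (um),
#'   grid coordinates and the center electrode index.
#' @export
make_layout <- function(rows, cols, pitch = 60) {
  if (rows * cols < 2L) stop("layout needs at least two electrodes")
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- (grid$col - 1) * pitch + ((grid$row - 1) %% 2) * pitch / 2
  y <- (grid$row - 1) * pitch * sqrt(3) / 2
  index <- matrix(seq_len(rows * cols), nrow = rows, ncol = cols,
                  byrow = TRUE)
  center <- index[ceiling(rows / 2), ceiling(cols / 2)]
  structure(list(positions = cbind(x = x, y = y), row = grid$row,
                 col = grid$col, index = index, rows = rows, cols = cols,
                 pitch = pitch, center = center),
            class = "mea_layout")
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout> %d x %d hexagonal grid, pitch %g um, center electrode %d\n",
              x$rows, x$cols, x$pitch, x$center))
  invisible(x)
}

#' Translate electrode indices on the grid
#'
#' Shifts every electrode by the grid offset that moves electrode `from`
#' onto electrode `to`, in (row, col) index space. Electrodes whose shifted
#' cell falls outside the grid map to `NA`. On the grid interior the map is
#' a bijection.
#'
#' @param layout a [make_layout()] object.
#' @param from,to electrode indices defining the shift.
#' @return integer vector: for each electrode, the index of its translated
#'   position, or `NA` if it leaves the grid.
#' @export
translate_electrodes <- function(layout, from, to) {
  dr <- layout$row[to] - layout$row[from]
  dc <- layout$col[to] - layout$col[from]
  r <- layout$row + dr
  c <- layout$col + dc
  ok <- r >= 1L & r <= layout$rows & c >= 1L & c <= layout$cols
  out <- rep(NA_integer_, length(r))
  out[ok] <- layout$index[cbind(r[ok], c[ok])]
  out
}
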