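#' Regular grid geometry
#'
#' Defines a cell-centred regular square grid: `origin_x`/`origin_y` is the
#' lower-left corner of the lower-left cell, `cell_size` the cell edge in
#' metres, and `nx`/`ny` the cell counts. Cell centres sit at
#' `origin + (i - 0.5) * cell_size`. Cells are stored in a single vector in
#' x-fastest order starting from the bottom row, i.e. cell `(ix, iy)` is
#' element `(iy - 1) * nx + ix`.
#'
#' @param origin_x,origin_y lower-left corner coordinates (m).
#' @param cell_size cell edge length (m), positive.
#' @param nx,ny number of cells in x and y, at least 1.
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(0, 0, 60, 120, 120)
#' head(grid_centres(g))
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 60,
                      nx = 120, ny = 120) {
  stopifnot(is.numeric(cell_size), cell_size > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), nx = nx, ny = ny),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (origin %g, %g; %.2f km2)\n",
              x$nx, x$ny, x$cell_size, x$origin_x, x$origin_y,
              x$nx * x$ny * x$cell_size^2 / 1e6))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a [grid_spec()].
#' @return Integer cell count `nx * ny`.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' Cell-centre coordinates
#' @param grid a [grid_spec()].
#' @return A two-column matrix of cell-centre x/y coordinates in storage
#'   order (x fastest, bottom row first).
#' @export
grid_centres <- function(grid) {
  cx <- grid$origin_x + (seq_len(grid$nx) - 0.5) * grid$cell_size
  cy <- grid$origin_y + (seq_len(grid$ny) - 0.5) * grid$cell_size
  cbind(x = rep(cx, times = grid$ny), y = rep(cy, each = grid$nx))
}

#' Map point coordinates to grid node indices
#'
#' Returns the storage-order index of the cell containing each point
#' (points on a cell boundary go to the higher cell, clamped to the grid).
#'
#' @param grid a [grid_spec()].
#' @param x,y point coordinates (m).
#' @return Integer vector of 1-based cell indices; `NA` for points outside
#'   the grid extent.
#' @export
grid_node_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin_x) / grid$cell_size) + 1
  iy <- floor((y - grid$origin_y) / grid$cell_size) + 1
  ix[ix == grid$nx + 1 & x <= grid$origin_x + grid$nx * grid$cell_size] <- grid$nx
  iy[iy == grid$ny + 1 & y <= grid$origin_y + grid$ny * grid$cell_size] <- grid$ny
  out <- (iy - 1) * grid$nx + ix
  out[ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny] <- NA_integer_
  as.integer(out)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Grid-valued map
#'
#' A single attribute on a [grid_spec()]: a values vector in storage order
#' plus the grid geometry. Probability maps, E-type estimates, risk masks
#' and land-use maps are all `grid_map`s (with subclasses).
#'
#' @param grid a [grid_spec()].
#' @param values numeric/integer/logical vector of length `n_cells(grid)`;
#'   `NA` marks masked (NODATA) cells.
#' @param attribute attribute name (for labels and file headers).
#' @return A `grid_map` object.
#' @export
grid_map <- function(grid, values, attribute = "value") {
  stopifnot(inherits(grid, "grid_spec"), length(values) == n_cells(grid))
  structure(list(grid = grid, values = values, attribute = attribute),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("grid_map '%s': %d x %d cells", x$attribute, x$grid$nx, x$grid$ny))
  if (is.numeric(v) && length(v))
    cat(sprintf("; range [%.4g, %.4g], mean %.4g", min(v), max(v), mean(v)))
  cat("\n")
  invisible(x)
}

#' Convert a grid map to a matrix
#'
#' @param x a [grid_map()].
#' @param ... unused.
#' @return An `ny` x `nx` matrix with row 1 the TOP row (map orientation,
#'   as in an ESRI ASCII grid body).
#' @export
as.matrix.grid_map <- function(x, ...) {
  m <- matrix(x$values, nrow = x$grid$nx, ncol = x$grid$ny) # [ix, iy]
  t(m)[x$grid$ny:1, , drop = FALSE]
}

#' Categorical land-use map
#'
#' @param grid a [grid_spec()].
#' @param codes integer vector (1-based class codes) of length `n_cells(grid)`.
#' @param levels character vector of class names; every code must index it.
#' @return A `land_use_map` (also a `grid_map`).
#' @export
land_use_map <- function(grid, codes, levels) {
  codes <- as.integer(codes)
  if (anyNA(codes) || any(codes < 1L | codes > length(levels)))
    stop("land-use codes must all reference a declared land-use type")
  out <- grid_map(grid, codes, attribute = "land_use")
  out$levels <- as.character(levels)
  class(out) <- c("land_use_map", class(out))
  out
}

#' @export
print.land_use_map <- function(x, ...) {
  tab <- table(factor(x$levels[x$values], levels = x$levels))
  cat(sprintf("land_use_map: %d x %d cells; shares: %s\n",
              x$grid$nx, x$grid$ny,
              paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Quick image plot of a grid map
#' @param x a [grid_map()].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.grid_map <- function(x, main = x$attribute, ...) {
  g <- x$grid
  cx <- g$origin_x + (seq_len(g$nx) - 0.5) * g$cell_size
  cy <- g$origin_y + (seq_len(g$ny) - 0.5) * g$cell_size
  z <- matrix(as.numeric(x$values), nrow = g$nx, ncol = g$ny)
  graphics::image(cx, cy, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
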