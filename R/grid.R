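#' Build an equal-area landscape grid
#'
#' Creates the spatial frame every other layer joins against: a regular
#' lattice of square cells on an equal-area plane. Cell ids are 0-based and
#' contiguous; coordinates are cell centres in km.
#'
#' @param nx,ny Number of columns / rows of the lattice.
#' @param cell_km Side length of a cell in km. The default 20 km gives the
#'   400 km2 cells typical of national-scale diversity grids.
#' @return A tibble with columns `cell_id`, `x`, `y`, `area` (km2).
#' @examples
#' make_grid(4, 3)
#' @export
make_grid <- function(nx, ny, cell_km = 20) {
  if (nx < 1 || ny < 1) abort("grid dimensions must be positive")
  n <- as.integer(nx) * as.integer(ny)
  tibble(
    cell_id = 0:(n - 1L),
    # row-major from the north-west corner: x fastest, y decreasing
    x = cell_km * (rep(seq_len(nx), times = ny) - 0.5),
    y = cell_km * (rep(rev(seq_len(ny)), each = nx) - 0.5),
    area = cell_km^2
  )
}

# Infer (nx, ny) from a regular grid tibble.
grid_dims <- function(grid) {
  nx <- length(unique(grid$x))
  ny <- length(unique(grid$y))
  if (nx * ny != nrow(grid)) abort("grid is not a regular lattice")
  c(nx = nx, ny = ny)
}
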