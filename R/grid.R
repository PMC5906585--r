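#' Lattice geometry of the simulated tissue block
#'
#' The tissue is discretised into a regular lattice of cubic patches of side
#' `patch_width` micrometres.  Patch coordinates are 0-based integer indices;
#' patch `(i, j, k)` occupies the half-open cube
#' `[i * dx, (i + 1) * dx) x ... ` along each axis.
#'
#' @param nx,ny,nz Patch counts per axis (integers >= 1).
#' @param patch_width Patch side length in micrometres (> 0).
#' @return An object of class `vf_grid`.
#' @export
#' @examples
#' g <- grid_spec(1390, 1006, 110, 15)
#' grid_extent_mm(g)  # 20.85 x 15.09 x 1.65 mm
grid_spec <- function(nx, ny, nz, patch_width = 15) {
  dims <- c(nx, ny, nz)
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != floor(dims)))
    stop("grid dimensions must be positive integers")
  if (!is.numeric(patch_width) || length(patch_width) != 1L || patch_width <= 0)
    stop("patch_width must be a single positive number")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 patch_width = as.numeric(patch_width)),
            class = "vf_grid")
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nz)

#' Number of patches in a grid or world
#' @param x A `vf_grid` or `vf_world`.
#' @return Total patch count (double, to stay exact beyond 2^31).
#' @export
patch_count <- function(x) {
  g <- if (inherits(x, "vf_world")) x$grid else x
  stopifnot(inherits(g, "vf_grid"))
  prod(as.numeric(grid_dims(g)))
}

#' Physical extent of the lattice in millimetres
#' @param grid A `vf_grid`.
#' @return Numeric vector `c(x, y, z)` of extents in mm.
#' @export
grid_extent_mm <- function(grid) {
  stopifnot(inherits(grid, "vf_grid"))
  as.numeric(grid_dims(grid)) * grid$patch_width / 1000
}

#' Stored data points per field family
#'
#' Every patch stores one value per chemical (8 fields) and one per ECM
#' protein (3 fields); the total is therefore 11 values per patch.
#'
#' @param x A `vf_grid` or `vf_world`.
#' @return List with `chemical_points`, `ecm_points` and `total`.
#' @export
data_point_counts <- function(x) {
  p <- patch_count(x)
  list(chemical_points = 8 * p, ecm_points = 3 * p, total = 11 * p)
}

#' @export
print.vf_grid <- function(x, ...) {
  ext <- grid_extent_mm(x)
  cat(sprintf("<grid %d x %d x %d patches (%g um) = %.4g x %.4g x %.4g mm>\n",
              x$nx, x$ny, x$nz, x$patch_width, ext[1], ext[2], ext[3]))
  invisible(x)
}

## 1-based linear index of 0-based patch coordinates (vectorised)
patch_index <- function(grid, x, y, z) {
  1L + x + grid$nx * (y + grid$ny * z)
}

## inverse of patch_index: matrix of 0-based coords
patch_coords <- function(grid, idx) {
  i <- idx - 1L
  x <- i %% grid$nx
  r <- i %/% grid$nx
  y <- r %% grid$ny
  z <- r %/% grid$ny
  cbind(x = x, y = y, z = z)
}

in_grid <- function(grid, x, y, z) {
  x >= 0L & x < grid$nx & y >= 0L & y < grid$ny & z >= 0L & z < grid$nz
}
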