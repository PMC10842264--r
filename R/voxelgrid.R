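#' Construct a voxel grid
#'
#' A `voxel_grid` is a 3D scalar density sampled on a regular isotropic
#' lattice. It is the working container for density segments, simulated
#' probe maps, masks, and correlation score volumes.
#'
#' The physical coordinate (in Angstrom) of the *center* of voxel
#' `(i, j, k)` (1-based R indices) is
#' `origin + voxel_size * (i - 1, j - 1, k - 1)`. The first array index is
#' the fastest-varying ("x") axis, matching the canonical MRC column axis.
#'
#' @param values numeric 3D array of finite densities.
#' @param voxel_size isotropic voxel edge length in Angstrom (> 0).
#' @param origin physical position (Angstrom) of the center of voxel
#'   `(1, 1, 1)`.
#' @return an object of class `voxel_grid` with fields `values`,
#'   `voxel_size`, `origin`.
#' @export
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), voxel_size = 2.612)
#' grid_dims(g)
voxel_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("voxel values must all be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("'voxel_size' must be a single positive number")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("'origin' must be three finite numbers")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size), origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.4g A/voxel\n", d[1], d[2], d[3],
    x$voxel_size))
  cat(sprintf("  origin   : (%.3f, %.3f, %.3f) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values   : min %.4g, max %.4g, mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Grid dimensions
#'
#' @param grid a [voxel_grid()].
#' @return integer triple `(nx, ny, nz)`.
#' @export
grid_dims <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  dim(grid$values)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

assert_grid <- function(grid, arg = deparse(substitute(grid))) {
  if (!is_voxel_grid(grid))
    stop(sprintf("'%s' must be a voxel_grid", arg))
  invisible(grid)
}

## Shared check that two grids live on commensurate lattices.
assert_same_frame <- function(a, b, check_dims = TRUE) {
  assert_grid(a, "a"); assert_grid(b, "b")
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop("voxel_size mismatch between grids")
  if (check_dims && !identical(grid_dims(a), grid_dims(b)))
    stop("grid dimension mismatch")
  invisible(TRUE)
}
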