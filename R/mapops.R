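## Map conditioning utilities: the operations the matching protocol applies
## to a target segment before scoring (low-pass, threshold cutoff, autocrop
## of zero margins, and the corner "edge guard" that defeats autocropping).

## Spatial frequency magnitude (1/A) for every voxel of an FFT layout grid.
fourier_freq_grid <- function(dims, voxel_size) {
  fr <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    if (n == 1) k <- 0
    k / (n * voxel_size)
  }
  kx <- fr(dims[1]); ky <- fr(dims[2]); kz <- fr(dims[3])
  sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
}

#' Low-pass filter a density map
#'
#' Attenuates Fourier amplitudes with a soft isotropic filter whose
#' amplitude falls to one half at spatial frequency `1/resolution`. The
#' default shape is Gaussian, `H(k) = exp(-ln 2 * (k * resolution)^2)`,
#' which matches the blur kernel of [simulate_map()] so that filtered
#' targets and simulated probes are directly comparable. A raised-cosine
#' shape is available as an alternative. The DC component is always
#' unchanged.
#'
#' @param grid a [voxel_grid()].
#' @param resolution target resolution in Angstrom; must satisfy
#'   `resolution >= 2 * voxel_size` (Nyquist).
#' @param shape `"gaussian"` (default) or `"raised_cosine"`. The raised
#'   cosine passes frequencies below `0.5/resolution` untouched and rolls
#'   off to zero at `1.5/resolution`, crossing one half at `1/resolution`.
#' @return the filtered [voxel_grid()].
#' @export
lowpass_filter <- function(grid, resolution,
                           shape = c("gaussian", "raised_cosine")) {
  assert_grid(grid)
  shape <- match.arg(shape)
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution < 2 * grid$voxel_size)
    stop(sprintf(
      "'resolution' must be >= 2 * voxel_size = %.4g A (Nyquist limit)",
      2 * grid$voxel_size))
  k <- fourier_freq_grid(grid_dims(grid), grid$voxel_size)
  h <- lowpass_transfer(k, resolution, shape)
  f <- stats::fft(grid$values) * h
  out <- Re(stats::fft(f, inverse = TRUE)) / length(f)
  voxel_grid(array(out, grid_dims(grid)), grid$voxel_size, grid$origin)
}

## Filter transfer function; exported logic kept separate so tests can
## evaluate the analytic attenuation at a single frequency.
lowpass_transfer <- function(k, resolution, shape = "gaussian") {
  if (shape == "gaussian") {
    exp(-log(2) * (k * resolution)^2)
  } else {
    k1 <- 0.5 / resolution; k2 <- 1.5 / resolution
    h <- 0.5 * (1 + cos(pi * (k - k1) / (k2 - k1)))
    h[k <= k1] <- 1
    h[k >= k2] <- 0
    h
  }
}

#' Zero densities at or below a threshold
#'
#' Sets every voxel with value `<= cutoff` to zero and preserves the rest,
#' the conditioning the matching protocol applies to a target segment
#' before correlation (protocol setting: cutoff 0.0048 on that map's
#' density scale).
#'
#' @param grid a [voxel_grid()].
#' @param cutoff density threshold, same units as the map values.
#' @return the thresholded [voxel_grid()].
#' @export
apply_cutoff <- function(grid, cutoff) {
  assert_grid(grid)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  v <- grid$values
  v[v <= cutoff] <- 0
  voxel_grid(v, grid$voxel_size, grid$origin)
}

#' Crop a map to the bounding box of above-cutoff density
#'
#' Returns the minimal axis-aligned sub-grid containing every voxel with
#' value strictly greater than `cutoff`, with the origin updated so
#' physical coordinates are preserved. This mirrors the automatic
#' zero-margin cropping the reference docking tool performs to cut
#' computational cost.
#'
#' @param grid a [voxel_grid()].
#' @param cutoff density threshold; at least one voxel must exceed it.
#' @return the cropped [voxel_grid()].
#' @seealso [apply_edge_guard()] for the protocol trick that defeats this
#'   cropping when the full box must be retained.
#' @export
autocrop <- function(grid, cutoff) {
  assert_grid(grid)
  above <- which(grid$values > cutoff, arr.ind = TRUE)
  if (nrow(above) == 0L)
    stop("autocrop: no voxel above cutoff")
  lo <- unname(apply(above, 2, min)); hi <- unname(apply(above, 2, max))
  v <- grid$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  voxel_grid(array(v, hi - lo + 1L), grid$voxel_size,
             grid$origin + grid$voxel_size * (lo - 1))
}

#' Guard a map's corners against autocropping
#'
#' Sets the first voxel `(1,1,1)` and the last voxel `(nx,ny,nz)` to a value
#' slightly above `cutoff`, so that [autocrop()] at that cutoff returns the
#' grid with unchanged dimensions. This reproduces the published fix of
#' hand-editing the first and last values of the map file to be slightly
#' larger than the threshold, preventing the docking tool from shrinking a
#' deliberately padded box.
#'
#' The guard value is `cutoff * (1 + 1e-3)` (relative epsilon 1e-3); for
#' `cutoff = 0` an absolute epsilon of 1e-9 is used so the guard voxels are
#' still strictly above the threshold.
#'
#' @param grid a [voxel_grid()].
#' @param cutoff the density threshold the guard must defeat.
#' @return the guarded [voxel_grid()], same dimensions.
#' @export
apply_edge_guard <- function(grid, cutoff) {
  assert_grid(grid)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  eps <- if (cutoff != 0) abs(cutoff) * 1e-3 else 1e-9
  d <- grid_dims(grid)
  v <- grid$values
  v[1, 1, 1] <- cutoff + eps
  v[d[1], d[2], d[3]] <- cutoff + eps
  voxel_grid(v, grid$voxel_size, grid$origin)
}
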