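#' Simulation parameters
#'
#' Parameters controlling how an atomic model is blurred into a density
#' map. Each atom contributes an isotropic 3D Gaussian whose Fourier
#' amplitude falls to one half at spatial frequency `1/resolution` — the
#' same convention as [lowpass_filter()], so simulated probes and
#' low-passed targets live on a common resolution scale. The corresponding
#' real-space standard deviation is
#' `sigma = resolution * sqrt(ln 2 / 2) / pi` (about 0.187 * resolution).
#'
#' @param resolution nominal resolution in Angstrom; must be at least
#'   `2 * voxel_size` (Nyquist).
#' @param voxel_size grid spacing in Angstrom.
#' @param padding empty margin (Angstrom) around the model's bounding box
#'   when no frame is supplied.
#' @param weight_mode `"unit"` (every atom weight as stored in the model)
#'   or `"mass"` (element-mass weights; requires elements).
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(resolution = 6.0, voxel_size = 2.612,
                              padding = 3 * resolution,
                              weight_mode = c("unit", "mass")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.numeric(resolution), length(resolution) == 1L,
            is.finite(resolution), resolution > 0,
            is.numeric(voxel_size), length(voxel_size) == 1L, voxel_size > 0,
            is.numeric(padding), length(padding) == 1L, padding >= 0)
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 * voxel_size (Nyquist)")
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 padding = padding, weight_mode = weight_mode),
            class = "simulation_params")
}

## Blur kernel width for the half-amplitude-at-1/resolution convention.
sigma_from_resolution <- function(resolution) {
  resolution * sqrt(log(2) / 2) / pi
}

## Gaussian kernels are truncated at 4 sigma per axis (then renormalized);
## mass loss before renormalization is below 0.02%.
KERNEL_TRUNC <- 4.0

#' Simulate a density map from an atomic model
#'
#' Accumulates one truncated, renormalized Gaussian per atom (weight `w`,
#' standard deviation `sigma(resolution)`, see [simulation_params()]) on a
#' voxel grid. With unit weights and adequate sampling the map integrates
#' to the atom count: `sum(values) * voxel_size^3 ~ sum(weights)`.
#'
#' @param model an [atomic_model()].
#' @param params a [simulation_params()].
#' @param frame optional [voxel_grid()] supplying dims and origin (its
#'   values are ignored); its voxel size must equal `params$voxel_size`.
#'   With a frame, Gaussian tails falling outside the box are clipped.
#'   Without one, a minimal box padded by `params$padding` is used.
#' @return a [voxel_grid()] of simulated density.
#' @export
simulate_map <- function(model, params = simulation_params(), frame = NULL) {
  stopifnot(inherits(model, "atomic_model"),
            inherits(params, "simulation_params"))
  h <- params$voxel_size
  sigma <- sigma_from_resolution(params$resolution)
  w <- if (params$weight_mode == "mass") element_mass(model$element)
       else model$weight
  if (is.null(frame)) {
    pad <- params$padding + KERNEL_TRUNC * sigma
    lo <- apply(model$coords, 2, min) - pad
    hi <- apply(model$coords, 2, max) + pad
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / h)) + 1L)
    origin <- lo
  } else {
    assert_grid(frame, "frame")
    if (abs(frame$voxel_size - h) > 1e-6 * h)
      stop("frame voxel_size does not match params$voxel_size")
    dims <- grid_dims(frame)
    origin <- frame$origin
  }
  vals <- cpp_simulate_map(model$coords, as.numeric(w), as.integer(dims),
                           as.numeric(origin), h, sigma, KERNEL_TRUNC)
  voxel_grid(vals, h, origin)
}

#' Add reproducible Gaussian noise to a map
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `sigma` to
#' every voxel. The same seed always yields the same output; the caller's
#' RNG state is left untouched.
#'
#' @param grid a [voxel_grid()].
#' @param sigma noise standard deviation in density units (>= 0).
#' @param seed integer seed.
#' @return the noisy [voxel_grid()].
#' @export
add_noise <- function(grid, sigma, seed) {
  assert_grid(grid)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0) return(grid)
  vals <- grid$values +
    with_seed(seed, stats::rnorm(length(grid$values), sd = sigma))
  voxel_grid(array(vals, grid_dims(grid)), grid$voxel_size, grid$origin)
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
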