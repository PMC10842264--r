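## Shared fixture builders. Everything is generated in code; no data files.

## Small random grid with reproducible values.
random_grid <- function(dims = c(8, 8, 8), voxel = 2.0, seed = 1,
                        origin = c(0, 0, 0)) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(dims)), dims), voxel, origin)
}

## A model placed so its centroid sits at the center of an n^3 frame.
centered_model <- function(model, dims = c(48, 48, 48), voxel = 2.612) {
  ctr <- (dims - 1) / 2 * voxel
  atomic_model(model$model_id,
               sweep(model$coords, 2, ctr - model_centroid(model), "+"),
               element = model$element, weight = model$weight)
}

empty_frame <- function(dims = c(48, 48, 48), voxel = 2.612) {
  voxel_grid(array(0, dims), voxel)
}

## Direct triple-loop linear cross-correlation:
## score(d) = sum_v t(v) * p(v - d), the independent oracle for the FFT scan.
brute_force_correlation <- function(tvals, pvals) {
  td <- dim(tvals); pd <- dim(pvals)
  od <- td + pd - 1L
  out <- array(0, od)
  for (dz in seq_len(od[3]) - pd[3]) {
    for (dy in seq_len(od[2]) - pd[2]) {
      for (dx in seq_len(od[1]) - pd[1]) {
        acc <- 0
        for (k in seq_len(pd[3])) {
          vz <- k + dz
          if (vz < 1 || vz > td[3]) next
          for (j in seq_len(pd[2])) {
            vy <- j + dy
            if (vy < 1 || vy > td[2]) next
            vx <- seq_len(pd[1]) + dx
            ok <- vx >= 1 & vx <= td[1]
            if (any(ok))
              acc <- acc + sum(tvals[vx[ok], vy, vz] * pvals[ok, j, k])
          }
        }
        out[dx + pd[1], dy + pd[2], dz + pd[3]] <- acc
      }
    }
  }
  out
}

## Zero-boundary discrete Laplacian oracle (direct stencil).
brute_force_laplacian <- function(vals, h) {
  d <- dim(vals)
  out <- array(0, d)
  gv <- function(i, j, k) {
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) 0
    else vals[i, j, k]
  }
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1]))
        out[i, j, k] <- (gv(i - 1, j, k) + gv(i + 1, j, k) + gv(i, j - 1, k) +
                           gv(i, j + 1, k) + gv(i, j, k - 1) +
                           gv(i, j, k + 1) - 6 * vals[i, j, k]) / h^2
  out
}

## Geodesic rotation error (degrees) between a pose rotation and a truth.
rot_error <- function(fit, true_rotation) {
  rotation_distance(fit$pose$rotation, true_rotation)
}
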