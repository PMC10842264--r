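#' Fitting parameters
#'
#' Settings of the rigid-body matching protocol. Defaults mirror the
#' published operating point: 6 Angstrom resolution, 15 degree rotational
#' step, density cutoff applied to the target before scoring.
#'
#' @param resolution blur/comparison resolution in Angstrom.
#' @param step_deg nominal rotational sampling step in degrees.
#' @param cutoff density threshold applied to the target ([apply_cutoff()])
#'   before any scoring.
#' @param mode correlation mode: `"standard"` (plain cross-correlation) or
#'   `"laplacian"` (discrete 3D Laplacian applied to target and probe
#'   before correlation, emphasizing surface contrast).
#' @param mirror if `TRUE`, [fit_model()] additionally searches the mirror
#'   image of the model and returns the better of the two, flagged. Off by
#'   default; mirroring is never applied silently.
#' @param weight_mode atom weighting for the simulated probe: `"unit"` or
#'   `"mass"`.
#' @param search `"auto"` (the default: exhaustive in [fit_model()],
#'   two-stage in [scan_library()]), `"full"` for the exhaustive
#'   single-stage rotation scan, or `"two_stage"` for the accelerated
#'   coarse-then-local scan described in the package vignette.
#' @param keep number of coarse orientations whose neighborhoods are
#'   rescanned in two-stage mode.
#' @param neighborhood radius of those neighborhoods, as a multiple of
#'   `step_deg`.
#' @param polish apply the deterministic local orientation polish to the
#'   best lattice orientations (default `TRUE`). At intermediate
#'   resolution the correlation decays steeply with misorientation, so the
#'   raw lattice argmax understates every model's attainable score; the
#'   polish is a sampling-based shrinking-step local search (no
#'   gradients), see the vignette.
#' @param n_polish number of mutually distant lattice orientations taken
#'   as polish starting points.
#' @return a `fit_params` list.
#' @export
fit_params <- function(resolution = 6.0, step_deg = 15.0, cutoff = 0.0,
                       mode = c("standard", "laplacian"), mirror = FALSE,
                       weight_mode = c("unit", "mass"),
                       search = c("auto", "full", "two_stage"),
                       keep = 6L, neighborhood = 1.5,
                       polish = TRUE, n_polish = 4L) {
  mode <- match.arg(mode)
  weight_mode <- match.arg(weight_mode)
  search <- match.arg(search)
  stopifnot(is.numeric(resolution), resolution > 0,
            is.numeric(step_deg), step_deg > 0, step_deg <= 360,
            is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff),
            is.logical(mirror), length(mirror) == 1L,
            is.numeric(keep), keep >= 1, is.numeric(neighborhood),
            neighborhood > 0, is.logical(polish), length(polish) == 1L,
            is.numeric(n_polish), n_polish >= 1)
  structure(list(resolution = resolution, step_deg = step_deg,
                 cutoff = cutoff, mode = mode, mirror = mirror,
                 weight_mode = weight_mode, search = search,
                 keep = as.integer(keep), neighborhood = neighborhood,
                 polish = polish, n_polish = as.integer(n_polish)),
            class = "fit_params")
}

#' Rigid pose
#'
#' A proper rotation plus a translation, placing a model in a grid frame.
#' The transform of an atom at `x` is `R (x - c) + c + t`, where `c` is the
#' model centroid: rotation about the centroid, then translation.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation in Angstrom.
#' @return a `pose` object.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), all(is.finite(rotation)),
            length(translation) == 3L, all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("'rotation' must be a proper rotation matrix")
  structure(list(rotation = rotation, translation = translation),
            class = "pose")
}

#' Translational cross-correlation scan
#'
#' Computes, for every integer voxel displacement `d`,
#' `score(d) = sum_v target(v) * probe(v - d)`, by zero-padded FFT so the
#' result equals the direct (non-circular) linear correlation. In
#' `"laplacian"` mode the discrete 6-neighbor Laplacian (zero outside the
#' box) is applied to both grids first.
#'
#' @param target,probe [voxel_grid()]s with equal voxel size.
#' @param mode `"standard"` or `"laplacian"`.
#' @return a [voxel_grid()] of scores with dims `dim(target) + dim(probe)
#'   - 1`; the voxel at R index `(i, j, k)` holds the score of displacement
#'   `d = (i, j, k) - dim(probe)` (so displacement zero sits at index
#'   `dim(probe)`), and the stored origin is `-dim(probe) * voxel_size`.
#' @export
cc_translation_scan <- function(target, probe,
                                mode = c("standard", "laplacian")) {
  mode <- match.arg(mode)
  assert_same_frame(target, probe, check_dims = FALSE)
  vals <- cpp_linear_correlation(
    as.numeric(target$values), grid_dims(target),
    as.numeric(probe$values), grid_dims(probe),
    target$voxel_size, identical(mode, "laplacian"))
  voxel_grid(vals, target$voxel_size,
             -grid_dims(probe) * target$voxel_size)
}

## Discrete 6-neighbor Laplacian with zero-outside boundary (R side, used
## by score_pose in laplacian mode).
discrete_laplacian <- function(grid) {
  v <- grid$values
  d <- dim(v)
  sh <- function(k, axis) {  # shift by k along axis, zero fill
    out <- array(0, d)
    n <- d[axis]
    if (abs(k) >= n) return(out)
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    if (k > 0) { dst[[axis]] <- (1 + k):n; src[[axis]] <- 1:(n - k) }
    if (k < 0) { dst[[axis]] <- 1:(n + k); src[[axis]] <- (1 - k):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  lap <- -6 * v + sh(1, 1) + sh(-1, 1) + sh(1, 2) + sh(-1, 2) +
    sh(1, 3) + sh(-1, 3)
  voxel_grid(lap / grid$voxel_size^2, grid$voxel_size, grid$origin)
}

#' Score a model at a fixed pose
#'
#' Places the model at the pose (rotation about the centroid, then
#' translation), simulates its density on the target's frame at the
#' parameters' resolution, and returns both score flavors over the full
#' box, after applying the density cutoff to the target:
#' `cc_unnormalized = sum(t * p)` — an overlap integral that grows without
#' bound with probe mass — and
#' `cc_normalized = sum(t * p) / sqrt(sum(t^2) * sum(p^2))`, which
#' Cauchy-Schwarz confines to `[-1, 1]`. In `"laplacian"` mode both maps
#' are Laplacian-filtered before the sums.
#'
#' @param target a [voxel_grid()].
#' @param model an [atomic_model()].
#' @param pose a [pose()].
#' @param params a [fit_params()].
#' @return named numeric: `cc_normalized`, `cc_unnormalized`.
#' @export
score_pose <- function(target, model, pose, params = fit_params()) {
  assert_grid(target)
  stopifnot(inherits(model, "atomic_model"), inherits(pose, "pose"),
            inherits(params, "fit_params"))
  tc <- apply_cutoff(target, params$cutoff)
  coords <- transform_coords(model, pose$rotation, pose$translation)
  d <- grid_dims(target)
  h <- target$voxel_size
  pad <- KERNEL_TRUNC * sigma_from_resolution(params$resolution)
  lo <- target$origin - pad
  hi <- target$origin + (d - 1L) * h + pad
  inside <- coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
    coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
    coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
  if (!any(inside))
    stop("model lies entirely outside the target frame at this pose")
  w <- if (params$weight_mode == "mass") element_mass(model$element)
       else model$weight
  p <- cpp_simulate_map(coords, as.numeric(w), d, as.numeric(target$origin),
                        h, sigma_from_resolution(params$resolution),
                        KERNEL_TRUNC)
  tv <- tc$values
  pv <- p
  if (params$mode == "laplacian") {
    tv <- discrete_laplacian(tc)$values
    pv <- discrete_laplacian(voxel_grid(p, h, target$origin))$values
  }
  raw <- sum(tv * pv)
  den <- sqrt(sum(tv^2) * sum(pv^2))
  c(cc_normalized = if (den > 0) raw / den else 0, cc_unnormalized = raw)
}

## Internal: run the compiled rotation scan for a set of rotation indices.
scan_rotation_subset <- function(tc, model_coords, weights, centroid,
                                 rotset, indices, params) {
  rot <- rotset$matrices[, , indices, drop = FALSE]
  res <- cpp_scan_rotations(
    as.numeric(tc$values), grid_dims(tc), tc$voxel_size,
    as.numeric(tc$origin), model_coords, as.numeric(weights),
    as.numeric(centroid), as.numeric(rot), params$resolution,
    identical(params$mode, "laplacian"))
  cbind(res, index = indices)
}

## Internal: full or two-stage rotation search. Returns the (sorted,
## feasible) per-rotation results matrix over fine-set members.
search_rotations <- function(tc, model, weights, rotset, params, search) {
  centroid <- model_centroid(model)
  tidy <- function(m) {
    m <- m[m[, "feasible"] > 0, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    m[order(-m[, "cc_norm"], -m[, "cc_raw"], m[, "index"]), , drop = FALSE]
  }
  if (search == "full") {
    return(tidy(scan_rotation_subset(
      tc, model$coords, weights, centroid, rotset,
      seq_len(rotset$size), params)))
  }
  ## two-stage: coarse scan at twice the step, then rescan the fine-set
  ## neighborhoods of the best coarse orientations
  coarse <- generate_rotations(min(360, 2 * params$step_deg))
  cm <- scan_rotation_subset(tc, model$coords, weights, centroid, coarse,
                             seq_len(coarse$size), params)
  cm <- cm[cm[, "feasible"] > 0, , drop = FALSE]
  if (nrow(cm) == 0L) return(NULL)
  kept <- cm[order(-cm[, "cc_norm"], -cm[, "cc_raw"],
                   cm[, "index"])[seq_len(min(params$keep, nrow(cm)))],
             "index"]
  kq <- coarse$quaternions[kept, , drop = FALSE]
  cos_lim <- cos(params$neighborhood * params$step_deg * pi / 360)
  prox <- abs(rotset$quaternions %*% t(kq))
  cand <- which(apply(prox, 1, max) >= cos_lim)
  if (length(cand) == 0L) cand <- seq_len(rotset$size)
  tidy(scan_rotation_subset(tc, model$coords, weights, centroid,
                            rotset, cand, params))
}

## Internal: pick up to n rows of a sorted results matrix whose rotations
## are mutually at least min_sep degrees apart (greedy), so the polish
## starts from distinct orientation basins rather than one cluster.
diverse_candidates <- function(results, rotset, n, min_sep_deg) {
  chosen <- integer()
  cos_lim <- cos(min_sep_deg * pi / 360)
  for (r in seq_len(nrow(results))) {
    idx <- as.integer(results[r, "index"])
    q <- rotset$quaternions[idx, ]
    if (length(chosen) == 0L ||
        all(abs(rotset$quaternions[chosen, , drop = FALSE] %*% q) < cos_lim))
      chosen <- c(chosen, idx)
    if (length(chosen) >= n) break
  }
  results[match(chosen, results[, "index"]), , drop = FALSE]
}

## Internal: deterministic local orientation polish. Starting from a
## lattice rotation, repeatedly evaluates the six single-axis
## perturbations of the current orientation (same FFT translation scan,
## shrinking angular scale, strict improvement required to move) until the
## scale drops below stop_deg. Sampling-based; no gradients.
polish_rotation <- function(tc, model, weights, R0, score0, params,
                            start_deg = params$step_deg / 2,
                            stop_deg = 1.6, max_batches = 14L) {
  centroid <- model_centroid(model)
  axes <- rbind(diag(3), -diag(3))
  cur_R <- R0
  cur_norm <- unname(score0)
  s <- start_deg
  batches <- 0L
  while (s >= stop_deg && batches < max_batches) {
    batches <- batches + 1L
    rots <- array(0, c(3, 3, 6))
    for (i in 1:6) {
      a <- axes[i, ] * s * pi / 180
      rots[, , i] <- axis_angle_matrix(a) %*% cur_R
    }
    m <- cpp_scan_rotations(
      as.numeric(tc$values), grid_dims(tc), tc$voxel_size,
      as.numeric(tc$origin), model$coords, as.numeric(weights),
      as.numeric(centroid), as.numeric(rots), params$resolution,
      identical(params$mode, "laplacian"))
    feas <- which(m[, "feasible"] > 0)
    if (length(feas)) {
      b <- feas[order(-m[feas, "cc_norm"])[1]]
      if (isTRUE(unname(m[b, "cc_norm"]) > cur_norm)) {
        cur_R <- rots[, , b]
        cur_norm <- unname(m[b, "cc_norm"])
        next                       # moved: keep the current scale
      }
    }
    s <- s / 2
  }
  list(rotation = cur_R, cc_norm = cur_norm)
}

## Internal: exact 6D local refinement (standard mode). Pattern search over
## single-axis rotation and translation perturbations of the pose, scored by
## the exact double-precision kernel (cpp_pose_score), shrinking both scales
## until convergence. Replaces any scan-landscape bias with the true
## objective near the optimum.
exact_pose_refine <- function(tc, model, weights, pose0, params,
                              start_rot_deg = 3, start_trans = NULL,
                              max_batches = 24L) {
  h <- tc$voxel_size
  if (is.null(start_trans)) start_trans <- 0.35 * h
  sigma <- sigma_from_resolution(params$resolution)
  sumt2 <- sum(tc$values^2)
  ctr <- model_centroid(model)
  tvals <- tc$values
  dim(tvals) <- NULL                      # one copy, reused by every eval
  dims <- grid_dims(tc)
  org <- as.numeric(tc$origin)
  w <- as.numeric(weights)
  base <- sweep(model$coords, 2, ctr)
  eval_pose <- function(R, tr) {
    coords <- base %*% t(R) +
      matrix(ctr + tr, nrow(base), 3, byrow = TRUE)
    v <- cpp_pose_score(tvals, dims, org, h, coords, w, sigma)
    den <- sqrt(sumt2 * v[2])
    if (den > 0) v[1] / den else 0
  }
  cur_R <- pose0$rotation; cur_t <- pose0$translation
  cur <- eval_pose(cur_R, cur_t)
  s_r <- start_rot_deg; s_t <- start_trans
  axes <- rbind(diag(3), -diag(3))
  for (batch in seq_len(max_batches)) {
    best_v <- cur; best_R <- cur_R; best_t <- cur_t
    for (i in 1:6) {
      R2 <- axis_angle_matrix(axes[i, ] * s_r * pi / 180) %*% cur_R
      v <- eval_pose(R2, cur_t)
      if (v > best_v) { best_v <- v; best_R <- R2; best_t <- cur_t }
      t2 <- cur_t + axes[i, ] * s_t
      v <- eval_pose(cur_R, t2)
      if (v > best_v) { best_v <- v; best_R <- cur_R; best_t <- t2 }
    }
    if (best_v > cur) {
      cur <- best_v; cur_R <- best_R; cur_t <- best_t
    } else {
      s_r <- s_r / 2; s_t <- s_t / 2
      if (s_r < 0.08 && s_t < 0.02) break
    }
  }
  list(pose = pose(cur_R, cur_t), cc_normalized = cur)
}

## Rotation matrix from an axis-angle vector (angle = |v| radians).
axis_angle_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  u <- v / th
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * ux + (1 - cos(th)) * (ux %*% ux)
}

## Internal: sub-voxel parabolic interpolation of the correlation peak of
## the chosen rotation; returns list(d = integer displacement, off = sub-
## voxel offset per axis).
refine_translation <- function(tc, model, weights, rotation, params) {
  vol <- cpp_rotation_volume(
    as.numeric(tc$values), grid_dims(tc), tc$voxel_size,
    as.numeric(tc$origin), model$coords, as.numeric(weights),
    as.numeric(model_centroid(model)), as.numeric(rotation),
    params$resolution, identical(params$mode, "laplacian"))
  if (!isTRUE(vol$feasible)) return(NULL)
  d <- grid_dims(tc)
  ax <- lapply(1:3, function(a) vol$dlo[a]:vol$dhi[a])
  ix <- lapply(1:3, function(a) (ax[[a]] %% d[a]) + 1L)
  sub <- vol$corr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  best <- vapply(1:3, function(a) ax[[a]][w[a]], numeric(1))
  off <- numeric(3)
  for (a in 1:3) {
    if (w[a] <= 1L || w[a] >= length(ax[[a]])) next
    sel <- as.list(w); sel[[a]] <- w[a] + c(-1L, 0L, 1L)
    tri <- sub[sel[[1]], sel[[2]], sel[[3]]]
    ## the correlation peak is near-Gaussian, for which the parabola of the
    ## log is exact; fall back to a plain parabola for non-positive flanks
    if (all(tri > 0)) tri <- log(tri)
    den <- tri[1] - 2 * tri[2] + tri[3]
    if (den < 0) off[a] <- max(-0.5, min(0.5, 0.5 * (tri[1] - tri[3]) / den))
  }
  list(d = best, off = off)
}

#' Fit a model into a target density
#'
#' The 6D rigid-body search: every rotation of a quasi-uniform sample at
#' `params$step_deg` is scored against the (cutoff-conditioned) target for
#' every integer voxel displacement that keeps the probe's density inside
#' the box, via an FFT correlation scan. The best pose by normalized
#' cross-correlation (ties: unnormalized score, then rotation index) is
#' refined to sub-voxel translation by parabolic interpolation of the score
#' peak — the refined translation is kept only if it improves the
#' double-precision rescore — and re-scored exactly with [score_pose()].
#'
#' With `params$mirror = TRUE` the mirror image of the model is searched
#' too and the better of the two results is returned, flagged `mirrored`.
#'
#' @param target a [voxel_grid()] density segment.
#' @param model an [atomic_model()].
#' @param params a [fit_params()]; `search = "auto"` means the exhaustive
#'   single-stage scan here.
#' @return a `fit_result`: list with `model_id`, `pose`, `cc_normalized`,
#'   `cc_unnormalized`, `rotation_index`, `n_rotations`, `n_atoms`,
#'   `mirrored`, and the `params` used.
#' @export
fit_model <- function(target, model, params = fit_params()) {
  assert_grid(target)
  stopifnot(inherits(model, "atomic_model"), inherits(params, "fit_params"))
  if (params$resolution < 2 * target$voxel_size)
    stop("params$resolution must be >= 2 * voxel_size (Nyquist)")
  tc <- apply_cutoff(target, params$cutoff)
  if (all(tc$values == 0))
    stop("degenerate target: no density above the cutoff")
  search <- if (params$search == "auto") "full" else params$search
  rotset <- generate_rotations(params$step_deg)
  h <- target$voxel_size

  fit_one <- function(mod, mirrored) {
    w <- if (params$weight_mode == "mass") element_mass(mod$element)
         else mod$weight
    results <- search_rotations(tc, mod, w, rotset, params, search)
    if (is.null(results))
      stop("model does not fit inside the target box at any displacement")
    best <- results[1, ]
    ridx <- as.integer(best[["index"]])
    rot <- rotset$matrices[, , ridx]
    ## exact (double-precision, exact-kernel) evaluation of one rotation:
    ## integer peak and its sub-voxel refinement, the better of the two
    rescore_rotation <- function(rot) {
      ref <- refine_translation(tc, mod, w, rot, params)
      d_int <- if (is.null(ref)) best[c("dx", "dy", "dz")] else ref$d
      cand <- list(pose(rot, as.numeric(d_int) * h))
      if (!is.null(ref) && any(ref$off != 0))
        cand <- c(cand, list(pose(rot, (as.numeric(d_int) + ref$off) * h)))
      scores <- lapply(cand, function(p) score_pose(target, mod, p, params))
      cc <- vapply(scores, `[[`, numeric(1), "cc_normalized")
      pick <- which.max(cc)   # first maximum wins: a tie keeps the integer pose
      list(pose = cand[[pick]],
           cc_normalized = scores[[pick]][["cc_normalized"]],
           cc_unnormalized = scores[[pick]][["cc_unnormalized"]])
    }
    if (isTRUE(params$polish)) {
      ## a coarser lattice resolves basins less well, so it affords (and
      ## needs) proportionally more polish starting points
      n_starts <- max(params$n_polish,
                      ceiling(params$n_polish * params$step_deg / 15))
      starts <- diverse_candidates(results, rotset, n_starts,
                                   min_sep_deg = 1.2 * params$step_deg)
      polished <- lapply(seq_len(nrow(starts)), function(i) {
        idx <- as.integer(starts[i, "index"])
        polish_rotation(tc, mod, w, rotset$matrices[, , idx],
                        starts[i, "cc_norm"], params)
      })
      ## candidates compete on their exact rescored correlation, not on the
      ## smoothed search score
      exact <- lapply(polished, function(p) rescore_rotation(p$rotation))
      win <- which.max(vapply(exact, `[[`, numeric(1), "cc_normalized"))
      final <- exact[[win]]
      ridx <- as.integer(starts[win, "index"])
      ## second phase: exact local 6D refinement of the winning pose
      ## (standard mode; the Laplacian objective keeps the scan optimum)
      if (params$mode == "standard") {
        ref2 <- exact_pose_refine(tc, mod, w, final$pose, params,
                                  start_rot_deg = max(3, params$step_deg / 6))
        if (ref2$cc_normalized > final$cc_normalized) {
          sc <- score_pose(target, mod, ref2$pose, params)
          final <- list(pose = ref2$pose,
                        cc_normalized = sc[["cc_normalized"]],
                        cc_unnormalized = sc[["cc_unnormalized"]])
        }
      }
      rot <- final$pose$rotation
    } else {
      final <- rescore_rotation(rot)
    }
    list(model_id = mod$model_id, pose = final$pose,
         cc_normalized = final$cc_normalized,
         cc_unnormalized = final$cc_unnormalized,
         rotation_index = ridx, n_rotations = rotset$size,
         n_atoms = n_atoms(mod), mirrored = mirrored, params = params)
  }

  res <- fit_one(model, FALSE)
  if (isTRUE(params$mirror)) {
    resm <- fit_one(mirror_model(model), TRUE)
    if (resm$cc_normalized > res$cc_normalized) res <- resm
  }
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> '%s': CC %.4f (unnormalized %.4g)%s\n",
              x$model_id, x$cc_normalized, x$cc_unnormalized,
              if (x$mirrored) " [mirrored]" else ""))
  cat(sprintf("  rotation #%d of %d (step %.3g deg), translation (%.2f, %.2f, %.2f) A\n",
              x$rotation_index, x$n_rotations, x$params$step_deg,
              x$pose$translation[1], x$pose$translation[2],
              x$pose$translation[3]))
  invisible(x)
}
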