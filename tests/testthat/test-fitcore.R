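test_that("FFT translation scan equals the brute-force correlation", {
  for (seed in 1:3) {
    t <- random_grid(c(8, 8, 8), voxel = 2.0, seed = seed)
    p <- random_grid(c(8, 8, 8), voxel = 2.0, seed = seed + 50)
    for (mode in c("standard", "laplacian")) {
      scan <- cc_translation_scan(t, p, mode = mode)
      tv <- t$values; pv <- p$values
      if (mode == "laplacian") {
        tv <- brute_force_laplacian(tv, 2.0)
        pv <- brute_force_laplacian(pv, 2.0)
      }
      oracle <- brute_force_correlation(tv, pv)
      expect_lt(max(abs(scan$values - oracle)), 1e-8)
    }
  }
  ## mismatched probe shapes work too (non-cubic)
  t <- random_grid(c(9, 6, 7), voxel = 1.5, seed = 4)
  p <- random_grid(c(4, 5, 3), voxel = 1.5, seed = 5)
  scan <- cc_translation_scan(t, p)
  expect_identical(grid_dims(scan), c(12L, 10L, 9L))
  expect_lt(max(abs(scan$values -
                      brute_force_correlation(t$values, p$values))), 1e-8)
  expect_error(cc_translation_scan(t, random_grid(c(4, 4, 4), voxel = 2)),
               "voxel_size")
})

test_that("scan peaks sit at the constructed displacement", {
  g <- random_grid(c(8, 8, 8), voxel = 2.0, seed = 9)
  self <- cc_translation_scan(g, g)
  peak <- which(self$values == max(self$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]) - grid_dims(g), c(0, 0, 0))
  ## probe = target shifted by (2, 0, 1) voxels
  shifted <- array(0, c(8, 8, 8))
  shifted[3:8, , 2:8] <- g$values[1:6, , 1:7]
  scan <- cc_translation_scan(voxel_grid(shifted, 2.0), g)
  peak <- which(scan$values == max(scan$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]) - grid_dims(g), c(2, 0, 1))
})

test_that("self-scoring attains the Cauchy-Schwarz bound", {
  m <- centered_model(make_helix_bundle(3, 20, seed = 2, model_id = "m"))
  target <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  sc <- score_pose(target, m, pose(), fit_params(cutoff = 0))
  expect_equal(unname(sc["cc_normalized"]), 1.0, tolerance = 1e-6)
  expect_gt(unname(sc["cc_unnormalized"]), 0)
})

test_that("normalized scores are bounded and scale-invariant; raw scores scale", {
  m <- centered_model(make_helix_bundle(2, 15, seed = 3, model_id = "m"))
  for (seed in 1:5) {
    target <- add_noise(random_grid(c(48, 48, 48), voxel = 2.612,
                                    seed = seed), 0.01, seed)
    sc <- score_pose(target, m, pose(), fit_params(cutoff = 0))
    expect_gte(1, abs(unname(sc["cc_normalized"])))
  }
  target <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  s1 <- score_pose(target, m, pose(), fit_params(cutoff = 0))
  scaled <- voxel_grid(target$values * 12, target$voxel_size, target$origin)
  s2 <- score_pose(scaled, m, pose(), fit_params(cutoff = 0))
  expect_equal(unname(s2["cc_normalized"]), unname(s1["cc_normalized"]),
               tolerance = 1e-9)
  expect_equal(unname(s2["cc_unnormalized"]),
               12 * unname(s1["cc_unnormalized"]), tolerance = 1e-9)
})

test_that("heavy probes break the unnormalized score but not the normalized", {
  ## the reported pathology: matching a much more massive model can push
  ## the raw overlap integral above 1 while the normalized score cannot
  m <- centered_model(make_helix_bundle(4, 40, seed = 6, model_id = "m"))
  target <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  heavy <- atomic_model("heavy", m$coords, weight = 10)
  sc <- score_pose(target, heavy, pose(), fit_params(cutoff = 0))
  expect_gt(unname(sc["cc_unnormalized"]), 1)
  expect_lte(unname(sc["cc_normalized"]), 1)
  expect_equal(unname(sc["cc_normalized"]), 1, tolerance = 1e-6)
})

test_that("fit recovers the identity pose from a noiseless self-target", {
  m <- centered_model(make_helix_bundle(3, 25, seed = 11, model_id = "m"))
  target <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  fit <- fit_model(target, m, fit_params(step_deg = 30, cutoff = 0))
  expect_gte(fit$cc_normalized, 0.99)
  expect_lte(rot_error(fit, diag(3)), 30)
  expect_lt(max(abs(fit$pose$translation)), 0.5 * 2.612)
})

test_that("a target rotated by a set member is recovered exactly", {
  m <- centered_model(make_helix_bundle(3, 25, seed = 11, model_id = "m"))
  params <- fit_params(step_deg = 30, cutoff = 0)
  rs <- generate_rotations(30)
  R <- rs$matrices[, , 137]
  rotated <- atomic_model("m", denscan:::transform_coords(m, R))
  target <- simulate_map(rotated, simulation_params(6, 2.612), empty_frame())
  fit <- fit_model(target, m, params)
  expect_equal(fit$pose$rotation, R, tolerance = 1e-12)
  expect_identical(fit$rotation_index, 137L)
  expect_equal(max(abs(fit$pose$translation)), 0, tolerance = 1e-9)
  ## the score equals the unrotated self-fit score
  target0 <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  fit0 <- fit_model(target0, m, params)
  expect_equal(fit$cc_normalized, fit0$cc_normalized, tolerance = 1e-6)
})

test_that("a finer rotational step never scores worse", {
  m <- centered_model(make_helix_bundle(3, 25, seed = 13, model_id = "m"))
  set.seed(21)
  R <- denscan:::quat_to_matrix(denscan:::random_quaternions(1))[, , 1]
  rotated <- atomic_model("m", denscan:::transform_coords(m, R))
  target <- simulate_map(rotated, simulation_params(6, 2.612), empty_frame())
  ## polish off: this compares the raw lattice search spaces
  coarse <- fit_model(target, m, fit_params(step_deg = 360, cutoff = 0,
                                            polish = FALSE))
  fine <- fit_model(target, m, fit_params(step_deg = 15, cutoff = 0,
                                          polish = FALSE))
  expect_gt(fine$cc_normalized, coarse$cc_normalized)
})

test_that("scores are invariant under a joint rigid motion", {
  m <- centered_model(make_helix_bundle(3, 20, seed = 17, model_id = "m"))
  rs <- generate_rotations(45)
  R <- rs$matrices[, , 40]
  moved <- atomic_model("m", denscan:::transform_coords(m, R, c(3.1, -2.2, 1.0)))
  t1 <- simulate_map(m, simulation_params(6, 2.612), empty_frame())
  t2 <- simulate_map(moved, simulation_params(6, 2.612), empty_frame())
  s1 <- score_pose(t1, m, pose(), fit_params(cutoff = 0))
  s2 <- score_pose(t2, moved, pose(), fit_params(cutoff = 0))
  expect_equal(unname(s1["cc_normalized"]), unname(s2["cc_normalized"]),
               tolerance = 1e-9)
})

test_that("degenerate targets and out-of-frame models are rejected", {
  m <- make_helix_bundle(2, 10, seed = 1, model_id = "m")
  zero <- voxel_grid(array(0, c(16, 16, 16)), 2.612)
  expect_error(fit_model(zero, m, fit_params(step_deg = 90)), "degenerate")
  target <- random_grid(c(16, 16, 16), voxel = 2.612, seed = 1)
  far <- atomic_model("far", m$coords + 500)
  expect_error(score_pose(target, far, pose(), fit_params(cutoff = 0)),
               "outside")
})

test_that("the mirror search flags and recovers mirrored targets", {
  m <- centered_model(make_helix_bundle(3, 22, seed = 19, model_id = "m"))
  mm <- denscan:::mirror_model(m)
  target <- simulate_map(mm, simulation_params(6, 2.612), empty_frame())
  params <- fit_params(step_deg = 30, cutoff = 0, mirror = TRUE)
  fit <- fit_model(target, m, params)
  expect_true(fit$mirrored)
  expect_gte(fit$cc_normalized, 0.99)
  ## without the mirror flag the achievable score is visibly lower
  plain <- fit_model(target, m, fit_params(step_deg = 30, cutoff = 0))
  expect_false(plain$mirrored)
  expect_lt(plain$cc_normalized, fit$cc_normalized)
})
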