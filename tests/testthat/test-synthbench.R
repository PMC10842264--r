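test_that("alpha-helix geometry is exact", {
  m <- make_alpha_helix(20)
  z <- m$coords[, 3]
  expect_equal(max(z) - min(z), 1.5 * 19, tolerance = 1e-9)
  ## angular advance about the axis between consecutive residues
  ang <- atan2(m$coords[, 2], m$coords[, 1]) * 180 / pi
  adv <- (diff(ang) + 360) %% 360
  expect_equal(adv, rep(100, 19), tolerance = 1e-9)
  ## radius and axis orientation
  expect_equal(sqrt(rowSums(m$coords[, 1:2]^2)), rep(2.3, 20),
               tolerance = 1e-9)
  tilted <- make_alpha_helix(20, start = c(5, 5, 5), axis = c(1, 1, 0))
  u <- c(1, 1, 0) / sqrt(2)
  proj <- tilted$coords %*% u
  expect_equal(max(proj) - min(proj), 1.5 * 19, tolerance = 1e-9)
  expect_error(make_alpha_helix(1), "at least 2")
})

test_that("helix bundles respect count, spacing and seeding", {
  m <- make_helix_bundle(3, 25, spacing = 11, seed = 4)
  expect_identical(n_atoms(m), 75L)
  ## axis positions form a regular polygon with nearest distance = spacing
  rc <- 11 / (2 * sin(pi / 3))
  axes <- t(sapply(0:2, function(k)
    c(rc * cos(2 * pi * k / 3), rc * sin(2 * pi * k / 3))))
  d <- as.matrix(dist(axes))
  expect_equal(min(d[d > 0]), 11, tolerance = 1e-9)
  ## atoms of each helix stay within helix radius of its axis
  for (k in 1:3) {
    sub <- m$coords[((k - 1) * 25 + 1):(k * 25), 1:2]
    expect_lt(max(sqrt(colSums((t(sub) - axes[k, ])^2))), 2.3 + 1e-6)
  }
  expect_identical(make_helix_bundle(3, 25, seed = 4)$coords, m$coords)
  expect_false(identical(make_helix_bundle(3, 25, seed = 5)$coords,
                         m$coords))
  expect_error(make_helix_bundle(0, 10), "at least 1")
  expect_error(make_helix_bundle(3, 10, spacing = -1), "spacing")
})

test_that("periodic filaments repeat at the 16-nm default", {
  unit <- make_alpha_helix(10, model_id = "u")
  fil <- make_periodic_filament(unit, 3)
  expect_identical(n_atoms(fil), 30L)
  for (j in 1:2) {
    off <- fil$coords[(j * 10 + 1):((j + 1) * 10), ] - fil$coords[1:10, ]
    expect_equal(unname(off),
                 matrix(rep(c(0, 0, 160 * j), each = 10), 10),
                 tolerance = 1e-9)
  }
  fil2 <- make_periodic_filament(unit, 2, period = 95.5)
  expect_equal(unname(fil2$coords[11, 3] - fil2$coords[1, 3]), 95.5,
               tolerance = 1e-9)
  expect_error(make_periodic_filament(unit, 0), "at least 1")
  expect_error(make_periodic_filament(unit, 2, period = 0), "period")
})

test_that("decoy libraries are sized, unique and seeded", {
  lib <- make_decoy_library(20, size_range = c(60, 120), seed = 9)
  expect_length(lib, 20)
  ids <- vapply(lib, function(m) m$model_id, character(1))
  expect_false(any(duplicated(ids)))
  sizes <- vapply(lib, n_atoms, integer(1))
  ## bundles round the target size to a multiple of the helix count
  expect_true(all(sizes >= 55 & sizes <= 125))
  lib2 <- make_decoy_library(20, size_range = c(60, 120), seed = 9)
  expect_identical(lapply(lib2, function(m) m$coords),
                   lapply(lib, function(m) m$coords))
  lib3 <- make_decoy_library(20, size_range = c(60, 120), seed = 10)
  expect_false(identical(lapply(lib3, function(m) m$coords),
                         lapply(lib, function(m) m$coords)))
})

test_that("benchmark cases are pure functions of their seed", {
  a <- make_benchmark_case(5, n_decoys = 3, snr = 2)
  b <- make_benchmark_case(5, n_decoys = 3, snr = 2)
  expect_identical(a$target$values, b$target$values)
  expect_identical(a$truth$coords, b$truth$coords)
  expect_identical(lapply(a$library, function(m) m$coords),
                   lapply(b$library, function(m) m$coords))
  expect_identical(a$true_pose$rotation, b$true_pose$rotation)
  expect_false(identical(make_benchmark_case(6, n_decoys = 3, snr = 2)
                         $target$values, a$target$values))
  expect_identical(a$library[[1]]$model_id, a$truth$model_id)
})

test_that("benchmark noise is calibrated to the requested SNR", {
  for (snr in c(1, 4)) {
    case <- make_benchmark_case(8, n_decoys = 1, snr = snr)
    clean <- make_benchmark_case(8, n_decoys = 1, snr = Inf)
    noise <- case$target$values - clean$target$values
    expect_equal(sd(noise) / sqrt(mean(clean$target$values^2)), 1 / snr,
                 tolerance = 0.05)
  }
  case <- make_benchmark_case(8, n_decoys = 1, snr = Inf)
  expect_identical(case$noise_sigma, 0)
  expect_error(make_benchmark_case(8, n_decoys = 1, snr = 0), "snr")
  expect_error(make_benchmark_case(8, n_decoys = 0), "n_decoys")
})

test_that("a noiseless benchmark pipeline recovers its truth end to end", {
  params <- fit_params(resolution = 6, step_deg = 30, cutoff = 0.0025)
  case <- make_benchmark_case(12, n_decoys = 5, snr = Inf, params = params)
  tab <- scan_library(case$library, case$target, case$params)
  expect_identical(tab$model_id[1], "truth")
  expect_gte(tab$cc_normalized[1], 0.99)
  fit <- fit_model(case$target, case$truth, case$params)
  expect_lte(rot_error(fit, case$true_pose$rotation), 30)
  expect_lt(max(abs(fit$pose$translation - case$true_pose$translation)),
            0.5 * case$target$voxel_size)
})

test_that("benchmark cases serialize to MRC + PDB + manifest", {
  case <- make_benchmark_case(3, n_decoys = 2, snr = 1)
  dir <- withr::local_tempdir()
  write_benchmark_case(case, dir)
  expect_true(file.exists(file.path(dir, "target.mrc")))
  back <- read_density(file.path(dir, "target.mrc"))
  expect_equal(max(abs(back$values - case$target$values)), 0,
               tolerance = 1e-6)
  pdbs <- list.files(file.path(dir, "library"), pattern = "\\.pdb$")
  expect_length(pdbs, 3)
  truth_back <- read_model(file.path(dir, "library", "truth.pdb"))
  expect_equal(unname(truth_back$coords), unname(case$truth$coords),
               tolerance = 1e-3)
  manifest <- paste(readLines(file.path(dir, "manifest.json")),
                    collapse = "")
  expect_match(manifest, '"truth_id": "truth"')
})
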