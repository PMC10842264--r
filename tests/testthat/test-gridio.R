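test_that("MRC round trip preserves values, dims, voxel size and origin", {
  g0 <- random_grid(c(2, 3, 4), voxel = 2.612, seed = 3,
                    origin = c(-5.5, 0, 12.25))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_density(g0, path)
  g1 <- read_density(path)
  expect_identical(grid_dims(g1), grid_dims(g0))
  expect_equal(g1$voxel_size, 2.612, tolerance = 1e-6)
  expect_equal(g1$origin, g0$origin, tolerance = 1e-6)
  ## first pass quantizes doubles to float32; a second pass must be exact
  write_density(g1, path)
  g2 <- read_density(path)
  expect_identical(g2$values, g1$values)
  expect_equal(max(abs(g1$values - g0$values)), 0, tolerance = 1e-6)
})

test_that("malformed or unsupported map files give format errors", {
  path <- withr::local_tempfile(fileext = ".mrc")
  set.seed(1)
  writeBin(as.raw(sample(0:255, 4096, replace = TRUE)), path)
  expect_error(read_density(path), "MAP|header|MRC")
  expect_error(read_density(file.path(tempdir(), "does-not-exist.mrc")),
               "not found")
  ## mode errors name the offending field
  g <- random_grid(c(4, 4, 4))
  write_density(g, path)
  raw <- readBin(path, "raw", n = file.size(path))
  raw[13:16] <- writeBin(1L, raw(), size = 4L, endian = "little")  # mode 1
  writeBin(raw, path)
  expect_error(read_density(path), "mode")
})

test_that("non-finite values are refused before writing", {
  g <- random_grid(c(3, 3, 3))
  g$values[1, 1, 1] <- NaN
  expect_error(write_density(g, withr::local_tempfile()), "finite")
})

test_that("low-pass filter matches its analytic transfer function", {
  n <- 60; h <- 1.0
  x <- (seq_len(n) - 1) * h
  per6 <- array(rep(sin(2 * pi * x / 6), times = n * n), c(n, n, n))
  per20 <- array(rep(sin(2 * pi * x / 20), times = n * n), c(n, n, n))
  amp <- function(g, period) {
    f <- fft(g$values)
    2 * Mod(f[n / (period / h) + 1, 1, 1]) / length(f)
  }
  for (res in c(10, 14)) {
    f6 <- lowpass_filter(voxel_grid(per6, h), res)
    f20 <- lowpass_filter(voxel_grid(per20, h), res)
    expect_equal(amp(f6, 6), lowpass_transfer(1 / 6, res), tolerance = 1e-6)
    expect_equal(amp(f20, 20), lowpass_transfer(1 / 20, res),
                 tolerance = 1e-6)
    ## the shorter period is attenuated more
    expect_lt(amp(f6, 6), amp(f20, 20))
  }
})

test_that("low-pass preserves DC, never increases power, rejects sub-Nyquist", {
  g <- voxel_grid(array(5, c(6, 6, 6)), 2.0)
  expect_equal(lowpass_filter(g, 10)$values, g$values, tolerance = 1e-12)
  r <- random_grid(c(12, 12, 12), voxel = 2.0, seed = 7)
  once <- lowpass_filter(r, 8)
  twice <- lowpass_filter(once, 8)
  a1 <- Mod(fft(once$values)); a2 <- Mod(fft(twice$values))
  expect_true(all(a2 <= a1 + 1e-9))
  expect_equal(mean(twice$values), mean(r$values), tolerance = 1e-12)
  expect_error(lowpass_filter(r, 3.9), "Nyquist")
})

test_that("apply_cutoff zeroes exactly the voxels at or below the threshold", {
  set.seed(11)
  vals <- array(runif(64, 0, 0.01), c(4, 4, 4))
  g <- voxel_grid(vals, 2.612)
  out <- apply_cutoff(g, 0.0048)
  expect_identical(out$values == 0, vals <= 0.0048)
  expect_identical(out$values[vals > 0.0048], vals[vals > 0.0048])
  expect_identical(apply_cutoff(g, min(vals) - 1)$values, vals)
  expect_true(all(apply_cutoff(g, max(vals))$values == 0))
})

test_that("autocrop shrinks to the above-cutoff bounding box, keeping frame", {
  set.seed(2)
  core <- array(runif(5 * 4 * 3, 1, 2), c(5, 4, 3))
  for (k in 1:2) {
    d <- dim(core) + 2L * k
    vals <- array(0, d)
    vals[(k + 1):(k + 5), (k + 1):(k + 4), (k + 1):(k + 3)] <- core
    g <- voxel_grid(vals, 1.5, origin = c(10, 20, 30))
    out <- autocrop(g, 0)
    ## oracle: exhaustive scan for the nonzero bounding box
    idx <- which(vals > 0, arr.ind = TRUE)
    expect_identical(grid_dims(out),
                     unname(apply(idx, 2, max) - apply(idx, 2, min) + 1L))
    expect_identical(grid_dims(out), dim(core))
    expect_equal(out$origin, g$origin + 1.5 * k, tolerance = 1e-12)
    expect_identical(out$values, core)
  }
  ## corner voxels above cutoff: unchanged
  full <- voxel_grid(array(1, c(3, 3, 3)), 1)
  expect_identical(autocrop(full, 0.5)$values, full$values)
  expect_error(autocrop(voxel_grid(array(0, c(3, 3, 3)), 1), 0),
               "no voxel above cutoff")
})

test_that("edge guard defeats autocrop for any grid and is idempotent", {
  cutoff <- 0.0048
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(3:9, 3, replace = TRUE)
    vals <- array(0, d)
    ## a random interior blob that autocrop would otherwise shrink to
    vals[sample(prod(d), 4)] <- runif(4, cutoff * 2, 1)
    g <- voxel_grid(vals, 2.612)
    guarded <- apply_edge_guard(g, cutoff)
    expect_identical(grid_dims(autocrop(guarded, cutoff)), grid_dims(g))
    expect_gt(guarded$values[1, 1, 1], cutoff)
    expect_gt(guarded$values[d[1], d[2], d[3]], cutoff)
    expect_identical(apply_edge_guard(guarded, cutoff)$values,
                     guarded$values)
  }
  ## zero cutoff still guards strictly above the threshold
  g0 <- apply_edge_guard(voxel_grid(array(0, c(4, 4, 4)), 1), 0)
  expect_gt(g0$values[1, 1, 1], 0)
  expect_identical(grid_dims(autocrop(g0, 0)), c(4L, 4L, 4L))
})

test_that("FSC is 1 for self, symmetric, and scale invariant", {
  g <- random_grid(c(16, 16, 16), voxel = 2.0, seed = 5)
  self <- fsc(g, g)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  h <- random_grid(c(16, 16, 16), voxel = 2.0, seed = 6)
  ab <- fsc(g, h); ba <- fsc(h, g)
  expect_equal(ab$fsc, ba$fsc, tolerance = 1e-12)
  scaled <- voxel_grid(h$values * 37.5, h$voxel_size, h$origin)
  expect_equal(fsc(g, scaled)$fsc, ab$fsc, tolerance = 1e-9)
  expect_error(fsc(g, random_grid(c(8, 8, 8))), "mismatch")
})

test_that("FSC of independent white noise is zero-mean", {
  n <- 24L
  means <- vapply(1:20, function(s) {
    a <- random_grid(c(n, n, n), seed = 1000 + s)
    b <- random_grid(c(n, n, n), seed = 2000 + s)
    curve <- fsc(a, b)
    ## weight shells by their Fourier-voxel counts (excluding DC)
    k <- fourier_freq_grid(c(n, n, n), a$voxel_size)
    dk <- attr(curve, "shell_width")
    shell <- round(k / dk)
    cnt <- tabulate(shell[shell <= n %/% 2] + 1, nbins = nrow(curve))
    sum(curve$fsc[-1] * cnt[-1]) / sum(cnt[-1])
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 / sqrt(n^3))
})

test_that("FSC curves serialize as two-column TSV", {
  g <- random_grid(c(8, 8, 8), seed = 9)
  curve <- fsc(g, g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fsc(curve, path)
  back <- read.delim(path)
  expect_identical(names(back), c("freq", "fsc"))
  expect_equal(back$fsc, curve$fsc, tolerance = 1e-12)
})
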