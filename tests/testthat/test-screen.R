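## A small planted-truth case shared by several blocks (coarse step keeps
## these unit tests fast; the acceptance suite runs the full operating point).
mini_case <- function(seed = 31, n_decoys = 5) {
  params <- fit_params(resolution = 6, step_deg = 30, cutoff = 0.0025)
  make_benchmark_case(seed, n_decoys = n_decoys, snr = Inf, params = params)
}

test_that("a planted truth wins a library scan and the table is well-formed", {
  case <- mini_case()
  tab <- scan_library(case$library, case$target, case$params)
  expect_s3_class(tab, "rank_table")
  expect_identical(tab$model_id[1], "truth")
  expect_gte(tab$cc_normalized[1], 0.99)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_false(any(duplicated(tab$model_id)))
  expect_true(all(diff(tab$cc_normalized) <= 0))
  expect_identical(nrow(tab), length(case$library))
})

test_that("library file order never changes ranks or scores", {
  case <- mini_case(seed = 32, n_decoys = 4)
  t1 <- scan_library(case$library, case$target, case$params)
  t2 <- scan_library(rev(case$library), case$target, case$params)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("repeated scans are bit-identical", {
  case <- mini_case(seed = 33, n_decoys = 3)
  t1 <- scan_library(case$library, case$target, case$params)
  t2 <- scan_library(case$library, case$target, case$params)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("an identical model under two names scores identically, ids break the tie", {
  case <- mini_case(seed = 34, n_decoys = 2)
  twin <- case$truth
  twin$model_id <- "truth_copy"
  lib <- c(case$library, list(twin))
  tab <- scan_library(lib, case$target, case$params)
  i <- match(c("truth", "truth_copy"), tab$model_id)
  expect_lt(abs(tab$cc_normalized[i[1]] - tab$cc_normalized[i[2]]), 1e-9)
  expect_identical(diff(i), 1L)  # adjacent ranks, "truth" first by id
})

test_that("unreadable library files are skipped with a warning, not fatal", {
  case <- mini_case(seed = 35, n_decoys = 2)
  dir <- withr::local_tempdir()
  for (m in case$library)
    write_model(m, file.path(dir, paste0(m$model_id, ".pdb")))
  writeLines("this is not a pdb", file.path(dir, "broken.pdb"))
  expect_warning(tab <- scan_library(dir, case$target, case$params),
                 "skipping")
  expect_identical(nrow(tab), length(case$library))
  expect_match(attr(tab, "skipped"), "broken")
  expect_identical(tab$model_id[1], "truth")
})

test_that("empty or missing libraries are an error", {
  case <- mini_case(seed = 36, n_decoys = 1)
  expect_error(scan_library(list(), case$target, case$params), "empty")
  expect_error(scan_library(character(), case$target, case$params))
})

test_that("top_hits truncates while preserving ranks", {
  case <- mini_case(seed = 37, n_decoys = 6)
  tab <- scan_library(case$library, case$target, case$params)
  t5 <- top_hits(tab, 5)
  expect_identical(nrow(t5), 5L)
  expect_identical(t5$rank, 1:5)
  expect_identical(as.data.frame(t5), as.data.frame(tab)[1:5, ])
  expect_identical(nrow(top_hits(tab, 200)), nrow(tab))
  expect_identical(top_hits(tab, 1)$model_id, tab$model_id[1])
})

test_that("validate_control reports the control's rank", {
  case <- mini_case(seed = 38, n_decoys = 4)
  rank <- validate_control(case$target, case$library, "truth", case$params)
  expect_identical(as.integer(rank), 1L)
  expect_true(attr(rank, "passed"))
  expect_error(
    validate_control(case$target, case$library, "no_such_model",
                     case$params),
    "not in the library")
})

test_that("occupancy_ratio recovers a constructed depletion exactly", {
  set.seed(40)
  dims <- c(12, 12, 12)
  base <- voxel_grid(array(runif(prod(dims), 0.5, 1), dims), 2.0)
  fmask <- voxel_grid(array(0, dims), 2.0)
  fmask$values[2:4, 2:4, 2:4] <- 1
  rmask <- voxel_grid(array(0, dims), 2.0)
  rmask$values[8:11, 8:11, 8:11] <- 1
  expect_equal(occupancy_ratio(base, base, fmask, rmask), 1.0,
               tolerance = 1e-12)
  ko <- base
  ko$values[fmask$values > 0] <- 0.3 * ko$values[fmask$values > 0]
  expect_equal(occupancy_ratio(base, ko, fmask, rmask), 0.3,
               tolerance = 1e-9)
  empty <- voxel_grid(array(0, dims), 2.0)
  expect_error(occupancy_ratio(base, ko, fmask, empty), "reference mask")
  expect_error(occupancy_ratio(base, ko, empty, rmask), "feature mask")
  expect_error(occupancy_ratio(base, random_grid(c(6, 6, 6)), fmask, rmask),
               "mismatch")
})

test_that("rank tables round-trip through TSV with parameters echoed", {
  case <- mini_case(seed = 41, n_decoys = 3)
  tab <- scan_library(case$library, case$target, case$params)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_table(tab, path)
  lines <- readLines(path)
  expect_match(lines[2], "resolution=6")
  expect_match(lines[2], "step_deg=30")
  expect_match(lines[2], "cutoff=0.0025")
  back <- read_rank_table(path)
  expect_identical(back$rank, tab$rank)
  expect_identical(back$model_id, tab$model_id)
  expect_equal(back$cc_normalized, tab$cc_normalized, tolerance = 1e-12)
  ## pose serialized as 12 numbers
  expect_true(all(c(paste0("r", outer(1:3, 1:3, paste0)), "t1", "t2", "t3")
                  %in% names(back)))
  p <- attr(back, "params")
  expect_equal(p$resolution, 6)
  expect_equal(p$step_deg, 30)
  ## an emptied table is refused
  expect_error(write_rank_table(tab[0, ], path), "empty|rank_table")
})

test_that("confounders of the truth's fold class outrank unrelated decoys", {
  params <- fit_params(resolution = 6, step_deg = 30, cutoff = 0)
  truth <- make_helix_bundle(3, 30, seed = 70, model_id = "truth")
  placed <- centered_model(truth)
  target <- simulate_map(placed, simulation_params(6, 2.612), empty_frame())
  confounders <- lapply(1:3, function(i)
    make_helix_bundle(3, 30, seed = 80 + i,
                      model_id = sprintf("bundle_%d", i)))
  unrelated <- lapply(1:3, function(i)
    denscan:::make_blob(90, seed = 90 + i, model_id = sprintf("blob_%d", i)))
  lib <- c(list(truth), confounders, unrelated)
  tab <- scan_library(lib, target, params)
  expect_identical(tab$model_id[1], "truth")
  cc <- setNames(tab$cc_normalized, tab$model_id)
  expect_gt(min(cc[sprintf("bundle_%d", 1:3)]),
            max(cc[sprintf("blob_%d", 1:3)]))
  expect_gt(cc["truth"], max(cc[sprintf("bundle_%d", 1:3)]))
})
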