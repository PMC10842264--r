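#' Screen a model library against a target segment
#'
#' Scores every model of a library against one density segment with
#' [fit_model()] and returns a rank table: one row per model — the best
#' pose only, so multiple orientations of the same model never appear as
#' duplicate entries — sorted by descending normalized cross-correlation
#' (ties: unnormalized score, then model id). Models that fail to parse or
#' to fit are skipped with a warning and enumerated in the result's
#' `skipped` attribute: a proteome-scale screen must not die on one bad
#' file.
#'
#' @param library one of: a directory containing model files (`.pdb`,
#'   `.ent`, `.cif`, searched recursively, so batched sub-directory layouts
#'   work as-is), a character vector of file paths, or a list of
#'   [atomic_model()]s.
#' @param target a [voxel_grid()].
#' @param params a [fit_params()]; `search = "auto"` means the accelerated
#'   two-stage rotation scan here (see the vignette).
#' @param verbose print one progress line per model.
#' @return a `rank_table` data frame with columns `rank`, `model_id`,
#'   `cc_normalized`, `cc_unnormalized`, `n_atoms`, `mirrored`,
#'   `r11`..`r33` (row-major rotation), `t1`..`t3` (translation,
#'   Angstrom); attributes `params` and `skipped`.
#' @export
scan_library <- function(library, target, params = fit_params(),
                         verbose = FALSE) {
  assert_grid(target)
  stopifnot(inherits(params, "fit_params"))
  if (params$search == "auto") {
    params$search <- "two_stage"
  }
  models <- as_model_source(library)
  if (length(models) == 0L) stop("empty model library")
  rows <- vector("list", length(models))
  skipped <- character()
  for (i in seq_along(models)) {
    entry <- models[[i]]
    res <- tryCatch({
      mod <- if (inherits(entry, "atomic_model")) entry else read_model(entry)
      fit_model(target, mod, params)
    }, error = function(e) e)
    label <- if (inherits(entry, "atomic_model")) entry$model_id
             else as.character(entry)
    if (inherits(res, "error")) {
      warning(sprintf("skipping model '%s': %s", label,
                      conditionMessage(res)), call. = FALSE)
      skipped <- c(skipped, label)
      next
    }
    if (verbose)
      message(sprintf("  %-30s CC %.4f", res$model_id, res$cc_normalized))
    R <- res$pose$rotation
    rows[[i]] <- data.frame(
      model_id = res$model_id, cc_normalized = res$cc_normalized,
      cc_unnormalized = res$cc_unnormalized, n_atoms = res$n_atoms,
      mirrored = res$mirrored,
      r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
      r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
      r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
      t1 = res$pose$translation[1], t2 = res$pose$translation[2],
      t3 = res$pose$translation[3], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no model in the library could be scored")
  tab <- do.call(rbind, rows)
  ord <- order(-tab$cc_normalized, -tab$cc_unnormalized, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  structure(tab, class = c("rank_table", "data.frame"),
            params = params, skipped = skipped)
}

## Normalize the three accepted library forms into a list of models/paths.
as_model_source <- function(library) {
  if (is.list(library) &&
      all(vapply(library, inherits, logical(1), "atomic_model")))
    return(library)
  if (is.character(library) && length(library) == 1L &&
      dir.exists(library)) {
    files <- list.files(library, pattern = "\\.(pdb|ent|cif)$",
                        full.names = TRUE, recursive = TRUE,
                        ignore.case = TRUE)
    return(as.list(sort(files)))
  }
  if (is.character(library)) {
    missing <- library[!file.exists(library)]
    if (length(library) && length(missing) == length(library))
      stop("none of the given model files exist")
    return(as.list(library))
  }
  stop("'library' must be a directory, file paths, or a list of atomic_models")
}

#' Keep the top hits of a rank table
#'
#' @param table a `rank_table` from [scan_library()].
#' @param n number of rows to keep (the protocol inspected the top 200
#'   hits individually); if larger than the table, the full table is
#'   returned.
#' @return the truncated `rank_table`, ranks preserved.
#' @export
top_hits <- function(table, n) {
  stopifnot(inherits(table, "rank_table"), is.numeric(n), length(n) == 1L,
            n >= 1)
  out <- table[seq_len(min(n, nrow(table))), , drop = FALSE]
  structure(out, class = class(table), params = attr(table, "params"),
            skipped = attr(table, "skipped"))
}

#' Rank of a known control in a library screen
#'
#' Screens the library and returns the 1-based rank of the expected model —
#' the positive-control validation of the matching workflow (known
#' single-domain and multi-domain proteins must come up as top hits).
#'
#' @param target a [voxel_grid()].
#' @param library as in [scan_library()].
#' @param expected_id the model id that should win.
#' @param params a [fit_params()].
#' @param k rank threshold for the `passed` attribute (default 1: the
#'   control must be the best hit).
#' @return integer rank of `expected_id`, with attributes `passed`
#'   (`rank <= k`) and `table` (the full `rank_table`).
#' @export
validate_control <- function(target, library, expected_id,
                             params = fit_params(), k = 1L) {
  tab <- scan_library(library, target, params)
  hit <- which(tab$model_id == expected_id)
  if (length(hit) == 0L)
    stop(sprintf("expected model '%s' is not in the library", expected_id))
  rank <- as.integer(tab$rank[hit[1]])
  structure(rank, passed = rank <= k, table = tab)
}

#' Relative occupancy of a feature between two maps
#'
#' Quantifies how strongly a feature is occupied in map B relative to map
#' A, normalizing each map by a reference region (e.g. tubulin density) so
#' that global scale differences between reconstructions cancel:
#' `(mean_B(feature) / mean_B(reference)) / (mean_A(feature) /
#' mean_A(reference))`. Mask means (not integrals) are used, so the two
#' masks may contain different voxel counts. A value of 0.3 means the
#' feature retains 30% of its reference-normalized density in map B — the
#' quantitative form of comparing wild-type and knockout averages.
#'
#' @param map_a,map_b [voxel_grid()]s on the same frame (pre-aligned).
#' @param feature_mask,reference_mask [voxel_grid()]s on the same frame;
#'   voxels with value > 0 belong to the mask.
#' @return the occupancy ratio (dimensionless).
#' @export
occupancy_ratio <- function(map_a, map_b, feature_mask, reference_mask) {
  assert_same_frame(map_a, map_b)
  assert_same_frame(map_a, feature_mask)
  assert_same_frame(map_a, reference_mask)
  fm <- feature_mask$values > 0
  rm_ <- reference_mask$values > 0
  if (!any(fm)) stop("feature mask is empty")
  if (!any(rm_)) stop("reference mask is empty")
  ra <- mean(map_a$values[fm]) / mean(map_a$values[rm_])
  rb <- mean(map_b$values[fm]) / mean(map_b$values[rm_])
  rb / ra
}

#' Write a rank table as TSV
#'
#' Fixed column order, poses serialized as 12 numbers (row-major rotation
#' plus translation), fitting parameters echoed as leading comment lines.
#'
#' @param table a `rank_table` from [scan_library()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rank_table <- function(table, path) {
  stopifnot(inherits(table, "rank_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty rank table")
  p <- attr(table, "params")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# denscan rank table"),
    sprintf("# resolution=%g cutoff=%g step_deg=%g mode=%s mirror=%s search=%s",
            p$resolution, p$cutoff, p$step_deg, p$mode, p$mirror, p$search),
    sprintf("# skipped=%d", length(attr(table, "skipped")))), con)
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rank table written by [write_rank_table()]
#'
#' @param path TSV path.
#' @return a `rank_table` data frame; the echoed parameter line is parsed
#'   back into the `params` attribute.
#' @export
read_rank_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  params <- NULL
  pl <- grep("resolution=", meta, value = TRUE)
  if (length(pl) == 1L) {
    kv <- regmatches(pl, gregexpr("[a-z_]+=[^ ]+", pl))[[1]]
    vals <- sub("^[a-z_]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    params <- fit_params(
      resolution = as.numeric(vals[["resolution"]]),
      step_deg = as.numeric(vals[["step_deg"]]),
      cutoff = as.numeric(vals[["cutoff"]]),
      mode = vals[["mode"]],
      mirror = as.logical(vals[["mirror"]]),
      search = vals[["search"]])
  }
  structure(tab, class = c("rank_table", "data.frame"), params = params,
            skipped = character())
}

#' @export
print.rank_table <- function(x, n = 10L, ...) {
  p <- attr(x, "params")
  cat(sprintf("<rank_table> %d models ranked", nrow(x)))
  if (!is.null(p))
    cat(sprintf(" (res %g A, step %g deg, cutoff %g, %s)",
                p$resolution, p$step_deg, p$cutoff, p$mode))
  cat("\n")
  print.data.frame(utils::head(
    as.data.frame(x)[, c("rank", "model_id", "cc_normalized",
                         "cc_unnormalized", "n_atoms")], n),
    row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  sk <- attr(x, "skipped")
  if (length(sk)) cat(sprintf("  skipped: %s\n", paste(sk, collapse = ", ")))
  invisible(x)
}
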