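#' Fourier shell correlation between two maps
#'
#' Computes, per concentric Fourier shell, the normalized correlation
#' `Re(sum(Fa * Conj(Fb))) / sqrt(sum(|Fa|^2) * sum(|Fb|^2))` between two
#' commensurate maps. Shell width is one Fourier voxel, `1/(n * voxel_size)`
#' with `n` the largest grid dimension. The conventional resolution estimate
#' is the first crossing of the curve below a threshold (0.143 for
#' independently refined half maps); see [resolution_at()].
#'
#' @param grid_a,grid_b [voxel_grid()]s with identical dims and voxel size.
#' @param threshold threshold stored with the curve (default 0.143).
#' @return an `fsc_curve`: data frame with columns `freq` (shell center,
#'   1/Angstrom) and `fsc`, plus attributes `threshold` and `shell_width`.
#' @export
fsc <- function(grid_a, grid_b, threshold = 0.143) {
  assert_same_frame(grid_a, grid_b)
  d <- grid_dims(grid_a)
  fa <- stats::fft(grid_a$values)
  fb <- stats::fft(grid_b$values)
  k <- fourier_freq_grid(d, grid_a$voxel_size)
  dk <- 1 / (max(d) * grid_a$voxel_size)
  shell <- as.integer(round(k / dk))
  kmax <- floor(min(d) / 2)            # stop at the tightest Nyquist shell
  keep <- shell <= kmax
  idx <- shell[keep] + 1L
  num <- as.numeric(rowsum(Re(fa[keep] * Conj(fb[keep])), idx))
  pa  <- as.numeric(rowsum(Mod(fa[keep])^2, idx))
  pb  <- as.numeric(rowsum(Mod(fb[keep])^2, idx))
  den <- sqrt(pa * pb)
  val <- ifelse(den > 0, num / den, 0)
  curve <- data.frame(freq = (seq_along(val) - 1L) * dk, fsc = val)
  structure(curve, class = c("fsc_curve", "data.frame"),
            threshold = threshold, shell_width = dk)
}

#' Resolution at an FSC threshold
#'
#' Returns the resolution (Angstrom) at which an FSC curve first drops
#' below the threshold, using linear interpolation between the two shells
#' that bracket the crossing. If the curve never drops below the threshold
#' the Nyquist-limited resolution of the last shell is returned with a
#' warning.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold correlation threshold; defaults to the curve's stored
#'   threshold (0.143 unless overridden).
#' @return resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (is.null(threshold)) threshold <- attr(curve, "threshold")
  below <- which(curve$fsc < threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) {
    warning("FSC never drops below the threshold; returning the last shell")
    return(1 / curve$freq[nrow(curve)])
  }
  i <- below[1]
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  c0 <- curve$fsc[i - 1];  c1 <- curve$fsc[i]
  kc <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
  1 / kc
}

#' Write an FSC curve as two-column TSV
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param path output path; columns are spatial frequency (1/Angstrom) and
#'   correlation.
#' @return invisibly, `path`.
#' @export
write_fsc <- function(curve, path) {
  stopifnot(inherits(curve, "fsc_curve"))
  utils::write.table(curve[, c("freq", "fsc")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
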