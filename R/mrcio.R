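## MRC2014 / CCP4 volume input and output.
##
## Only the fields the matching workflow needs are interpreted: dimensions,
## data mode, cell size (voxel size = cella / m[xyz]), axis-order words
## (mapc/mapr/maps), and the MRC2014 ORIGIN record (words 50-52, Angstrom).
## The nstart words are read but deliberately ignored: the ORIGIN record is
## the single authoritative frame anchor here, so poses are unambiguous.
## Volumes are written little-endian, mode 2 (IEEE float32), x fastest.

MRC_HEADER_BYTES <- 1024L

read_mrc_header <- function(con, endian) {
  ints <- function(n) readBin(con, "integer", n = n, size = 4L, endian = endian)
  flts <- function(n) readBin(con, "double", n = n, size = 4L, endian = endian)
  h <- list()
  h$dims   <- ints(3)             # nx (columns, fastest), ny, nz
  h$mode   <- ints(1)
  h$nstart <- ints(3)
  h$m      <- ints(3)             # sampling along cell axes
  h$cella  <- flts(3)             # cell dimensions, Angstrom
  h$cellb  <- flts(3)
  h$mapcrs <- ints(3)             # which axis is columns / rows / sections
  h$dstats <- flts(3)             # dmin dmax dmean
  h$ispg   <- ints(1)
  h$nsymbt <- ints(1)
  invisible(ints(25))             # extra space incl. EXTTYP/NVERSION
  h$origin <- flts(3)             # MRC2014 ORIGIN, Angstrom
  h$map    <- readBin(con, "raw", n = 4L)
  h$machst <- readBin(con, "raw", n = 4L)
  h$rms    <- flts(1)
  h$nlabl  <- ints(1)
  invisible(readBin(con, "raw", n = 800L))
  h
}

#' Read a density volume (MRC2014/CCP4)
#'
#' Reads a 3D map in MRC2014/CCP4 format into a [voxel_grid()]. The axis
#' order is normalized to the canonical internal layout (x fastest)
#' regardless of the header's mapc/mapr/maps permutation. The voxel size is
#' taken as `cella / m` and must be isotropic; the MRC2014 ORIGIN record
#' becomes the grid origin, while the nstart words are ignored.
#'
#' @param path path to an MRC/CCP4 file with floating-point data (mode 2).
#' @return a [voxel_grid()].
#' @seealso [write_density()]
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) < MRC_HEADER_BYTES)
    stop("not an MRC2014 file: shorter than the 1024-byte header")
  con <- file(path, "rb"); on.exit(close(con))
  h <- read_mrc_header(con, "little")
  endian <- "little"
  is_map <- function(hh) identical(hh$map[1:3], charToRaw("MAP"))
  if (!is_map(h)) {
    ## retry as big-endian before giving up on the magic word
    seek(con, 0L)
    h2 <- read_mrc_header(con, "big")
    if (is_map(h2)) {
      h <- h2; endian <- "big"
    } else {
      stop("not an MRC2014 file: missing 'MAP ' magic word")
    }
  }
  if (!identical(h$mode, 2L))
    stop(sprintf("unsupported MRC mode %d: only float32 (mode 2) volumes are supported",
                 h$mode))
  if (any(h$dims < 1L) || any(h$dims > 1e5))
    stop("invalid MRC header field nx/ny/nz")
  if (any(h$m < 1L)) stop("invalid MRC header field mx/my/mz")
  vsz <- h$cella / h$m
  if (any(!is.finite(vsz)) || any(vsz <= 0))
    stop("invalid MRC header field cella: non-positive voxel size")
  if (diff(range(vsz)) > 1e-3 * mean(vsz))
    stop(sprintf("anisotropic voxel size in header field cella/m: %g %g %g",
                 vsz[1], vsz[2], vsz[3]))
  if (!all(sort(h$mapcrs) == 1:3))
    stop("invalid MRC header field mapc/mapr/maps")
  n <- prod(h$dims)
  vals <- readBin(con, "double", n = n, size = 4L, endian = endian)
  if (length(vals) < n) stop("truncated MRC data block")
  if (!all(is.finite(vals))) stop("MRC data block contains non-finite values")
  ## File layout: dims are (n_columns, n_rows, n_sections); mapcrs says which
  ## physical axis each of those is. Permute so physical x is fastest.
  arr <- array(vals, dim = h$dims)
  if (!identical(h$mapcrs, 1:3)) {
    perm <- match(1:3, h$mapcrs)   # position of physical axis among file axes
    arr <- aperm(arr, perm)
  }
  voxel_grid(arr, voxel_size = mean(vsz), origin = h$origin)
}

#' Write a density volume (MRC2014)
#'
#' Writes a [voxel_grid()] as a little-endian MRC2014 volume, data mode 2
#' (IEEE float32), x fastest, with `cella = dims * voxel_size` and the grid
#' origin stored in the MRC2014 ORIGIN record. [read_density()] inverts it
#' exactly for float32-representable values.
#'
#' @param grid a [voxel_grid()]; all values must be finite.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_density <- function(grid, path) {
  assert_grid(grid)
  if (!all(is.finite(grid$values)))
    stop("refusing to write non-finite voxel values")
  d <- grid_dims(grid)
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.numeric(grid$values)
  wi(d)                                  # nx ny nz
  wi(2L)                                 # mode 2: float32
  wi(c(0L, 0L, 0L))                      # nstart (unused; ORIGIN is the anchor)
  wi(d)                                  # mx my mz
  wf(d * grid$voxel_size)                # cella
  wf(c(90, 90, 90))                      # cellb
  wi(1:3)                                # mapc mapr maps: x fastest
  wf(c(min(v), max(v), mean(v)))         # dmin dmax dmean
  wi(1L)                                 # ispg: 3D volume
  wi(0L)                                 # nsymbt
  wi(integer(23L))                       # extra
  writeBin(charToRaw("MRC "), con)       # EXTTYP
  wi(20140L)                             # NVERSION
  wf(grid$origin)                        # ORIGIN (Angstrom)
  writeBin(charToRaw("MAP "), con)       # magic
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))                       # rms
  wi(1L)                                 # nlabl
  lab <- sprintf("%-80s", "denscan")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  wf(v)
  invisible(path)
}
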