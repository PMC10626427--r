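#' Density volume on a regular voxel grid
#'
#' A 3D scalar field with a physical voxel size. Voxel indexing is 0-based
#' in all physical-coordinate formulas (voxel (0,0,0) sits at the origin
#' corner); R's 1-based array indexing is converted internally.
#'
#' @param grid 3D numeric array; every side must be >= 16 voxels. Boxes need
#'   not be cubic (elongated boxes are natural for long filaments), but the
#'   symmetry-search operations expect equal x and y extents.
#' @param apix Voxel size in Angstrom (> 0); the bin4 tomogram default
#'   is 11.81 A/voxel.
#' @return Object of class `density_volume` with elements `grid` and `apix`.
#' @export
density_volume <- function(grid, apix = 11.81) {
  if (!(is.array(grid) && length(dim(grid)) == 3L))
    stop("grid must be a 3D array")
  if (any(dim(grid) < 16L)) stop("every box side must be >= 16 voxels")
  if (!(is.numeric(apix) && length(apix) == 1L && apix > 0))
    stop("apix must be a positive scalar (Angstrom/voxel)")
  structure(list(grid = grid, apix = apix), class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density volume: %d x %d x %d voxels at %.3f A/voxel (%.1f x %.1f x %.1f A)\n",
              d[1], d[2], d[3], x$apix, d[1] * x$apix, d[2] * x$apix, d[3] * x$apix))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' Read an MRC density map (mode 2, 32-bit float)
#'
#' Parses the 1024-byte MRC2014 header and the float32 data block. The
#' voxel size is taken from the cell dimensions divided by the sampling
#' grid. Only mode-2 maps with the standard column/row/section axis order
#' are accepted; anything else raises an error naming the offending field.
#'
#' @param path Path to an MRC file.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  if (length(hdr_int) < 10L)
    stop("truncated MRC file: incomplete 1024-byte header")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (header field MODE): only mode 2 float32", mode))
  if (any(c(nx, ny, nz) <= 0))
    stop("invalid MRC dimensions (header fields NX/NY/NZ)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("non-standard axis order (header fields MAPC/MAPR/MAPS)")
  if (mx <= 0 || cella[1] <= 0)
    stop("missing voxel size (header fields MX / CELLA)")
  apix <- cella[1] / mx
  seek(con, 1024 + nsymbt)
  n <- as.double(nx) * ny * nz
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) < n)
    stop(sprintf("truncated MRC data block: expected %d voxels, got %d", n, length(vals)))
  density_volume(array(vals, dim = c(nx, ny, nz)), apix = apix)
}

#' Write a density volume as MRC (mode 2)
#'
#' @param vol A [density_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * vol$apix)           # cella (A)
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(vol$grid), max(vol$grid), mean(vol$grid)))  # dmin dmax dmean
  wi(c(0L, 0L))              # ispg nsymbt
  wi(integer(25L))           # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)     # machst little-endian
  wf(stats::sd(vol$grid))    # rms
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(vol$grid), con, size = 4L, endian = "little")
  invisible(path)
}
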