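# Minimal MRC2014 I/O (mode 2, 32-bit float, cubic volumes).
# The header layout follows the MRC2014 standard: 256 4-byte words, with
# nx/ny/nz, mode, cell dimensions, axis order, density statistics, the
# "MAP " tag and a machine stamp, followed by the voxel data in
# column-major order (x fastest), which matches R's array linearization.

#' Read an MRC density map
#'
#' Reads an MRC2014 mode-2 (32-bit float) volume. Only cubic volumes are
#' supported; the voxel size is taken as `cella_x / mx`. Malformed headers
#' and truncated files raise errors rather than returning corrupt data.
#'
#' @param path path to a `.mrc` file.
#' @return A [map3d] object.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fsize <- file.info(path)$size
  if (fsize < 1024) stop("truncated MRC file (incomplete header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                       # nxstart, nystart, nzstart (ignored)
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                       # cellb
  mapcrs <- ri(3)
  rf(3)                       # dmin, dmax, dmean
  ri(1)                       # ispg
  nsymbt <- ri(1)
  readBin(con, "raw", 100)    # extra words 25-49
  rf(3)                       # origin
  maptag <- rawToChar(readBin(con, "raw", 4))
  if (maptag != "MAP ")
    stop("malformed MRC header (missing 'MAP ' tag): ", path)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)")
  if (any(nxyz <= 0) || any(mxyz <= 0))
    stop("malformed MRC header (non-positive dimensions)")
  if (nxyz[1] != nxyz[2] || nxyz[1] != nxyz[3])
    stop("non-cubic MRC volume (", paste(nxyz, collapse = "x"),
         ") is not supported")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order mapc/mapr/maps = ",
         paste(mapcrs, collapse = "/"))
  n <- nxyz[1]
  voxel <- cella[1] / mxyz[1]
  if (!is.finite(voxel) || voxel <= 0)
    stop("malformed MRC header (cell size implies voxel size ", voxel, ")")
  nvox <- as.numeric(n)^3
  if (fsize < 1024 + nsymbt + 4 * nvox)
    stop("truncated MRC file (expected ", 1024 + nsymbt + 4 * nvox,
         " bytes, found ", fsize, "): ", path)
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("truncated MRC data section: ", path)
  map3d(array(dat, dim = c(n, n, n)), voxel)
}

#' Write an MRC density map
#'
#' Writes a [map3d] as an MRC2014 mode-2 (32-bit float) file with
#' `nx = ny = nz` and `cella` consistent with the voxel size. Densities are
#' stored as 32-bit floats; a map read from an MRC file therefore
#' round-trips bit-exactly, while doubles are rounded once to float
#' precision on first write.
#'
#' @param map a [map3d].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  n <- grid_size(map)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- map$data
  wi(c(n, n, n))                       # nx, ny, nz
  wi(2L)                               # mode 2: float32
  wi(c(0L, 0L, 0L))                    # nxstart
  wi(c(n, n, n))                       # mx, my, mz
  wf(rep(n * map$voxel_size, 3))       # cella (A)
  wf(c(90, 90, 90))                    # cellb
  wi(c(1L, 2L, 3L))                    # mapc, mapr, maps
  wf(c(min(d), max(d), mean(d)))       # dmin, dmax, dmean
  wi(1L)                               # ispg: 3-D volume
  wi(0L)                               # nsymbt
  wi(integer(25))                      # extra
  wf(c(0, 0, 0))                       # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(d)))          # rms
  wi(1L)                               # nlabl
  lab <- charToRaw("icodiff density map")
  writeBin(c(lab, raw(80 - length(lab))), con)
  writeBin(raw(720), con)              # remaining labels
  wf(as.vector(d))
  invisible(path)
}
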