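#' Construct a 3-D density map
#'
#' A `map3d` is the package's universal currency: a cubic grid of real
#' densities together with its physical voxel size. Densities are in
#' arbitrary (relative) units; all statistics downstream are scale-covariant.
#'
#' The rotation/radius center of the grid is the voxel with (1-based) index
#' `floor(N/2) + 1` along each axis, i.e. the voxel a zero-frequency Fourier
#' component maps to. Even grid sizes are supported.
#'
#' @param data numeric 3-D array, cubic (N x N x N), all values finite.
#' @param voxel_size edge length of one voxel in angstrom (> 0).
#' @return An object of class `map3d` with elements `data` and `voxel_size`.
#' @export
map3d <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("grid must be cubic; got ", paste(d, collapse = " x "))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (angstrom)")
  if (anyNA(data) || !all(is.finite(data)))
    stop("all densities must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "map3d")
}

#' @export
print.map3d <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<map3d> %d^3 voxels, %.4g A/voxel (box edge %.4g A)\n",
              n, x$voxel_size, n * x$voxel_size))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Construct a voxel mask
#'
#' @param data logical 3-D array (same grid as its parent map).
#' @param voxel_size voxel edge in angstrom.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3-D array")
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("mask grid must be cubic")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<mask3d> %d^3 voxels, %d selected (%.2f%%)\n",
              n, sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

is_map3d <- function(x) inherits(x, "map3d")
is_mask3d <- function(x) inherits(x, "mask3d")

grid_size <- function(map) dim(map$data)[1]

center_index <- function(n) n %/% 2L + 1L

# coordinates of voxel centers along one axis, in angstrom, relative to the
# grid center voxel
axis_coord <- function(n, voxel_size = 1) {
  (seq_len(n) - center_index(n)) * voxel_size
}

# N^3 array of distances (angstrom) from the grid center voxel
radius_grid <- function(n, voxel_size = 1) {
  x2 <- axis_coord(n, voxel_size)^2
  sqrt(outer(outer(x2, x2, "+"), x2, "+"))
}

# N^3 x 3 matrix of voxel-center coordinates (angstrom, center origin),
# first index fastest -- matches R's array linearization
grid_coords <- function(n, voxel_size = 1) {
  x <- axis_coord(n, voxel_size)
  cbind(rep(x, times = n * n),
        rep(rep(x, each = n), times = n),
        rep(x, each = n * n))
}

assert_same_grid <- function(a, b, what = "maps") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " are on different grids: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop(what, " have different voxel sizes: ",
         a$voxel_size, " vs ", b$voxel_size)
  invisible(TRUE)
}

# Trilinear interpolation of a 3-D array at fractional 1-based indices.
# Samples outside the grid take the edge-padding value 0.
interp_trilinear <- function(a, x, y, z) {
  n <- dim(a)[1]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  out <- numeric(length(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) *
         (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & kk >= 1 & kk <= n & w > 0
    if (any(ok)) {
      lin <- ii[ok] + (jj[ok] - 1) * n + (kk[ok] - 1) * n * n
      out[ok] <- out[ok] + w[ok] * a[lin]
    }
  }
  out
}

#' Pixel size implied by film scanning
#'
#' Converts a film-scanner pitch and a microscope magnification to the
#' physical pixel size on the specimen: `pitch * 1e4 / magnification`
#' angstrom (1 um = 1e4 A).
#'
#' @param scan_pitch scanner sampling pitch in micrometre per pixel.
#' @param magnification microscope magnification (dimensionless).
#' @return Pixel size in angstrom.
#' @examples
#' pixel_size_from_scan(14, 48000) # ~2.9 A
#' @export
pixel_size_from_scan <- function(scan_pitch, magnification) {
  if (!is.numeric(scan_pitch) || length(scan_pitch) != 1L || scan_pitch <= 0)
    stop("`scan_pitch` must be a single positive number (um)")
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      magnification <= 0)
    stop("`magnification` must be a single positive number")
  scan_pitch * 1e4 / magnification
}
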