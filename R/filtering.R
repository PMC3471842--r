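# Fourier filtering and frequency-grid helpers.

# signed frequency indices of an FFT of length n (cycles per box)
fft_index <- function(n) {
  half <- n %/% 2
  out <- c(0:half, if (n - half - 1 > 0) (half + 1 - n):(-1))
  out[seq_len(n)]
}

# N^3 array of spatial-frequency magnitudes in 1/A
freq_grid <- function(n, voxel_size) {
  f2 <- (fft_index(n) / (n * voxel_size))^2
  sqrt(outer(outer(f2, f2, "+"), f2, "+"))
}

#' Low-pass filter a map
#'
#' Suppresses spatial frequencies above `1/resolution`. Two roll-offs are
#' available: a raised-cosine edge of full width `edge_width` (1/A) centered
#' on the cutoff frequency (default, avoids ringing in difference maps), and
#' a sharp cutoff. The DC term is always unchanged, so the map mean is
#' preserved, and the output is real-valued.
#'
#' @param map a [map3d].
#' @param resolution target resolution in angstrom; must be at least twice
#'   the voxel size (Nyquist).
#' @param roll_off `"cosine"` (default) or `"sharp"`.
#' @param edge_width full width of the cosine edge in 1/A; default half the
#'   cutoff frequency, i.e. the transfer function is 1 below 0.75/resolution
#'   and 0 above 1.25/resolution.
#' @return The filtered [map3d].
#' @export
low_pass_filter <- function(map, resolution,
                            roll_off = c("cosine", "sharp"),
                            edge_width = NULL) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  roll_off <- match.arg(roll_off)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (angstrom)")
  if (resolution < 2 * map$voxel_size)
    stop(sprintf(
      "resolution %.3g A is below the Nyquist limit %.3g A (2 x voxel size)",
      resolution, 2 * map$voxel_size))
  n <- grid_size(map)
  fc <- 1 / resolution
  f <- freq_grid(n, map$voxel_size)
  if (roll_off == "sharp") {
    transfer <- as.numeric(f <= fc)
  } else {
    if (is.null(edge_width)) edge_width <- 0.5 * fc
    lo <- fc - edge_width / 2
    hi <- fc + edge_width / 2
    transfer <- ifelse(f <= lo, 1,
                ifelse(f >= hi, 0,
                       0.5 * (1 + cos(pi * (f - lo) / edge_width))))
  }
  ft <- stats::fft(map$data) * transfer
  out <- Re(stats::fft(ft, inverse = TRUE)) / n^3
  map3d(array(out, dim = c(n, n, n)), map$voxel_size)
}
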