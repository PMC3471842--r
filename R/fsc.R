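# Fourier shell correlation and resolution at a cutoff.

#' Fourier shell correlation between two maps
#'
#' For each spherical shell `s` in frequency space,
#' `FSC(s) = Re sum(Fa * conj(Fb)) / sqrt(sum|Fa|^2 * sum|Fb|^2)` over the
#' Fourier voxels in the shell. Shells are assigned by nearest-integer
#' radius in frequency voxels (or `n_shells` uniform bins up to Nyquist);
#' voxel counts are recorded so degenerate shells are detectable. Shells
#' with zero power in either map report `NA`.
#'
#' @param a,b [map3d] objects on identical grids with equal voxel sizes.
#' @param n_shells optional number of uniform shells up to Nyquist; default
#'   one shell per integer frequency voxel (`N/2` shells).
#' @return An object of class `fsc_curve`: list with `frequencies` (1/A,
#'   strictly increasing, bounded by Nyquist), `correlations` (in [-1, 1])
#'   and `shell_voxel_counts`.
#' @export
fsc_curve <- function(a, b, n_shells = NULL) {
  if (!is_map3d(a) || !is_map3d(b)) stop("`a` and `b` must be map3d objects")
  assert_same_grid(a, b)
  n <- grid_size(a)
  half <- n %/% 2
  if (is.null(n_shells)) n_shells <- half
  if (n_shells < 1 || n_shells > half)
    stop("`n_shells` must be between 1 and N/2")
  width <- half / n_shells                 # frequency voxels per shell
  k2 <- fft_index(n)^2
  rv <- sqrt(outer(outer(k2, k2, "+"), k2, "+"))
  s <- as.integer(round(rv / width))
  keep <- s >= 1L & s <= n_shells
  s <- s[keep]
  fa <- stats::fft(a$data)[keep]
  fb <- stats::fft(b$data)[keep]
  num <- Re(fa * Conj(fb))
  pa <- Re(fa * Conj(fa))
  pb <- Re(fb * Conj(fb))
  agg <- rowsum(cbind(num, pa, pb), s)
  shells <- as.integer(rownames(agg))
  counts <- integer(n_shells)
  counts[shells] <- tabulate(s, nbins = n_shells)[shells]
  nums <- pas <- pbs <- numeric(n_shells)
  nums[shells] <- agg[, 1]; pas[shells] <- agg[, 2]; pbs[shells] <- agg[, 3]
  denom <- sqrt(pas * pbs)
  corr <- ifelse(denom > 0, nums / denom, NA_real_)
  corr <- pmin(1, pmax(-1, corr))          # guard FP round-off
  structure(list(
    frequencies = seq_len(n_shells) * width / (n * a$voxel_size),
    correlations = corr,
    shell_voxel_counts = counts,
    voxel_size = a$voxel_size,
    grid_size = n
  ), class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to Nyquist %.4g 1/A\n",
              length(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Resolution at an FSC cutoff
#'
#' The resolution is `1/f*`, where `f*` is the first frequency at which the
#' curve crosses below the cutoff, linearly interpolated between shells.
#' A curve that never falls below the cutoff yields `crossed = FALSE` with
#' `resolution = NA` ("better than Nyquist"); a curve already below the
#' cutoff at its first defined shell is an error.
#'
#' @param curve an [fsc_curve()].
#' @param cutoff correlation cutoff in (-1, 1); 0.5 is the conventional
#'   value for maps reconstructed from the same full data set.
#' @return An object of class `fsc_resolution`: list with `resolution` (A),
#'   `frequency` (1/A) and `crossed`.
#' @export
resolution_at_cutoff <- function(curve, cutoff = 0.5) {
  if (!inherits(curve, "fsc_curve")) stop("`curve` must be an fsc_curve")
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= -1 || cutoff >= 1)
    stop("`cutoff` must be a single value in (-1, 1)")
  ok <- !is.na(curve$correlations)
  f <- curve$frequencies[ok]
  c_ <- curve$correlations[ok]
  if (length(c_) == 0) stop("FSC curve has no defined shells")
  below <- which(c_ < cutoff)
  if (length(below) == 0) {
    return(structure(list(resolution = NA_real_, frequency = NA_real_,
                          crossed = FALSE,
                          note = "curve never falls below the cutoff; resolution better than the Nyquist limit"),
                     class = "fsc_resolution"))
  }
  i <- below[1]
  if (i == 1L)
    stop("FSC is already below the cutoff at the first shell; ",
         "maps share no resolved signal")
  f1 <- f[i - 1]; f2 <- f[i]
  c1 <- c_[i - 1]; c2 <- c_[i]
  fstar <- f1 + (c1 - cutoff) / (c1 - c2) * (f2 - f1)
  structure(list(resolution = 1 / fstar, frequency = fstar, crossed = TRUE),
            class = "fsc_resolution")
}

#' @export
print.fsc_resolution <- function(x, ...) {
  if (x$crossed) {
    cat(sprintf("<fsc_resolution> %.3g A (crossing at %.4g 1/A)\n",
                x$resolution, x$frequency))
  } else {
    cat("<fsc_resolution>", x$note, "\n")
  }
  invisible(x)
}

#' Export an FSC curve as two-column text
#'
#' Writes `frequency` (1/A) and `fsc` columns, tab-separated, suitable for
#' plotting.
#'
#' @param curve an [fsc_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fsc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fsc_curve"))
  utils::write.table(
    data.frame(frequency = curve$frequencies, fsc = curve$correlations),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
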