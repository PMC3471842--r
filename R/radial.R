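# Radial (spherical-shell) statistics and radial scaling.

#' Radial average of a map
#'
#' Bins voxels by the distance of their centers from the grid center voxel
#' into contiguous shells `[i*w, (i+1)*w)` of width `w` voxels, and reports
#' the per-shell mean density, optionally restricted to a mask. Empty shells
#' report `NA`, never 0.
#'
#' @param map a [map3d].
#' @param mask optional [mask3d] on the same grid.
#' @param shell_width shell width in voxels (default 1).
#' @return An object of class `radial_profile`: list with `shell_centers`
#'   (angstrom), `means`, `counts`, plus the `shell_width` (voxels) and
#'   `voxel_size` used.
#' @export
radial_average <- function(map, mask = NULL, shell_width = 1) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  if (!is.numeric(shell_width) || shell_width <= 0)
    stop("`shell_width` must be positive (voxels)")
  n <- grid_size(map)
  r <- radius_grid(n, 1)                    # voxel units
  bin <- as.integer(floor(r / shell_width)) # 0-based
  nb <- max(bin) + 1L
  sel <- if (is.null(mask)) {
    TRUE
  } else {
    if (!is_mask3d(mask)) stop("`mask` must be a mask3d")
    if (!identical(dim(mask$data), dim(map$data)))
      stop("mask grid does not match the map grid")
    as.vector(mask$data)
  }
  vals <- as.vector(map$data)
  if (is.logical(sel) && length(sel) > 1) {
    vals <- vals[sel]
    bing <- bin[sel]
  } else {
    bing <- as.vector(bin)
  }
  counts <- tabulate(bing + 1L, nbins = nb)
  sums <- numeric(nb)
  if (length(vals)) {
    agg <- rowsum(vals, bing)
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(
    shell_centers = (seq_len(nb) - 0.5) * shell_width * map$voxel_size,
    means = means,
    counts = counts,
    shell_width = shell_width,
    voxel_size = map$voxel_size
  ), class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d shells of %.3g voxel(s), %d voxels binned\n",
              length(x$means), x$shell_width, sum(x$counts)))
  invisible(x)
}

#' Apply per-shell radial scale factors
#'
#' Multiplies every voxel of `target` by
#' `reference_profile$means[shell] / target_profile$means[shell]` for the
#' shell the voxel falls in. Shells whose target mean is undefined (`NA`) or
#' smaller in magnitude than `epsilon` get factor 1, as do radii beyond the
#' profiles. The default `epsilon` is `1e-6` times the global density
#' standard deviation of the target map.
#'
#' @param target the [map3d] to rescale.
#' @param reference_profile,target_profile [radial_average()] profiles on
#'   the same shell grid (typically masked to the main shell of each map).
#' @param epsilon near-zero guard for target shell means.
#' @return The rescaled [map3d], with the per-shell factors attached as
#'   attribute `"radial_factors"`.
#' @export
radial_scale <- function(target, reference_profile, target_profile,
                         epsilon = NULL) {
  if (!is_map3d(target)) stop("`target` must be a map3d")
  for (p in list(reference_profile, target_profile))
    if (!inherits(p, "radial_profile"))
      stop("profiles must come from radial_average()")
  if (length(reference_profile$means) != length(target_profile$means) ||
      max(abs(reference_profile$shell_centers -
              target_profile$shell_centers)) > 1e-6)
    stop("reference and target profiles are on different shell grids")
  if (abs(target_profile$voxel_size - target$voxel_size) >
      1e-6 * target$voxel_size ||
      abs(target_profile$shell_width * target$voxel_size -
          2 * target_profile$shell_centers[1]) > 1e-6)
    stop("target profile was not computed on this map's grid")
  if (is.null(epsilon)) epsilon <- 1e-6 * stats::sd(as.vector(target$data))
  factors <- reference_profile$means / target_profile$means
  bad <- !is.finite(factors) | abs(target_profile$means) < epsilon
  factors[bad] <- 1
  n <- grid_size(target)
  r <- radius_grid(n, 1)
  bin <- as.integer(floor(r / target_profile$shell_width)) + 1L
  fac_of_bin <- c(factors, rep(1, max(0, max(bin) - length(factors))))
  out <- target$data * array(fac_of_bin[bin], dim = dim(target$data))
  res <- map3d(out, target$voxel_size)
  attr(res, "radial_factors") <- factors
  res
}
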