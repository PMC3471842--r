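# Fractional occupancy between background (0%) and the densest shell
# region (100%).

#' Estimate fractional occupancy at a site
#'
#' `occupancy = (site_mean - background_mean) /
#' (p1_reference - background_mean)`, where `p1_reference` is the mean of
#' the top `reference_quantile` fraction of shell-mask densities (the
#' "highest density region" of the fully occupied shell, taken as 100%)
#' and the background annulus is taken as 0%. The ratio of differences
#' makes the estimate invariant under any affine transform applied jointly
#' to the map.
#'
#' The estimator is position-conditional: it measures density inside the
#' supplied site mask only, so protein copies shifted away from the nominal
#' site do not count. Values are deliberately not clipped to [0, 1]; noise
#' can push them slightly outside, and values far outside flag scaling or
#' mask problems (`out_of_range`).
#'
#' @param map a [map3d] (normalized scale recommended).
#' @param site_mask [mask3d] over the candidate protein site (e.g. derived
#'   from a difference map); must be non-empty and disjoint from the
#'   background.
#' @param p1_mask [mask3d] over the fully occupied shell.
#' @param background_mask [mask3d] over the background annulus.
#' @param reference_quantile top fraction of shell densities averaged for
#'   the 100% reference; default 0.01 (robust to single-voxel outliers
#'   while honoring "highest density region").
#' @param reference_map optional [map3d] from which the 100% shell
#'   reference and the background level are read instead of `map`. Use it
#'   when the site density is read from a difference map (where the shell
#'   cancels) while the fully occupied shell lives in the parent map; both
#'   maps must share the normalized scale.
#' @param site_name optional label.
#' @return An object of class `occupancy_estimate`: list with `site_name`,
#'   `occupancy`, `site_mean`, `p1_reference`, `background_mean`,
#'   `out_of_range`.
#' @export
estimate_occupancy <- function(map, site_mask, p1_mask, background_mask,
                               reference_quantile = 0.01,
                               reference_map = NULL, site_name = NULL) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  if (is.null(reference_map)) reference_map <- map
  if (!is_map3d(reference_map)) stop("`reference_map` must be a map3d")
  assert_same_grid(map, reference_map)
  for (m in list(site_mask, p1_mask, background_mask)) {
    if (!is_mask3d(m)) stop("all masks must be mask3d objects")
    if (!identical(dim(m$data), dim(map$data)))
      stop("mask grid does not match the map grid")
    if (!any(m$data)) stop("empty mask")
  }
  if (any(site_mask$data & background_mask$data))
    stop("site mask and background mask overlap")
  if (!is.numeric(reference_quantile) || reference_quantile <= 0 ||
      reference_quantile > 1)
    stop("`reference_quantile` must be in (0, 1]")
  site_mean <- mean(map$data[site_mask$data])
  background_mean <- mean(map$data[background_mask$data])
  ref_background <- mean(reference_map$data[background_mask$data])
  p1_vals <- reference_map$data[p1_mask$data]
  k <- max(1L, ceiling(reference_quantile * length(p1_vals)))
  p1_reference <- mean(sort(p1_vals, decreasing = TRUE)[seq_len(k)])
  if (p1_reference <= ref_background)
    stop("shell reference density does not exceed the background; ",
         "cannot define the 100% level")
  occ <- (site_mean - background_mean) / (p1_reference - ref_background)
  structure(list(site_name = site_name %||% NA_character_,
                 occupancy = occ,
                 site_mean = site_mean,
                 p1_reference = p1_reference,
                 background_mean = background_mean,
                 out_of_range = occ < -0.05 || occ > 1.05),
            class = "occupancy_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy_estimate> %s: %.1f%%%s\n",
              x$site_name, 100 * x$occupancy,
              if (x$out_of_range) "  [out of range]" else ""))
  cat(sprintf("  site %.4g | shell ref %.4g | background %.4g\n",
              x$site_mean, x$p1_reference, x$background_mean))
  invisible(x)
}

#' Site-availability occupancy bound
#'
#' The maximum occupancy compatible with the number of sites that can
#' actually be occupied: `available_sites / total_sites`. The unexpanded
#' procapsid shows density at 20 three-fold polymerase sites but at most 12
#' can be occupied, bounding its polymerase occupancy at 0.6.
#'
#' @param available_sites number of occupiable sites (0..total).
#' @param total_sites total number of symmetry-related sites (> 0).
#' @return Fraction in [0, 1].
#' @export
max_occupancy <- function(available_sites, total_sites) {
  if (!is.numeric(available_sites) || !is.numeric(total_sites) ||
      length(available_sites) != 1L || length(total_sites) != 1L)
    stop("inputs must be single numbers")
  if (total_sites <= 0) stop("`total_sites` must be positive")
  if (available_sites < 0 || available_sites > total_sites)
    stop("`available_sites` must be between 0 and `total_sites`")
  available_sites / total_sites
}
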