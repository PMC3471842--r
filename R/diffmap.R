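# Difference-map arithmetic and axis-constrained site detection.

#' Subtract two normalized maps
#'
#' Voxelwise `a - b`. Both maps should come from one normalized set so the
#' difference is in units of the common standard deviation; positive
#' density marks mass present in the minuend only.
#'
#' @param a,b [map3d] objects on the same grid (minuend, subtrahend).
#' @param names optional character(2) with the map names for provenance.
#' @return An object of class `difference_map`: list with `data` (a
#'   [map3d]), `minuend_name`, `subtrahend_name`.
#' @export
subtract_maps <- function(a, b, names = c("a", "b")) {
  if (!is_map3d(a) || !is_map3d(b)) stop("`a` and `b` must be map3d objects")
  assert_same_grid(a, b)
  structure(list(data = map3d(a$data - b$data, a$voxel_size),
                 minuend_name = names[1], subtrahend_name = names[2]),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %s - %s\n", x$minuend_name,
              x$subtrahend_name))
  print(x$data)
  invisible(x)
}

.diff_data <- function(x) {
  if (inherits(x, "difference_map")) x$data else x
}

#' Shell-plus-packaging-motor composite map
#'
#' Voxelwise `p124 + p147 - p1247`: subtracting the complete-particle map
#' from the sum of the two single-deletion maps cancels the proteins unique
#' to each deletion and leaves the components common to all three (the
#' shell and, at its residual occupancy, the five-fold vertex density).
#' Together with the two difference maps it satisfies the exact
#' decomposition `(p1247-p124) + (p1247-p147) + (p124+p147-p1247) = p1247`.
#'
#' @param p124,p147,p1247 [map3d] objects on one normalized grid.
#' @return A [map3d].
#' @export
composite_p14 <- function(p124, p147, p1247) {
  for (m in list(p124, p147, p1247))
    if (!is_map3d(m)) stop("inputs must be map3d objects")
  assert_same_grid(p124, p147)
  assert_same_grid(p124, p1247)
  map3d(p124$data + p147$data - p1247$data, p124$voxel_size)
}

#' Detect density sites at symmetry-axis directions
#'
#' For each axis direction, finds the maximum-density voxel inside a
#' cylinder of radius `cylinder_radius` about the axis, restricted to the
#' radial band `[r_min, r_max]` (angstrom from the particle center) and to
#' the hemisphere of that direction. A voxel lying inside several cylinders
#' is assigned to the axis with the smaller angular distance; ambiguities
#' below 1 degree raise a warning. An axis is reported as a detected site
#' iff its peak reaches `threshold * sigma`.
#'
#' `sigma` defaults to the standard deviation of the whole difference map,
#' so `threshold = 2` reproduces the conventional 2-sigma isosurface
#' contour level of a difference map. Pass `sigma = 1` to use absolute
#' (normalized-set) units.
#'
#' @param diff a `difference_map` or [map3d].
#' @param axes an `axis_set` from [axis_directions()].
#' @param radial_band numeric c(r_min, r_max) in angstrom, non-empty,
#'   inside the grid.
#' @param threshold detection threshold in multiples of `sigma`.
#' @param cylinder_radius search cylinder radius in angstrom; default
#'   0.15 * r_max.
#' @param sigma reference standard deviation; default `sd` of the map.
#' @return A data.frame of class `site_detection` with one row per axis
#'   direction: direction components, peak position (A from center), peak
#'   coordinates (`peak_x/y/z`, A -- peaks may sit off the axis, e.g. a
#'   ring of subunits around it), peak value (map units) and in sigma
#'   multiples, integrated density above threshold (map units x nm^3), and
#'   `detected`. The threshold and sigma used are attached as attributes.
#' @export
detect_axis_sites <- function(diff, axes, radial_band, threshold = 2,
                              cylinder_radius = NULL, sigma = NULL) {
  map <- .diff_data(diff)
  if (!is_map3d(map)) stop("`diff` must be a difference_map or map3d")
  if (!inherits(axes, "axis_set")) stop("`axes` must be an axis_set")
  n <- grid_size(map)
  half_edge <- n * map$voxel_size / 2
  if (length(radial_band) != 2L || radial_band[1] >= radial_band[2] ||
      radial_band[1] < 0)
    stop("`radial_band` must be c(r_min, r_max) with 0 <= r_min < r_max")
  if (radial_band[1] > sqrt(3) * half_edge)
    stop("radial band lies entirely outside the grid")
  if (is.null(cylinder_radius)) cylinder_radius <- 0.15 * radial_band[2]
  if (is.null(sigma)) sigma <- stats::sd(as.vector(map$data))
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  thr <- threshold * sigma

  r <- as.vector(radius_grid(n, map$voxel_size))
  in_band <- r >= radial_band[1] & r <= radial_band[2]
  co <- grid_coords(n, map$voxel_size)[in_band, , drop = FALSE]
  vals <- as.vector(map$data)[in_band]
  rb <- r[in_band]
  dirs <- axes$directions
  ax <- co %*% t(dirs)                       # axial components, m x K
  best <- max.col(ax, ties.method = "first")
  # angular ambiguity: second-nearest axis within 1 degree of the nearest
  m <- nrow(ax)
  cosang <- ax / pmax(rb, 1e-12)
  top1 <- cosang[cbind(seq_len(m), best)]
  tmp <- cosang
  tmp[cbind(seq_len(m), best)] <- -Inf
  top2 <- do.call(pmax, as.data.frame(tmp))
  amb <- (acos(pmin(1, top2)) - acos(pmin(1, pmax(-1, top1)))) < pi / 180
  voxvol <- (map$voxel_size / 10)^3
  rows <- vector("list", nrow(dirs))
  n_ambig <- 0L
  for (k in seq_len(nrow(dirs))) {
    axial <- ax[, k]
    perp2 <- rb^2 - axial^2
    memb <- best == k & axial > 0 & perp2 <= cylinder_radius^2
    if (!any(memb)) {
      rows[[k]] <- data.frame(axis_order = axes$order,
                              dir_x = dirs[k, 1], dir_y = dirs[k, 2],
                              dir_z = dirs[k, 3],
                              peak_position = NA_real_,
                              peak_x = NA_real_, peak_y = NA_real_,
                              peak_z = NA_real_,
                              peak_value = NA_real_, peak_sigma = NA_real_,
                              integrated_density = 0, detected = FALSE)
      next
    }
    v <- vals[memb]
    imax <- which.max(v)
    pk <- co[memb, , drop = FALSE][imax, ]
    n_ambig <- n_ambig + as.integer(amb[memb][imax])
    rows[[k]] <- data.frame(
      axis_order = axes$order,
      dir_x = dirs[k, 1], dir_y = dirs[k, 2], dir_z = dirs[k, 3],
      peak_position = rb[memb][imax],
      peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
      peak_value = v[imax],
      peak_sigma = v[imax] / sigma,
      integrated_density = sum(v[v >= thr]) * voxvol,
      detected = v[imax] >= thr)
  }
  if (n_ambig > 0)
    warning(n_ambig, " peak(s) lie within 1 degree of two axes; ",
            "assigned to the nearer axis")
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "sigma") <- sigma
  attr(out, "cylinder_radius") <- cylinder_radius
  attr(out, "radial_band") <- radial_band
  class(out) <- c("site_detection", "data.frame")
  out
}

#' Number of detected sites
#'
#' @param sites a [detect_axis_sites()] table.
#' @return Integer count of rows with `detected = TRUE`.
#' @export
site_count <- function(sites) {
  stopifnot(inherits(sites, "site_detection"))
  sum(sites$detected)
}

#' Spherical mask around a point
#'
#' Voxels within `radius` of `center` (angstrom coordinates relative to the
#' grid center voxel). An off-grid center yields an empty mask, not an
#' error; such masks separate overlapping features in superimposed
#' difference maps.
#'
#' @param center numeric(3), angstrom from the grid center.
#' @param radius sphere radius in angstrom (> 0).
#' @param grid_like a [map3d] defining the grid.
#' @return A [mask3d].
#' @export
spherical_mask <- function(center, radius, grid_like) {
  if (!is_map3d(grid_like)) stop("`grid_like` must be a map3d")
  if (!is.numeric(center) || length(center) != 3L)
    stop("`center` must be numeric(3) (angstrom)")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number (angstrom)")
  n <- grid_size(grid_like)
  x <- axis_coord(n, grid_like$voxel_size)
  d2 <- outer(outer((x - center[1])^2, (x - center[2])^2, "+"),
              (x - center[3])^2, "+")
  mask3d(d2 <= radius^2, grid_like$voxel_size)
}

#' Export a site table as TSV
#'
#' @param sites a [detect_axis_sites()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  stopifnot(inherits(sites, "site_detection"))
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
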