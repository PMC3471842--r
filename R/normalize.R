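# Intensity normalization: volume-matched thresholding against a protein
# mass budget, background annulus, joint standardization, radial factors.

.avogadro <- 6.02214076e23

#' Expected protein volume from a mass budget
#'
#' `V = copies * (mass * 1e3 / N_A) / density`, converted to nm^3
#' (1 cm^3 = 1e21 nm^3). Used to pick the density threshold whose enclosed
#' volume matches the protein content of a shell, e.g. 120 copies of an
#' 84 kDa shell protein at 1.41 g/cm^3 give about 1.19e4 nm^3.
#'
#' @param mass_kDa molecular mass of one copy in kilodalton.
#' @param copies number of copies in the particle.
#' @param density protein mass density in g/cm^3 (1.41 is the standard
#'   value for globular proteins).
#' @return Expected volume in nm^3.
#' @export
expected_protein_volume <- function(mass_kDa, copies, density = 1.41) {
  for (v in list(mass_kDa, copies, density))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all of `mass_kDa`, `copies`, `density` must be single positive numbers")
  copies * (mass_kDa * 1e3 / .avogadro) / density * 1e21
}

#' Density threshold enclosing a target volume
#'
#' Returns the threshold `t` such that the volume of voxels with density
#' `>= t` is the closest achievable to `target_volume`: the k-th largest
#' density where `k = round(target / voxel_volume)`. The achieved volume is
#' reported alongside (it can differ from the target by up to one voxel
#' volume, more if densities are tied at the threshold).
#'
#' @param map a [map3d].
#' @param target_volume target enclosed volume in nm^3; must be positive
#'   and no larger than the grid volume.
#' @return List with `threshold`, `achieved_volume` (nm^3),
#'   `target_volume` (nm^3) and `voxels` (count at or above threshold).
#' @export
threshold_for_volume <- function(map, target_volume) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  voxvol <- (map$voxel_size / 10)^3          # nm^3
  n3 <- length(map$data)
  total <- n3 * voxvol
  if (!is.numeric(target_volume) || length(target_volume) != 1L ||
      !is.finite(target_volume) || target_volume <= 0)
    stop("`target_volume` must be a single positive number (nm^3)")
  if (target_volume > total)
    stop(sprintf("target volume %.4g nm^3 exceeds the grid volume %.4g nm^3",
                 target_volume, total))
  k <- max(1L, min(n3, as.integer(round(target_volume / voxvol))))
  t <- sort(as.vector(map$data), decreasing = TRUE, method = "quick")[k]
  nvox <- sum(map$data >= t)
  list(threshold = t,
       achieved_volume = nvox * voxvol,
       target_volume = target_volume,
       voxels = nvox)
}

#' Shell mask at a density threshold
#'
#' Voxels with density at or above `threshold`, optionally intersected with
#' a radial band `[r_min, r_max]` (angstrom from the grid center), which is
#' useful to keep internal protein densities reaching the same threshold
#' out of a shell mask.
#'
#' @param map a [map3d].
#' @param threshold finite density threshold.
#' @param radial_band optional numeric length-2 vector `c(r_min, r_max)` in
#'   angstrom.
#' @return A [mask3d]. An empty result triggers a warning, not an error.
#' @export
p1_shell_mask <- function(map, threshold, radial_band = NULL) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    stop("`threshold` must be a single finite number")
  m <- map$data >= threshold
  if (!is.null(radial_band)) {
    if (length(radial_band) != 2L || radial_band[1] > radial_band[2])
      stop("`radial_band` must be c(r_min, r_max) with r_min <= r_max")
    r <- radius_grid(grid_size(map), map$voxel_size)
    m <- m & r >= radial_band[1] & r <= radial_band[2]
  }
  if (!any(m)) warning("shell mask is empty")
  mask3d(m, map$voxel_size)
}

#' Background annulus mask
#'
#' Voxels with `r_inner <= radius < r_outer` from the grid center, used as
#' the density-zero background reference. The annulus must lie strictly
#' inside the box so it excludes both the particle and the apodized
#' boundary of a reconstruction.
#'
#' @param map a [map3d] (defines grid and voxel size).
#' @param r_inner,r_outer annulus radii in angstrom;
#'   `0 < r_inner < r_outer <= half box edge`.
#' @return A [mask3d].
#' @export
background_annulus_mask <- function(map, r_inner, r_outer) {
  if (!is_map3d(map)) stop("`map` must be a map3d")
  half_edge <- grid_size(map) * map$voxel_size / 2
  if (!is.numeric(r_inner) || !is.numeric(r_outer) ||
      length(r_inner) != 1L || length(r_outer) != 1L ||
      r_inner <= 0 || r_outer <= r_inner || r_outer > half_edge + 1e-9)
    stop(sprintf(
      "need 0 < r_inner < r_outer <= %.4g A (half box edge); got [%s, %s]",
      half_edge, format(r_inner), format(r_outer)))
  r <- radius_grid(grid_size(map), map$voxel_size)
  mask3d(r >= r_inner & r < r_outer, map$voxel_size)
}

#' Put a set of maps on a common intensity scale
#'
#' Each map is affinely transformed (`gain * x + offset`, gain > 0) so that
#' over the union of the shared background annulus and the map's own shell
#' mask it has mean 0 and standard deviation 1 (the common reference).
#' Standardizing to 1 makes sigma-based contour thresholds directly
#' interpretable. With `region = "intersection"` the intersection of all
#' shell masks is used instead of each map's own.
#'
#' @param maps named list of [map3d] objects on a common grid.
#' @param p1_masks named list of [mask3d] shell masks, same names as `maps`.
#' @param background_mask shared background [mask3d].
#' @param region `"own"` (default) or `"intersection"`.
#' @return An object of class `normalized_map_set`: list with `maps`
#'   (normalized), `p1_masks`, `background_mask` and `scale_report` (a
#'   data.frame of per-map gain/offset and region size).
#' @export
normalize_set <- function(maps, p1_masks, background_mask,
                          region = c("own", "intersection")) {
  region <- match.arg(region)
  if (!is.list(maps) || is.null(names(maps)) || any(names(maps) == ""))
    stop("`maps` must be a named list of map3d objects")
  nms <- names(maps)
  if (!setequal(nms, names(p1_masks)))
    stop("`p1_masks` must carry the same names as `maps`")
  if (!is_mask3d(background_mask)) stop("`background_mask` must be a mask3d")
  ref <- maps[[1]]
  for (nm in nms) {
    if (!is_map3d(maps[[nm]])) stop("map '", nm, "' is not a map3d")
    assert_same_grid(ref, maps[[nm]])
    if (!identical(dim(p1_masks[[nm]]$data), dim(ref$data)))
      stop("mask '", nm, "' does not match the map grid")
  }
  if (!identical(dim(background_mask$data), dim(ref$data)))
    stop("background mask does not match the map grid")
  inter <- NULL
  if (region == "intersection") {
    inter <- Reduce(`&`, lapply(p1_masks[nms], function(m) m$data))
  }
  out <- list()
  rep_rows <- vector("list", length(nms))
  for (i in seq_along(nms)) {
    nm <- nms[i]
    own <- if (is.null(inter)) p1_masks[[nm]]$data else inter
    sel <- background_mask$data | own
    x <- maps[[nm]]$data[sel]
    mu <- mean(x)
    sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv < 1e-12 * max(1, abs(mu)))
      stop("map '", nm, "' has (near-)zero variance over its scaling region")
    gain <- 1 / sdv
    out[[nm]] <- map3d((maps[[nm]]$data - mu) * gain, maps[[nm]]$voxel_size)
    rep_rows[[i]] <- data.frame(map = nm, gain = gain, offset = -mu * gain,
                                region_voxels = sum(sel))
  }
  structure(list(maps = out,
                 p1_masks = p1_masks[nms],
                 background_mask = background_mask,
                 scale_report = do.call(rbind, rep_rows)),
            class = "normalized_map_set")
}

#' @export
print.normalized_map_set <- function(x, ...) {
  cat(sprintf("<normalized_map_set> %d maps: %s\n",
              length(x$maps), paste(names(x$maps), collapse = ", ")))
  print(x$scale_report, row.names = FALSE)
  invisible(x)
}

#' Write a normalization scale report
#'
#' Serializes per-map gain/offset (and any extra provenance fields) as JSON.
#'
#' @param nset a [normalize_set()] result.
#' @param path output path.
#' @param extra optional named list appended to the report.
#' @return `path`, invisibly.
#' @export
write_scale_report <- function(nset, path, extra = NULL) {
  stopifnot(inherits(nset, "normalized_map_set"))
  obj <- list(maps = nset$scale_report)
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
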