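# Synthetic icosahedral procapsid phantoms with ground truth.
#
# A phantom emulates an icosahedrally averaged procapsid reconstruction:
# a spherical shell with Gaussian radial cross-section and recessed
# five-fold vertices (the unexpanded dodecahedral shell), a packaging-motor
# blob on each five-fold axis at the outer surface, a polymerase blob on
# each three-fold axis inside the shell, three cofactor blobs bracketing
# each polymerase site, an optional diffuse central density, and white
# Gaussian noise. Substoichiometric occupancy is rendered as amplitude
# scaling, which is exactly how it appears in a symmetry-averaged map.

#' Phantom specification
#'
#' Builds and validates the parameter set of a procapsid phantom. Defaults
#' describe a 96^3 grid at 2.9 A/voxel carrying a grid-scaled-down particle
#' (shell radius 80 A): small enough for seconds-scale computation while
#' keeping every feature several voxels wide. Protein parameters are lists
#' with `radius` (A from center), `sigma` (Gaussian width, A), `amplitude`
#' (density units) and `occupancy` (fraction in [0, 1]); the cofactor list
#' additionally has `angle_offset` (degrees off its three-fold axis).
#'
#' Default occupancies mirror the complete-particle estimates for the
#' polymerase (0.5) and its cofactor (0.57); blob amplitudes default to the
#' shell amplitude so that a fully occupied site reaches the 100% reference
#' density of the occupancy estimator.
#'
#' @param box_size grid size N (voxels, even).
#' @param voxel_size A per voxel.
#' @param shell_radius,shell_thickness shell center radius and Gaussian
#'   radial sigma (A).
#' @param shell_amplitude peak shell density (arbitrary units).
#' @param vertex_recess_depth depth of the five-fold vertex dimples as a
#'   fraction of the shell amplitude.
#' @param vertex_recess_sigma Gaussian width of the dimples (A).
#' @param p2,p4,p7 protein parameter lists (partial lists are merged into
#'   the defaults).
#' @param central_diffuse_amplitude,central_sigma central Gaussian density.
#' @param noise_sigma white-noise standard deviation (density units).
#' @param seed integer seed (< 2^31); fixed seed gives bit-identical maps.
#' @param p2_sites optional integer subset of 1:20 selecting which
#'   three-fold directions carry a polymerase blob (default all).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(box_size = 96, voxel_size = 2.9,
                         shell_radius = 80, shell_thickness = 8,
                         shell_amplitude = 1,
                         vertex_recess_depth = 0.5, vertex_recess_sigma = 10,
                         p2 = list(), p4 = list(), p7 = list(),
                         central_diffuse_amplitude = 0.3, central_sigma = 20,
                         noise_sigma = 0.1, seed = 1, p2_sites = NULL) {
  p2 <- utils::modifyList(
    list(radius = 60, sigma = 11, amplitude = shell_amplitude,
         occupancy = 0.5), p2)
  p4 <- utils::modifyList(
    list(radius = 88, sigma = 7, amplitude = shell_amplitude,
         occupancy = 1), p4)
  p7 <- utils::modifyList(
    list(radius = 66, sigma = 8, amplitude = shell_amplitude,
         occupancy = 0.57, angle_offset = 15), p7)
  spec <- structure(list(
    box_size = as.integer(box_size), voxel_size = voxel_size,
    shell_radius = shell_radius, shell_thickness = shell_thickness,
    shell_amplitude = shell_amplitude,
    vertex_recess_depth = vertex_recess_depth,
    vertex_recess_sigma = vertex_recess_sigma,
    p2 = p2, p4 = p4, p7 = p7,
    central_diffuse_amplitude = central_diffuse_amplitude,
    central_sigma = central_sigma,
    noise_sigma = noise_sigma, seed = seed, p2_sites = p2_sites
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  half_extent <- spec$box_size * spec$voxel_size / 2
  if (spec$box_size < 16 || spec$box_size %% 2 != 0)
    stop("`box_size` must be an even integer >= 16")
  if (spec$voxel_size <= 0) stop("`voxel_size` must be positive")
  if (spec$shell_radius <= 0 || spec$shell_thickness <= 0 ||
      spec$shell_amplitude <= 0)
    stop("shell radius, thickness and amplitude must be positive")
  if (spec$shell_radius + 3 * spec$shell_thickness >= half_extent)
    stop("shell clips the box edge: shell_radius + 3*shell_thickness must ",
         "stay inside the half box extent ", half_extent, " A")
  for (nm in c("p2", "p4", "p7")) {
    p <- spec[[nm]]
    if (p$sigma <= 0 || p$radius < 0)
      stop(nm, ": sigma must be positive and radius non-negative")
    if (p$radius + 3 * p$sigma >= half_extent)
      stop(nm, " blobs clip the box edge")
    if (p$occupancy < 0 || p$occupancy > 1)
      stop(nm, ": occupancy must be in [0, 1]")
  }
  if (spec$vertex_recess_depth < 0 || spec$vertex_recess_depth > 1)
    stop("`vertex_recess_depth` must be a fraction in [0, 1]")
  if (spec$noise_sigma < 0) stop("`noise_sigma` must be non-negative")
  if (!is.numeric(spec$seed) || spec$seed != round(spec$seed) ||
      abs(spec$seed) >= 2^31)
    stop("`seed` must be an integer below 2^31")
  if (!is.null(spec$p2_sites)) {
    if (!all(spec$p2_sites %in% 1:20) || anyDuplicated(spec$p2_sites))
      stop("`p2_sites` must be a duplicate-free subset of 1:20")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> %d^3 @ %.3g A/voxel, shell R=%.4g A (sigma %.3g)\n",
    "  occupancies: polymerase %.2f, motor %.2f, cofactor %.2f; ",
    "noise sigma %.3g; seed %d\n"),
    x$box_size, x$voxel_size, x$shell_radius, x$shell_thickness,
    x$p2$occupancy, x$p4$occupancy, x$p7$occupancy, x$noise_sigma,
    as.integer(x$seed)))
  invisible(x)
}

# add A*exp(-|x - c|^2 / (2 s^2)) over a local +/-4 sigma box
add_blob <- function(vol, voxel_size, center, amplitude, sigma) {
  n <- dim(vol)[1]
  ctr <- center_index(n)
  lo <- pmax(1L, as.integer(floor((center - 4 * sigma) / voxel_size + ctr)))
  hi <- pmin(n, as.integer(ceiling((center + 4 * sigma) / voxel_size + ctr)))
  if (any(lo > hi)) return(vol)
  xs <- (lo[1]:hi[1] - ctr) * voxel_size
  ys <- (lo[2]:hi[2] - ctr) * voxel_size
  zs <- (lo[3]:hi[3] - ctr) * voxel_size
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    amplitude * exp(-d2 / (2 * sigma^2))
  vol
}

# cofactor blob centers: orbit of one off-axis seed point under the 60
# rotations -- exactly icosahedrally symmetric, three positions ringing
# each three-fold axis at the configured angular offset
cofactor_positions <- function(radius, angle_offset_deg) {
  d1 <- axis_directions(3)$directions[1, ]
  ref <- if (abs(d1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e <- c(d1[2] * ref[3] - d1[3] * ref[2],
         d1[3] * ref[1] - d1[1] * ref[3],
         d1[1] * ref[2] - d1[2] * ref[1])
  e <- e / sqrt(sum(e^2))
  th <- angle_offset_deg * pi / 180
  p0 <- radius * (cos(th) * d1 + sin(th) * e)
  pos <- t(vapply(icosahedral_group(), function(R) as.vector(R %*% p0),
                  numeric(3)))
  keep <- rep(TRUE, nrow(pos))
  for (i in seq_len(nrow(pos))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(pos)) > i)
    if (length(j))
      keep[j[colSums((t(pos[j, , drop = FALSE]) - pos[i, ])^2) < 1e-8]] <- FALSE
  }
  pos[keep, , drop = FALSE]
}

# noiseless building blocks, each at unit occupancy (amplitude included)
phantom_components <- function(spec) {
  n <- spec$box_size
  vox <- spec$voxel_size
  r <- radius_grid(n, vox)
  shell <- spec$shell_amplitude *
    exp(-(r - spec$shell_radius)^2 / (2 * spec$shell_thickness^2))
  dirs5 <- axis_directions(5)$directions
  for (k in seq_len(nrow(dirs5)))
    shell <- add_blob(shell, vox, spec$shell_radius * dirs5[k, ],
                      -spec$vertex_recess_depth * spec$shell_amplitude,
                      spec$vertex_recess_sigma)
  p4 <- array(0, dim(r))
  for (k in seq_len(nrow(dirs5)))
    p4 <- add_blob(p4, vox, spec$p4$radius * dirs5[k, ],
                   spec$p4$amplitude, spec$p4$sigma)
  dirs3 <- axis_directions(3)$directions
  sites <- spec$p2_sites %||% seq_len(nrow(dirs3))
  p2 <- array(0, dim(r))
  for (k in sites)
    p2 <- add_blob(p2, vox, spec$p2$radius * dirs3[k, ],
                   spec$p2$amplitude, spec$p2$sigma)
  p7pos <- cofactor_positions(spec$p7$radius, spec$p7$angle_offset)
  p7 <- array(0, dim(r))
  for (k in seq_len(nrow(p7pos)))
    p7 <- add_blob(p7, vox, p7pos[k, ], spec$p7$amplitude, spec$p7$sigma)
  central <- spec$central_diffuse_amplitude *
    exp(-r^2 / (2 * spec$central_sigma^2))
  list(shell = shell, p2 = p2, p4 = p4, p7 = p7, central = central,
       truth = list(
         p2 = list(positions = spec$p2$radius * dirs3[sites, , drop = FALSE],
                   directions = dirs3[sites, , drop = FALSE],
                   axis_indices = sites, axis_order = 3L,
                   occupancy = spec$p2$occupancy,
                   amplitude = spec$p2$amplitude, sigma = spec$p2$sigma),
         p4 = list(positions = spec$p4$radius * dirs5,
                   directions = dirs5, axis_order = 5L,
                   occupancy = spec$p4$occupancy,
                   amplitude = spec$p4$amplitude, sigma = spec$p4$sigma),
         p7 = list(positions = p7pos, axis_order = 3L,
                   occupancy = spec$p7$occupancy,
                   amplitude = spec$p7$amplitude, sigma = spec$p7$sigma)))
}

assemble_map <- function(spec, comps, weights = c(p2 = NA, p4 = NA, p7 = NA,
                                                  central = 1),
                         noise_seed = NULL) {
  w2 <- if (is.na(weights[["p2"]])) spec$p2$occupancy else weights[["p2"]]
  w4 <- if (is.na(weights[["p4"]])) spec$p4$occupancy else weights[["p4"]]
  w7 <- if (is.na(weights[["p7"]])) spec$p7$occupancy else weights[["p7"]]
  dat <- comps$shell + w2 * comps$p2 + w4 * comps$p4 + w7 * comps$p7 +
    weights[["central"]] * comps$central
  if (spec$noise_sigma > 0 && !is.null(noise_seed)) {
    set.seed(noise_seed)
    dat <- dat + array(stats::rnorm(length(dat), 0, spec$noise_sigma),
                       dim(dat))
  }
  map3d(dat, spec$voxel_size)
}

#' Generate a single procapsid phantom
#'
#' Builds the full phantom (shell with recessed vertices, all protein blobs
#' at their occupancy-scaled amplitudes, central diffuse density, noise)
#' together with its ground truth. The noiseless construction is exactly
#' icosahedrally symmetric; a fixed seed gives a bit-reproducible map.
#'
#' @param spec a [phantom_spec()].
#' @return List with `map` (a [map3d]), `truth` (per-protein positions,
#'   occupancies, amplitudes) and `spec`.
#' @export
generate_procapsid <- function(spec) {
  validate_phantom_spec(spec)
  comps <- phantom_components(spec)
  map <- assemble_map(spec, comps, noise_seed = spec$seed)
  list(map = map, truth = comps$truth, spec = spec)
}

#' Generate a deletion-mutant map triple
#'
#' Emulates the three particle populations used for difference mapping:
#' `P1247` (complete), `P124` (cofactor-minus: cofactor amplitude 0, more
#' diffuse central density) and `P147` (polymerase-minus: polymerase
#' amplitude 0, motor and cofactor amplitudes reduced, central density
#' reduced). Each map receives an independent noise realization with a seed
#' derived from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param p124_central_factor central-density enhancement in the
#'   cofactor-minus particle (default 1.6).
#' @param p147_p4_factor,p147_p7_factor,p147_central_factor motor,
#'   cofactor and central attenuation in the polymerase-minus particle
#'   (defaults 0.5, 0.33, 0.3, mirroring the observed qualitative changes).
#' @return List with `maps` (named list `P1247`, `P124`, `P147`), `truth`,
#'   `factors` and `spec`.
#' @export
generate_mutant_triple <- function(spec,
                                   p124_central_factor = 1.6,
                                   p147_p4_factor = 0.5,
                                   p147_p7_factor = 0.33,
                                   p147_central_factor = 0.3) {
  validate_phantom_spec(spec)
  comps <- phantom_components(spec)
  occ <- c(p2 = spec$p2$occupancy, p4 = spec$p4$occupancy,
           p7 = spec$p7$occupancy)
  maps <- list(
    P1247 = assemble_map(spec, comps, noise_seed = spec$seed + 1),
    P124 = assemble_map(spec, comps,
                        weights = c(p2 = occ[["p2"]], p4 = occ[["p4"]],
                                    p7 = 0, central = p124_central_factor),
                        noise_seed = spec$seed + 2),
    P147 = assemble_map(spec, comps,
                        weights = c(p2 = 0,
                                    p4 = p147_p4_factor * occ[["p4"]],
                                    p7 = p147_p7_factor * occ[["p7"]],
                                    central = p147_central_factor),
                        noise_seed = spec$seed + 3))
  list(maps = maps, truth = comps$truth,
       factors = list(p124_central_factor = p124_central_factor,
                      p147_p4_factor = p147_p4_factor,
                      p147_p7_factor = p147_p7_factor,
                      p147_central_factor = p147_central_factor),
       spec = spec)
}

#' Generate half-maps for FSC testing
#'
#' The same noiseless phantom plus two independent noise realizations, as
#' produced by splitting a particle set in half.
#'
#' @param spec a [phantom_spec()].
#' @return List with `half1`, `half2` ([map3d]) and `truth`.
#' @export
generate_half_maps <- function(spec) {
  validate_phantom_spec(spec)
  comps <- phantom_components(spec)
  list(half1 = assemble_map(spec, comps, noise_seed = spec$seed + 1),
       half2 = assemble_map(spec, comps, noise_seed = spec$seed + 2),
       truth = comps$truth)
}

#' Analytic shell volume of a phantom
#'
#' The volume of the radial band `|r - shell_radius| <= half_width` of a
#' thin spherical shell, `4 pi R^2 (2 half_width)`, in nm^3. This is the
#' natural volume budget for volume-matched thresholding of a phantom,
#' playing the role the protein mass budget plays for a real
#' reconstruction.
#'
#' @param spec a [phantom_spec()].
#' @param half_width band half-width in angstrom; default the shell
#'   thickness (one Gaussian sigma).
#' @return Volume in nm^3.
#' @export
phantom_target_volume <- function(spec, half_width = spec$shell_thickness) {
  4 * pi * spec$shell_radius^2 * 2 * half_width / 1e3
}

#' Write phantom ground truth as JSON
#'
#' @param truth the `truth` element of a generator result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
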