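# Shared fixtures: grid-scaled phantom specifications and pipeline
# configurations sized for fast tests. All fixtures are generated in code.

# 64^3 phantom: same architecture as the default 96^3 spec, scaled to a
# 50 A shell so the whole analysis runs in a couple of seconds.
small_spec <- function(...) {
  defaults <- list(
    box_size = 64, voxel_size = 2.9,
    shell_radius = 50, shell_thickness = 6,
    vertex_recess_sigma = 8,
    p2 = list(radius = 36, sigma = 8),
    p4 = list(radius = 58, sigma = 5),
    p7 = list(radius = 40, sigma = 5),
    central_sigma = 14,
    noise_sigma = 0.1, seed = 7)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# pipeline configuration matched to a phantom's geometry; ... overrides
phantom_config <- function(spec, ...) {
  args <- list(
    target_volume_nm3 = phantom_target_volume(spec),
    p1_radial_band = c(spec$shell_radius - 2 * spec$shell_thickness,
                       spec$shell_radius + 2 * spec$shell_thickness),
    site_radial_band = c(0.5, 0.95) * spec$shell_radius,
    cylinder_radius = 0.15 * spec$shell_radius)
  do.call(pipeline_config, utils::modifyList(args, list(...)))
}

# quick white-noise map
noise_map <- function(n, voxel_size = 2.9, seed = 1, sd = 1) {
  set.seed(seed)
  map3d(array(stats::rnorm(n^3, 0, sd), rep(n, 3)), voxel_size)
}

# spherically symmetric Gaussian-shell map (radius/width in voxels)
shell_map <- function(n, radius, width, voxel_size = 1) {
  r <- icodiff:::radius_grid(n, 1)
  map3d(array(exp(-(r - radius)^2 / (2 * width^2)), rep(n, 3)), voxel_size)
}
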