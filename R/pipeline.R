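# End-to-end difference-mapping pipeline.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the difference-mapping pipeline.
#' Defaults follow the reference analysis: low-pass filtering to 16 A
#' (1.6 nm), a P1 volume budget of 120 copies of 84 kDa at 1.41 g/cm^3,
#' a background annulus at [0.40, 0.47] of the box edge, a detection
#' threshold of 2 sigma, and the top 1% of shell densities as the 100%
#' occupancy reference. `target_volume_nm3` overrides the mass budget
#' (useful for scaled-down phantoms whose shell is smaller than a real
#' particle's). The site search geometry defaults fit the default phantom
#' (band [40, 76] A, cylinder radius 12 A = 0.15 x shell radius).
#'
#' @param filter_resolution low-pass resolution in angstrom.
#' @param filter_roll_off `"cosine"` or `"sharp"`.
#' @param mass_kDa,copies,protein_density volume-budget parameters.
#' @param target_volume_nm3 optional explicit threshold volume target.
#' @param annulus_fraction background annulus radii as fractions of the
#'   box edge.
#' @param p1_radial_band optional radial band (A) intersected with the
#'   shell masks.
#' @param site_radial_band radial search band (A) for axis sites.
#' @param cylinder_radius axis search cylinder radius (A) for the
#'   polymerase difference map.
#' @param cofactor_cylinder_radius search cylinder radius (A) for the
#'   cofactor difference map; default 1.5 x `cylinder_radius`, because the
#'   cofactor subunits ring the axis rather than sitting on it.
#' @param detection_threshold site detection threshold (multiples of the
#'   difference map's sigma).
#' @param reference_quantile occupancy 100% reference quantile.
#' @param site_mask_radius radius (A) of the spherical site masks placed at
#'   detected difference-map peaks for occupancy estimation.
#' @param apply_radial_scale apply per-shell radial factors (ratio of
#'   shell-masked radial averages against the complete map) before
#'   subtracting.
#' @param seed recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_resolution = 16,
                            filter_roll_off = "cosine",
                            mass_kDa = 84, copies = 120,
                            protein_density = 1.41,
                            target_volume_nm3 = NULL,
                            annulus_fraction = c(0.40, 0.47),
                            p1_radial_band = NULL,
                            site_radial_band = c(40, 76),
                            cylinder_radius = 12,
                            cofactor_cylinder_radius = NULL,
                            detection_threshold = 2,
                            reference_quantile = 0.01,
                            site_mask_radius = 4,
                            apply_radial_scale = TRUE,
                            seed = 1) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (cfg$filter_resolution <= 0) stop("`filter_resolution` must be positive")
  if (!cfg$filter_roll_off %in% c("cosine", "sharp"))
    stop("`filter_roll_off` must be 'cosine' or 'sharp'")
  if (length(cfg$annulus_fraction) != 2L ||
      cfg$annulus_fraction[1] <= 0 ||
      cfg$annulus_fraction[1] >= cfg$annulus_fraction[2] ||
      cfg$annulus_fraction[2] > 0.5)
    stop("`annulus_fraction` must satisfy 0 < inner < outer <= 0.5")
  if (length(cfg$site_radial_band) != 2L ||
      cfg$site_radial_band[1] >= cfg$site_radial_band[2])
    stop("`site_radial_band` must be c(r_min, r_max), r_min < r_max")
  if (cfg$detection_threshold <= 0)
    stop("`detection_threshold` must be positive")
  if (cfg$reference_quantile <= 0 || cfg$reference_quantile > 1)
    stop("`reference_quantile` must be in (0, 1]")
  if (is.null(cfg$target_volume_nm3)) {
    for (v in c(cfg$mass_kDa, cfg$copies, cfg$protein_density))
      if (v <= 0) stop("volume-budget parameters must be positive")
  } else if (cfg$target_volume_nm3 <= 0) {
    stop("`target_volume_nm3` must be positive")
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full difference-mapping pipeline
#'
#' Executes, on a complete / cofactor-minus / polymerase-minus map triple:
#' low-pass filtering, volume-matched thresholding and shell masks,
#' background annulus, joint standardization, optional radial scaling,
#' the two difference maps and the shell composite, axis-constrained site
#' detection at the three-fold axes, and occupancy estimation with site
#' masks generated from the difference maps. All parameters are taken from
#' the [pipeline_config()]; every output is deterministic for a fixed
#' configuration.
#'
#' @param maps named list (`P1247`, `P124`, `P147`) of [map3d] objects or
#'   paths to MRC files.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, normalized maps,
#'   difference maps, the composite, site tables, the occupancy table and
#'   the scale report are written there.
#' @param verbose log stage progress and parameters via [message()].
#' @return A report list: `config`, `thresholds`, `normalized` (the
#'   [normalize_set()] result), `diffs`, `composite`, `sites` (site tables
#'   for the polymerase and cofactor difference maps), `site_counts`, and
#'   `occupancy` (a data.frame).
#' @export
run_pipeline <- function(maps, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")
  say <- function(...) if (verbose) message(sprintf(...))
  required <- c("P1247", "P124", "P147")

  maps <- .stage("input", {
    if (is.null(names(maps)) || !setequal(names(maps), required))
      stop("`maps` must be named P1247, P124, P147")
    maps <- maps[required]
    loaded <- lapply(maps, function(m) {
      if (is.character(m)) read_mrc(m) else if (is_map3d(m)) m
      else stop("each map must be a map3d or an MRC path")
    })
    for (m in loaded[-1]) assert_same_grid(loaded[[1]], m)
    loaded
  })
  n <- grid_size(maps[[1]])
  edge <- n * maps[[1]]$voxel_size
  say("pipeline: %d^3 grid, %.3g A/voxel", n, maps[[1]]$voxel_size)

  filtered <- .stage("filter", {
    say("low-pass filtering to %.3g A (%s roll-off)",
        config$filter_resolution, config$filter_roll_off)
    lapply(maps, low_pass_filter, resolution = config$filter_resolution,
           roll_off = config$filter_roll_off)
  })

  target <- .stage("volume-budget", {
    tv <- config$target_volume_nm3 %||%
      expected_protein_volume(config$mass_kDa, config$copies,
                              config$protein_density)
    say("volume-matched threshold target: %.4g nm^3", tv)
    tv
  })

  thresholds <- .stage("threshold", lapply(filtered, threshold_for_volume,
                                           target_volume = target))
  p1_masks <- .stage("shell-masks", {
    lapply(required, function(nm) {
      p1_shell_mask(filtered[[nm]], thresholds[[nm]]$threshold,
                    radial_band = config$p1_radial_band)
    }) |> stats::setNames(required)
  })
  background <- .stage("background", background_annulus_mask(
    filtered[[1]], config$annulus_fraction[1] * edge,
    config$annulus_fraction[2] * edge))

  nset <- .stage("normalize", normalize_set(filtered, p1_masks, background))
  scaled <- nset$maps

  if (config$apply_radial_scale) {
    scaled <- .stage("radial-scale", {
      ref_prof <- radial_average(scaled$P1247, nset$p1_masks$P1247)
      for (nm in c("P124", "P147")) {
        prof <- radial_average(scaled[[nm]], nset$p1_masks[[nm]])
        scaled[[nm]] <- radial_scale(scaled[[nm]], ref_prof, prof)
      }
      scaled
    })
  }

  diffs <- .stage("subtract", list(
    polymerase = subtract_maps(scaled$P1247, scaled$P147,
                               names = c("P1247", "P147")),
    cofactor = subtract_maps(scaled$P1247, scaled$P124,
                             names = c("P1247", "P124"))))
  composite <- .stage("composite",
                      composite_p14(scaled$P124, scaled$P147, scaled$P1247))

  axes3 <- axis_directions(3)
  cof_cyl <- config$cofactor_cylinder_radius %||%
    (1.5 * config$cylinder_radius)
  sites <- .stage("detect", list(
    polymerase = detect_axis_sites(diffs$polymerase, axes = axes3,
                                   radial_band = config$site_radial_band,
                                   threshold = config$detection_threshold,
                                   cylinder_radius = config$cylinder_radius),
    cofactor = detect_axis_sites(diffs$cofactor, axes = axes3,
                                 radial_band = config$site_radial_band,
                                 threshold = config$detection_threshold,
                                 cylinder_radius = cof_cyl)))
  site_counts <- vapply(sites, site_count, integer(1))
  say("detected sites: polymerase %d, cofactor %d",
      site_counts[["polymerase"]], site_counts[["cofactor"]])

  occupancy <- .stage("occupancy", {
    # site masks: spheres at the detected difference-map peaks
    site_mask_of <- function(d) {
      det <- sites[[d]][sites[[d]]$detected, , drop = FALSE]
      if (nrow(det) == 0) return(NULL)
      acc <- array(FALSE, dim = rep(n, 3))
      for (i in seq_len(nrow(det))) {
        ctr <- c(det$peak_x[i], det$peak_y[i], det$peak_z[i])
        acc <- acc | spherical_mask(ctr, config$site_mask_radius,
                                    scaled$P1247)$data
      }
      mask3d(acc, scaled$P1247$voxel_size)
    }
    masks <- list(polymerase = site_mask_of("polymerase"),
                  cofactor = site_mask_of("cofactor"))
    # complete-particle occupancies are read from the difference maps
    # (the shell cancels there); the 100% reference comes from the
    # complete map. Mutant-map occupancies are read from the mutant map
    # directly, as for the original reconstructions.
    cases <- list(list("polymerase", "P1247", diffs$polymerase$data),
                  list("polymerase", "P124", scaled$P124),
                  list("cofactor", "P1247", diffs$cofactor$data),
                  list("cofactor", "P147", scaled$P147))
    do.call(rbind, lapply(cases, function(cs) {
      prot <- cs[[1]]; nm <- cs[[2]]; src <- cs[[3]]
      if (is.null(masks[[prot]]))
        return(data.frame(protein = prot, map = nm, occupancy = NA_real_,
                          site_mean = NA_real_, p1_reference = NA_real_,
                          background_mean = NA_real_))
      est <- estimate_occupancy(src, masks[[prot]],
                                nset$p1_masks[[nm]], background,
                                reference_quantile = config$reference_quantile,
                                reference_map = scaled[[nm]],
                                site_name = prot)
      data.frame(protein = prot, map = nm, occupancy = est$occupancy,
                 site_mean = est$site_mean, p1_reference = est$p1_reference,
                 background_mean = est$background_mean)
    }))
  })

  report <- list(config = config, thresholds = thresholds,
                 normalized = nset, maps = scaled, diffs = diffs,
                 composite = composite, sites = sites,
                 site_counts = site_counts, occupancy = occupancy)

  if (!is.null(out_dir)) .stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in required)
      write_mrc(scaled[[nm]], file.path(out_dir, paste0(nm, "_norm.mrc")))
    write_mrc(diffs$polymerase$data,
              file.path(out_dir, "diff_polymerase.mrc"))
    write_mrc(diffs$cofactor$data, file.path(out_dir, "diff_cofactor.mrc"))
    write_mrc(composite, file.path(out_dir, "composite_p14.mrc"))
    write_site_table(sites$polymerase,
                     file.path(out_dir, "sites_polymerase.tsv"))
    write_site_table(sites$cofactor, file.path(out_dir, "sites_cofactor.tsv"))
    utils::write.table(occupancy, file.path(out_dir, "occupancy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_scale_report(nset, file.path(out_dir, "scale_report.json"),
                       extra = list(
                         thresholds = lapply(thresholds, function(t)
                           t[c("threshold", "achieved_volume",
                               "target_volume")]),
                         config = unclass(config)))
    say("outputs written to %s", out_dir)
  })
  report
}

# voxels inside any axis search cylinder within the radial band
.axis_region_mask <- function(map, axes, radial_band, cylinder_radius) {
  n <- grid_size(map)
  r <- as.vector(radius_grid(n, map$voxel_size))
  in_band <- r >= radial_band[1] & r <= radial_band[2]
  co <- grid_coords(n, map$voxel_size)[in_band, , drop = FALSE]
  ax <- co %*% t(axes$directions)
  rb <- r[in_band]
  hit <- rep(FALSE, nrow(co))
  for (k in seq_len(ncol(ax)))
    hit <- hit | (ax[, k] > 0 & rb^2 - ax[, k]^2 <= cylinder_radius^2)
  out <- rep(FALSE, n^3)
  out[which(in_band)[hit]] <- TRUE
  array(out, dim = c(n, n, n))
}
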