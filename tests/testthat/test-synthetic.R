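# Phantom generator: determinism, symmetry, ground truth, mutant algebra.

test_that("phantom specifications are validated", {
  expect_s3_class(small_spec(), "phantom_spec")
  expect_error(small_spec(shell_radius = 90), "clips the box edge")
  expect_error(small_spec(p2 = list(occupancy = 1.2)), "occupancy")
  expect_error(small_spec(p4 = list(sigma = -1)), "sigma")
  expect_error(small_spec(noise_sigma = -0.1), "non-negative")
  expect_error(small_spec(seed = 2^31), "seed")
  expect_error(small_spec(p2_sites = c(1, 1, 2)), "p2_sites")
  expect_error(small_spec(p2_sites = c(0, 5)), "p2_sites")
})

test_that("generation is deterministic for a fixed seed and seeds change the noise", {
  a <- generate_procapsid(small_spec(seed = 77))
  b <- generate_procapsid(small_spec(seed = 77))
  expect_identical(a$map$data, b$map$data)
  c_ <- generate_procapsid(small_spec(seed = 78))
  expect_false(identical(a$map$data, c_$map$data))
})

test_that("a noiseless shell-only phantom is exactly icosahedrally symmetric", {
  sp <- small_spec(box_size = 48, shell_radius = 36, shell_thickness = 6,
                   p2 = list(radius = 26, sigma = 6),
                   p4 = list(radius = 42, sigma = 5),
                   p7 = list(radius = 29, sigma = 5),
                   noise_sigma = 0)
  g <- generate_procapsid(sp)
  s <- symmetrize(g$map)
  expect_lt(max(abs(s$data - g$map$data)) / max(g$map$data), 0.05)
})

test_that("ground-truth geometry follows the axis sets", {
  g <- generate_procapsid(small_spec())
  tr <- g$truth
  expect_identical(nrow(tr$p2$positions), 20L)
  expect_identical(nrow(tr$p4$positions), 12L)
  expect_identical(nrow(tr$p7$positions), 60L)   # three per three-fold axis
  expect_equal(sqrt(rowSums(tr$p2$positions^2)),
               rep(36, 20), tolerance = 1e-9)
  # each cofactor position sits at the configured angle off a three-fold axis
  d3 <- axis_directions(3)$directions
  ang <- apply(tr$p7$positions, 1, function(p) {
    u <- p / sqrt(sum(p^2))
    min(acos(pmin(1, d3 %*% u))) * 180 / pi
  })
  expect_equal(unname(ang), rep(15, 60), tolerance = 1e-6)
})

test_that("blob integrals match the closed-form Gaussian volume", {
  sp <- small_spec(noise_sigma = 0, p4 = list(occupancy = 0),
                   p7 = list(occupancy = 0), central_diffuse_amplitude = 0,
                   p2 = list(occupancy = 1))
  with_p2 <- generate_procapsid(sp)$map
  shell_only <- generate_procapsid(
    small_spec(noise_sigma = 0, p4 = list(occupancy = 0),
               p7 = list(occupancy = 0), central_diffuse_amplitude = 0,
               p2 = list(occupancy = 0)))$map
  total <- sum(with_p2$data - shell_only$data) * sp$voxel_size^3
  analytic <- 20 * (2 * pi)^1.5 * sp$p2$sigma^3 * sp$p2$amplitude
  expect_lt(abs(total - analytic) / analytic, 0.01)
})

test_that("mutant triples implement the deletion algebra", {
  sp <- small_spec(noise_sigma = 0)
  # hold the central density fixed so the complete-minus-cofactor-minus
  # difference isolates the cofactor exactly
  tr <- generate_mutant_triple(sp, p124_central_factor = 1)
  d <- tr$maps$P1247$data - tr$maps$P124$data
  r <- icodiff:::radius_grid(sp$box_size, sp$voxel_size)
  p7r <- sqrt(sum(tr$truth$p7$positions[1, ]^2))
  # blob evaluation is truncated at a 4-sigma box whose corners reach
  # sqrt(3)*(4 sigma + 1 voxel); beyond 8 sigma of the cofactor radius the
  # difference must vanish identically
  away <- abs(r - p7r) > 8 * sp$p7$sigma
  expect_gt(max(abs(d)), 0.1)
  expect_identical(max(abs(d[away])), 0)
  # polymerase-minus: only shell/central tails near the three-fold band,
  # nothing at the blob level
  sites <- detect_axis_sites(map3d(tr$maps$P147$data, sp$voxel_size),
                             axis_directions(3),
                             c(0.9, 1.1) * sp$p2$radius, threshold = 2,
                             cylinder_radius = 4, sigma = 1)
  expect_identical(site_count(sites), 0L)
  expect_lt(max(sites$peak_value, na.rm = TRUE), 0.5 * sp$shell_amplitude)
})

test_that("half-maps share the signal but differ in noise", {
  hm <- generate_half_maps(small_spec(seed = 81))
  expect_false(identical(hm$half1$data, hm$half2$data))
  f <- fsc_curve(hm$half1, hm$half2)
  # signal-dominated at low frequency
  expect_gt(f$correlations[2], 0.95)
  # amplitude-zero phantom: pure noise, FSC fluctuates about zero
  sp0 <- small_spec(shell_amplitude = 1e-9, vertex_recess_depth = 0,
                    p2 = list(occupancy = 0), p4 = list(occupancy = 0),
                    p7 = list(occupancy = 0), central_diffuse_amplitude = 0,
                    seed = 82)
  hm0 <- generate_half_maps(sp0)
  f0 <- fsc_curve(hm0$half1, hm0$half2)
  expect_lt(mean(abs(f0$correlations), na.rm = TRUE), 0.1)
})

test_that("the full pipeline recovers ground-truth site counts and polymerase occupancy", {
  sp <- phantom_spec(seed = 5)            # default 96^3 study conditions
  tr <- generate_mutant_triple(sp)
  cfg <- phantom_config(sp)
  rep <- run_pipeline(tr$maps, cfg)
  expect_identical(unname(rep$site_counts["polymerase"]), 20L)
  occ <- rep$occupancy
  est_p2 <- occ$occupancy[occ$protein == "polymerase" & occ$map == "P1247"]
  est_p7 <- occ$occupancy[occ$protein == "cofactor" & occ$map == "P1247"]
  expect_lt(abs(est_p2 - sp$p2$occupancy), 0.10)
  expect_lt(abs(est_p7 - sp$p7$occupancy), 0.10)
})
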