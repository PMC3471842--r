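# Volume-matched thresholding, masks, joint standardization, radial
# scaling.

test_that("expected protein volume matches the direct molar computation", {
  # oracle: 84000 g/mol / N_A / 1.41 g/cm^3 * 120 copies, cm^3 -> nm^3
  oracle <- 120 * (84 * 1e3 / 6.02214076e23) / 1.41 * 1e21
  expect_equal(expected_protein_volume(84, 120, 1.41), oracle,
               tolerance = 1e-12)
  expect_equal(oracle / 1e4, 1.187, tolerance = 1e-3)
  expect_equal(expected_protein_volume(84, 240, 1.41),
               2 * expected_protein_volume(84, 120, 1.41), tolerance = 1e-12)
  expect_error(expected_protein_volume(84, 0, 1.41), "positive")
  expect_error(expected_protein_volume(-84, 120, 1.41), "positive")
})

test_that("volume-matched threshold equals the sort-and-index oracle", {
  set.seed(41)
  n <- 24
  m <- map3d(array(stats::rnorm(n^3), rep(n, 3)), 2)
  voxvol <- (2 / 10)^3
  sorted <- sort(as.vector(m$data), decreasing = TRUE)
  for (k in c(1, 10, 500, 5000, n^3 %/% 2)) {
    res <- threshold_for_volume(m, k * voxvol)
    expect_identical(res$threshold, sorted[k])  # brute-force oracle
    expect_identical(res$voxels, as.integer(k)) # continuous values: no ties
    expect_equal(res$achieved_volume, k * voxvol, tolerance = 1e-12)
  }
  # half the grid volume: threshold is the median within one quantile step
  res <- threshold_for_volume(m, n^3 / 2 * voxvol)
  expect_lte(abs(res$threshold - stats::median(m$data)),
             diff(range(sorted[(n^3 %/% 2 - 1):(n^3 %/% 2 + 1)])) + 1e-12)
})

test_that("threshold is monotone in the target and handles two-level maps exactly", {
  two <- array(0, c(16, 16, 16)); two[1:4, 1:4, 1:4] <- 1
  m <- map3d(two, 10)             # voxel volume 1 nm^3
  res <- threshold_for_volume(m, 64)
  expect_gt(res$threshold, 0)
  expect_lte(res$threshold, 1)
  expect_equal(res$achieved_volume, 64, tolerance = 1e-12)
  set.seed(42)
  rnd <- map3d(array(stats::rnorm(16^3), rep(16, 3)), 10)
  targets <- c(10, 100, 1000, 3000)
  thr <- vapply(targets, function(t) threshold_for_volume(rnd, t)$threshold,
                numeric(1))
  expect_true(all(diff(thr) <= 0))
  expect_error(threshold_for_volume(rnd, 16^3 + 1), "exceeds")
  expect_error(threshold_for_volume(rnd, -5), "positive")
})

test_that("shell masks honor the threshold and the radial band", {
  two <- array(0, c(16, 16, 16)); two[1:4, 1:4, 1:4] <- 1
  m <- map3d(two, 1)
  expect_identical(p1_shell_mask(m, 0.5)$data, two == 1)
  expect_warning(msk <- p1_shell_mask(m, 0.5, radial_band = c(0, 0)),
                 "empty")
  expect_false(any(msk$data))
  # phantom shell: mask volume within 5% of the analytic band volume
  sp <- small_spec(noise_sigma = 0, p2 = list(occupancy = 0),
                   p4 = list(occupancy = 0), p7 = list(occupancy = 0),
                   vertex_recess_depth = 0, central_diffuse_amplitude = 0)
  g <- generate_procapsid(sp)
  # threshold at one sigma of the radial Gaussian -> band |r - R| <= sigma
  msk <- p1_shell_mask(g$map, exp(-0.5) * sp$shell_amplitude)
  analytic <- 4 * pi * sp$shell_radius^2 * 2 * sp$shell_thickness
  expect_lt(abs(sum(msk$data) * sp$voxel_size^3 - analytic) / analytic, 0.05)
})

test_that("background annulus validates radii and matches the analytic volume", {
  m <- noise_map(32, voxel_size = 1, seed = 43)
  expect_error(background_annulus_mask(m, 10, 8), "r_inner")
  expect_error(background_annulus_mask(m, 0, 8), "r_inner")
  expect_error(background_annulus_mask(m, 10, 40), "r_inner")
  msk <- background_annulus_mask(m, 8, 15)
  analytic <- 4 / 3 * pi * (15^3 - 8^3)
  expect_lt(abs(sum(msk$data) - analytic) / analytic, 0.02)
  # disjoint from a particle sphere inside r_inner
  part <- spherical_mask(c(0, 0, 0), 7.5, m)
  expect_false(any(msk$data & part$data))
})

test_that("normalization fixes mean 0 / sd 1 on the union region and is affine-invariant", {
  set.seed(44)
  n <- 32
  base <- array(stats::rnorm(n^3, 1, 2), rep(n, 3))
  m1 <- map3d(base, 1)
  m2 <- map3d(3 * base + 5, 1)               # affine copy
  p1 <- p1_shell_mask(m1, stats::quantile(base, 0.9))
  bg <- background_annulus_mask(m1, 10, 15)
  nset <- normalize_set(list(a = m1, b = m2), list(a = p1, b = p1), bg)
  for (nm in c("a", "b")) {
    sel <- bg$data | p1$data
    expect_lt(abs(mean(nset$maps[[nm]]$data[sel])), 1e-6)
    expect_lt(abs(stats::sd(nset$maps[[nm]]$data[sel]) - 1), 1e-6)
  }
  expect_lt(max(abs(nset$maps$a$data - nset$maps$b$data)), 1e-9)
  # already-normalized map is a fixed point: gain 1, offset 0
  nset2 <- normalize_set(list(a = nset$maps$a), list(a = p1), bg)
  expect_equal(nset2$scale_report$gain, 1, tolerance = 1e-9)
  expect_equal(nset2$scale_report$offset, 0, tolerance = 1e-9)
  # zero-variance region is an error
  flat <- map3d(array(1, rep(n, 3)), 1)
  expect_error(normalize_set(list(a = flat), list(a = p1), bg), "variance")
})

test_that("a normalized phantom triple has matching shell-mean densities", {
  # the triple shares one shell construction; keep the internal proteins
  # compact and the in-band motor density common so the shell region is
  # the same physical density in all three maps
  sp <- small_spec(p2 = list(radius = 28, sigma = 5),
                   p7 = list(radius = 32, sigma = 4), seed = 19)
  tr <- generate_mutant_triple(sp, p124_central_factor = 1.3,
                               p147_p4_factor = 1,
                               p147_p7_factor = 0.33,
                               p147_central_factor = 0.5)
  filtered <- lapply(tr$maps, low_pass_filter, resolution = 16)
  target <- phantom_target_volume(sp)
  band <- c(sp$shell_radius - 2 * sp$shell_thickness,
            sp$shell_radius + 2 * sp$shell_thickness)
  masks <- lapply(filtered, function(m)
    p1_shell_mask(m, threshold_for_volume(m, target)$threshold, band))
  edge <- sp$box_size * sp$voxel_size
  bg <- background_annulus_mask(filtered[[1]], 0.40 * edge, 0.47 * edge)
  nset <- normalize_set(filtered, masks, bg)
  shell_means <- vapply(names(nset$maps), function(nm)
    mean(nset$maps[[nm]]$data[nset$p1_masks[[nm]]$data]), numeric(1))
  expect_lt(diff(range(shell_means)) / mean(shell_means), 0.02)
})

test_that("radial scaling recovers a per-shell distortion and keeps identical profiles fixed", {
  m <- low_pass_filter(noise_map(32, voxel_size = 1, seed = 45), 6)
  prof <- radial_average(m)
  same <- radial_scale(m, prof, prof)
  expect_lt(max(abs(same$data - m$data)), 1e-9)
  # distort each shell by g(r), then undo
  n <- 32
  r <- icodiff:::radius_grid(n, 1)
  bin <- floor(r) + 1
  g <- 1 + 0.5 * sin(seq_len(max(bin)) / 3)
  distorted <- map3d(m$data * array(g[bin], dim = dim(m$data)), 1)
  dprof <- radial_average(distorted)
  fixed <- radial_scale(distorted, prof, dprof)
  rprof <- radial_average(fixed)
  keep <- prof$counts > 0 & abs(prof$means) > 1e-3
  expect_lt(max(abs(rprof$means[keep] - prof$means[keep])), 1e-6)
  # mismatched shell grids are rejected
  prof2 <- radial_average(m, shell_width = 2)
  expect_error(radial_scale(m, prof2, prof), "shell grids")
})
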