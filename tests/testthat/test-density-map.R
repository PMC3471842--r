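# Volume data model, MRC I/O, pixel-size arithmetic, filtering, radial
# statistics.

test_that("map3d validates its grid and densities", {
  expect_s3_class(map3d(array(0, c(4, 4, 4)), 1.5), "map3d")
  expect_error(map3d(array(0, c(4, 4, 5)), 1), "cubic")
  expect_error(map3d(array(0, c(4, 4)), 1), "3-D")
  expect_error(map3d(array(0, c(4, 4, 4)), -1), "positive")
  bad <- array(0, c(4, 4, 4)); bad[2, 2, 2] <- NaN
  expect_error(map3d(bad, 1), "finite")
})

test_that("MRC round-trips densities bit-exactly and the voxel size", {
  m0 <- noise_map(16, voxel_size = 2.9, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".mrc")
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m0, p1)
  m1 <- read_mrc(p1)               # densities now float32-representable
  expect_equal(m1$voxel_size, 2.9, tolerance = 1e-6)
  expect_equal(m1$data, m0$data, tolerance = 1e-6)
  write_mrc(m1, p2)
  m2 <- read_mrc(p2)
  expect_identical(m2$data, m1$data)
  expect_identical(m2$voxel_size, m1$voxel_size)
})

test_that("malformed and truncated MRC files raise errors, not silent corruption", {
  m <- noise_map(16, seed = 2)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, path)
  # truncate the data section
  trunc <- withr::local_tempfile(fileext = ".mrc")
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:(1024 + 100)], trunc)
  expect_error(read_mrc(trunc), "truncated")
  # header shorter than 1024 bytes
  stub <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw[1:200], stub)
  expect_error(read_mrc(stub), "truncated")
  # corrupt the MAP tag
  bad <- withr::local_tempfile(fileext = ".mrc")
  raw2 <- raw; raw2[209:212] <- as.raw(0)
  writeBin(raw2, bad)
  expect_error(read_mrc(bad), "malformed")
  expect_error(read_mrc(file.path(tempdir(), "does-not-exist.mrc")),
               "no such file")
})

test_that("non-cubic MRC volumes are rejected", {
  path <- withr::local_tempfile(fileext = ".mrc")
  m <- noise_map(16, seed = 3)
  write_mrc(m, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  con <- file(path, "r+b")
  writeBin(c(16L, 16L, 8L), con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(path), "non-cubic")
})

test_that("scanner pitch and magnification give the specimen pixel size", {
  expect_equal(signif(pixel_size_from_scan(14, 48000), 2), 2.9)
  expect_equal(pixel_size_from_scan(14, 48000), 14e4 / 48000,
               tolerance = 1e-12)
  expect_equal(pixel_size_from_scan(14, 140000), 1.0, tolerance = 1e-12)
  expect_equal(pixel_size_from_scan(7, 48000),
               pixel_size_from_scan(14, 48000) / 2, tolerance = 1e-12)
  expect_error(pixel_size_from_scan(-14, 48000), "positive")
  expect_error(pixel_size_from_scan(14, 0), "positive")
})

test_that("low-pass filter preserves DC, kills above-cutoff sinusoids, and is linear", {
  n <- 32
  const <- map3d(array(3.7, rep(n, 3)), 1)
  expect_lt(max(abs(low_pass_filter(const, 8)$data - 3.7)), 1e-9)
  # pure sinusoid at 1.5x the cutoff frequency: cutoff 1/8, k = 6 -> f = 6/32
  x <- 2 * pi * (0:(n - 1)) * 6 / n
  sine <- map3d(array(rep(sin(x), times = n * n), rep(n, 3)), 1)
  filt <- low_pass_filter(sine, 8)
  expect_lt(max(abs(filt$data)), 0.01 * max(abs(sine$data)))
  # mean (DC) preservation on a generic map
  m <- noise_map(n, voxel_size = 1, seed = 5)
  expect_lt(abs(mean(low_pass_filter(m, 6)$data) - mean(m$data)), 1e-9)
  # linearity
  a <- noise_map(n, voxel_size = 1, seed = 6)
  b <- noise_map(n, voxel_size = 1, seed = 7)
  lin <- map3d(2 * a$data - 0.5 * b$data, 1)
  lhs <- low_pass_filter(lin, 6)$data
  rhs <- 2 * low_pass_filter(a, 6)$data - 0.5 * low_pass_filter(b, 6)$data
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  # Nyquist guard
  expect_error(low_pass_filter(m, 1.5), "Nyquist")
})

test_that("sharp roll-off fully suppresses just-above-cutoff components", {
  n <- 32
  x <- 2 * pi * (0:(n - 1)) * 5 / n          # f = 5/32, cutoff 1/8 = 4/32
  sine <- map3d(array(rep(sin(x), times = n * n), rep(n, 3)), 1)
  filt <- low_pass_filter(sine, 8, roll_off = "sharp")
  expect_lt(max(abs(filt$data)), 1e-9)
})

test_that("radial averages match per-voxel binning and flag empty shells", {
  n <- 24
  const <- map3d(array(2.5, rep(n, 3)), 1)
  prof <- radial_average(const)
  expect_true(all(prof$means[prof$counts > 0] == 2.5))
  expect_identical(sum(prof$counts), as.integer(n^3))
  # map equal to its own radius: shell means must sit near shell centers
  r <- icodiff:::radius_grid(n, 1)
  mr <- map3d(r, 1)
  prof_r <- radial_average(mr, shell_width = 1)
  # brute-force oracle: bin voxel radii directly
  bin <- floor(as.vector(r))
  oracle <- tapply(as.vector(r), bin, mean)
  got <- prof_r$means[as.integer(names(oracle)) + 1L]
  expect_equal(unname(got), unname(as.vector(oracle)), tolerance = 1e-12)
  expect_true(all(abs(got - prof_r$shell_centers[as.integer(names(oracle)) + 1L])
                  <= 0.5 + 1e-9))
  # all-false mask: every shell undefined
  empty <- mask3d(array(FALSE, rep(n, 3)), 1)
  expect_true(all(is.na(radial_average(const, empty)$means)))
})

test_that("radial averages are rotation-invariant (symmetrized map)", {
  m <- low_pass_filter(noise_map(32, voxel_size = 1, seed = 9), 8)
  s <- symmetrize(m)
  pm <- radial_average(m)
  ps <- radial_average(s)
  core <- pm$counts > 0 & pm$shell_centers < 12   # away from corner shells
  expect_lt(max(abs(pm$means[core] - ps$means[core])),
            0.05 * diff(range(m$data)))
})
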