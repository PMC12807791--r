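test_that("sphere signal averages the eroded in-plane mask only", {
  dims <- c(40, 40, 3)
  m2 <- array(0L, dims)
  disk <- digital_disk(dims[1:2], c(20, 20), 8)
  m2[, , 2][disk] <- 1L

  vox <- array(100, dims)
  vox[, , 2][disk] <- 40
  x0 <- cine_volume(vox, 0.14, 0.14)
  expect_equal(sphere_signal(x0, m2, 1L, 2L), 40)

  # a 3-pixel rim at 70 must be excluded by the 3-pixel erosion
  inner <- digital_disk(dims[1:2], c(20, 20), 5)
  vox2 <- array(100, dims)
  vox2[, , 2][disk] <- 70
  vox2[, , 2][inner] <- 40
  x02 <- cine_volume(vox2, 0.14, 0.14)
  expect_equal(sphere_signal(x02, m2, 1L, 2L), 40)

  # a small fragment vanishes after three erosions: unmeasurable
  m2s <- array(0L, dims)
  m2s[, , 2][digital_disk(dims[1:2], c(20, 20), 2.5)] <- 1L
  expect_true(is.na(sphere_signal(x0, m2s, 1L, 2L)))
})

test_that("background stats pool the 4d cylinder and exclude the dilated raw mask", {
  dims <- c(80, 80, 10)
  vox <- array(100, dims)
  x0 <- cine_volume(vox, 0.14, 0.14)
  none <- array(FALSE, dims)
  bs <- background_stats(x0, none, xi = 40, yi = 40, d = 2)
  expect_equal(bs$Sb, 100)
  expect_equal(bs$sigma_b, 0)
  # cylinder radius 2d = 4 mm is ~28.6 px: check the pooled voxel count
  expect_equal(bs$n / dims[3], pi * (4 / 0.14)^2, tolerance = 0.01)

  set.seed(301)
  vox2 <- array(rnorm(prod(dims), 100, 10), dims)
  sphere <- digital_ball(dims, c(40, 40, 5), 7)
  vox2[sphere] <- 40
  x02 <- cine_volume(pmax(vox2, 0), 0.14, 0.14)
  m0d <- binary_dilate3d(sphere, 1)
  with_excl <- background_stats(x02, m0d, 40, 40, 2)
  expect_equal(with_excl$Sb, 100, tolerance = 0.01)
  expect_equal(with_excl$sigma_b, 10, tolerance = 0.05)
  without <- background_stats(x02, none, 40, 40, 2)
  expect_lt(without$Sb, with_excl$Sb - 1)  # sphere voxels bias the mean down

  # too small a background sample drops the sphere
  tiny <- background_stats(x02, array(TRUE, dims), 40, 40, 2)
  expect_true(is.na(tiny$Sb))
})

test_that("lsnr follows the defining formula and its invariances", {
  expect_equal(lsnr(40, 100, 10), -6)
  expect_equal(lsnr(100, 100, 10), 0)
  expect_equal(lsnr(2 * 40 + 5, 2 * 100 + 5, 2 * 10), -6)
  expect_true(is.na(lsnr(40, 100, 0)))
})

test_that("lsnr_curve bins half-open slabs with standard errors", {
  sp <- tibble::tibble(
    depth_cm = c(0.1, 0.15, 0.18), lsnr = c(-8, -10, -12),
    eligible = TRUE
  )
  cv <- lsnr_curve(sp, c(0, 10), n_slabs = 25)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$lsnr, -10)
  expect_equal(cv$sigma_lsnr, 2)
  expect_equal(cv$epsilon, 2 / sqrt(3))
  expect_equal(cv$n_spheres, 3L)
  # 10 cm split into 25 slabs: 0.4 cm extent each
  edges <- attr(cv, "edges")
  expect_equal(unique(round(diff(edges), 10)), 0.4)

  empty <- lsnr_curve(sp[0, ], c(0, 10), 25)
  expect_equal(nrow(empty), 0L)

  # single-sphere slabs have no epsilon; boundary depths go to the upper slab
  sp2 <- tibble::tibble(depth_cm = c(0.39999, 0.4), lsnr = c(-5, -7),
                        eligible = TRUE)
  cv2 <- lsnr_curve(sp2, c(0, 10), 25)
  expect_equal(cv2$slab, c(1L, 2L))
  expect_true(all(is.na(cv2$epsilon)))
})

test_that("variability reproduces the hand-computed RSDs", {
  mk <- function(vals, ns = 5) {
    sp <- tibble::tibble(depth_cm = seq(0.2, by = 0.4, length.out = length(vals)),
                         lsnr = vals, eligible = TRUE)
    lsnr_curve(sp, c(0, 0.4 * ns), n_slabs = ns)
  }
  c1 <- mk(c(-10, -10, -10))
  expect_equal(glance(variability(list(c1, c1)))$overall_rsd_lsnr, 0)

  c2 <- mk(c(-10, -10, -10))
  c3 <- mk(c(-11, -11, -11))
  v <- variability(list(c2, c3))
  expect_equal(v$overall_rsd_lsnr, 100 * sd(c(-10, -11)) / 10.5,
               tolerance = 1e-10)
  expect_equal(round(v$overall_rsd_lsnr, 2), 6.73)

  # counts {10, 14, 12} at one slab: RSD = 2/12
  one_slab <- function(n) {
    sp <- tibble::tibble(depth_cm = rep(0.2, n), lsnr = rnorm(n, -10),
                         eligible = TRUE)
    lsnr_curve(sp, c(0, 2), n_slabs = 5)
  }
  set.seed(302)
  vc <- variability(list(one_slab(10), one_slab(14), one_slab(12)))
  expect_equal(vc$overall_rsd_counts, 100 * 2 / 12, tolerance = 1e-10)

  expect_error(variability(list(c1)), class = "rhsp_input_error")
  # mismatched grids are rejected
  expect_error(variability(list(c1, mk(c(-10, -10), ns = 4))),
               class = "rhsp_input_error")
})

test_that("the point report picks the slab containing the requested depth", {
  sp <- tibble::tibble(depth_cm = c(0.5, 1.5, 0.5, 1.5),
                       lsnr = c(-10, -8, -12, -9), eligible = TRUE)
  cva <- lsnr_curve(sp[1:2, ], c(0, 2), n_slabs = 2)
  cvb <- lsnr_curve(sp[3:4, ], c(0, 2), n_slabs = 2)
  v <- variability(list(cva, cvb), at_depth = 1.5)
  expect_equal(v$at_depth, 1.5)
  expect_equal(v$point_rsd_lsnr, 100 * sd(c(-8, -9)) / 8.5)
  expect_error(variability(list(cva, cvb), at_depth = 5),
               class = "rhsp_input_error")
})
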