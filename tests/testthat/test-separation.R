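test_that("the distance transform matches a brute-force oracle", {
  set.seed(201)
  mask <- array(runif(12 * 10 * 8) > 0.6, c(12, 10, 8))
  mask[1, 1, 1] <- FALSE  # keep at least one background voxel
  expect_equal(distance_transform(mask), edt_brute(mask), tolerance = 1e-12)

  ball <- digital_ball(c(21, 21, 21), c(11, 11, 11), 6)
  dt <- distance_transform(ball)
  expect_equal(which.max(dt), which(ball & edt_brute(ball) == max(edt_brute(ball)))[1])
  expect_true(all(dt[!ball] == 0))
})

test_that("touching balls split into two labels with accurate centroids", {
  dims <- c(40, 30, 30)
  m <- digital_ball(dims, c(14, 15, 15), 6) | digital_ball(dims, c(26, 15, 15), 6)
  m2 <- split_connected(m)
  expect_equal(max(m2), 2L)
  expect_identical(m2 > 0, m)  # watershed relabels, never adds/removes
  for (lab in 1:2) {
    idx <- which(m2 == lab)
    cc <- colMeans(arrayInd(idx, dims))
    d1 <- sqrt(sum((cc - c(14, 15, 15))^2))
    d2 <- sqrt(sum((cc - c(26, 15, 15))^2))
    expect_lt(min(d1, d2), 1)
  }
})

test_that("balls merged beyond the seed rule stay one label and fail the area band", {
  dims <- c(40, 30, 24)
  # centers 3 voxels apart in-plane: seeds collapse under the 5-voxel rule
  m <- digital_ball(dims, c(18, 15, 12), 6) | digital_ball(dims, c(21, 15, 12), 6)
  m2 <- split_connected(m)
  expect_equal(max(m2), 1L)

  vol <- cine_volume(array(100, dims), 0.14, 0.14)
  sp <- max_cross_sections(m2, vol)
  # union of two radius-6 disks offset 3 exceeds the 1.25 x (pi d^2/4) bound
  # for d = 12 pixels
  d_mm <- 12 * 0.14
  filt <- area_filter(sp, d_mm, exclude_edge = FALSE)
  expect_false(any(filt$eligible))

  single <- split_connected(digital_ball(dims, c(18, 15, 12), 6))
  expect_equal(max(single), 1L)
  sps <- area_filter(max_cross_sections(single, vol), d_mm,
                     exclude_edge = FALSE)
  expect_true(all(sps$eligible))
})

test_that("empty masks yield empty label maps", {
  m2 <- split_connected(array(FALSE, c(10, 10, 5)))
  expect_true(all(m2 == 0L))
})

test_that("max cross-section is the argmax frame, not the area centroid", {
  dims <- c(30, 30, 5)
  m2 <- array(0L, dims)
  areas <- c(3, 9, 30, 28, 5)
  for (f in seq_along(areas)) {
    px <- which(digital_disk(dims[1:2], c(15, 15), 6))[seq_len(areas[f])]
    fr <- matrix(FALSE, dims[1], dims[2])
    fr[px] <- TRUE
    m2[, , f][fr] <- 1L
  }
  vol <- cine_volume(array(100, dims), 0.14, 0.14)
  sp <- max_cross_sections(m2, vol)
  expect_equal(sp$zi, 3L)        # frame with area 30
  expect_equal(sp$si_px, 30L)
  # the area-weighted centroid frame (~3.31) differs from the argmax frame
  expect_equal(sum(seq_along(areas) * areas) / sum(areas), 3.3067,
               tolerance = 1e-4)

  # ties break toward the lower frame index
  m2t <- array(0L, dims)
  m2t[10:12, 10:13, 2] <- 1L
  m2t[10:12, 10:13, 4] <- 1L
  spt <- max_cross_sections(m2t, vol)
  expect_equal(spt$zi, 2L)
})

test_that("area_filter applies the inclusive eligibility band", {
  expected <- pi * 2^2 / 4  # mm^2, d = 2
  px_area <- 0.14 * 0.14
  expect_equal(0.5 * expected / px_area, 80.14, tolerance = 1e-3)
  expect_equal(1.25 * expected / px_area, 200.36, tolerance = 1e-3)

  sp <- tibble::tibble(
    label = 1:5, zi = 1L, si_px = 1L,
    si_mm2 = c(pi, 1.0, 0.5 * pi, 1.25 * pi, 1.26 * pi),
    xi = 1, yi = 1, depth_cm = 0.5, edge = FALSE
  )
  out <- area_filter(sp, 2)
  expect_equal(out$eligible, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(area_filter(sp, 0), class = "rhsp_config_error")

  # edge-touching spheres are excluded unless asked otherwise
  sp$edge[1] <- TRUE
  expect_false(area_filter(sp, 2)$eligible[1])
  expect_true(area_filter(sp, 2, exclude_edge = FALSE)$eligible[1])
})

test_that("label support equals the mask and labels are contiguous", {
  set.seed(202)
  spec <- phantom_spec(size_cm = c(depth = 1.2, width = 1, length = 1.6))
  sim <- simulate_acquisition(spec, scan_profile(n_frames = 24,
                                                 coverage_cm = 0.8),
                              seed = 4)
  x1 <- preprocess(extract_fov(sim$volume))
  masks <- segment(x1, slab_thresholds(x1))
  m2 <- split_connected(masks$m1)
  expect_identical(m2 > 0L, masks$m1)
  labs <- sort(unique(as.integer(m2[m2 > 0])))
  expect_identical(labs, seq_along(labs))
  sp <- max_cross_sections(m2, x1)
  expect_equal(nrow(sp), max(m2))
  expect_true(all(sp$si_px > 0))
})

test_that("elevational sampling at d/4 keeps the diameter underestimate small", {
  d <- 2
  delta <- d / 4
  # numeric oracle: the plane nearest the centre misses it by at most delta/2
  offsets <- seq(0, delta / 2, length.out = 2001)
  diam <- 2 * sqrt((d / 2)^2 - offsets^2)
  worst <- 1 - min(diam) / d
  expect_equal(worst, 1 - sqrt(1 - (delta / d)^2), tolerance = 1e-9)
  expect_lt(worst, 0.035)
  # averaged over a uniform plane offset the bias is well under 3%
  expect_lt(1 - mean(diam) / d, 0.03)
})
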