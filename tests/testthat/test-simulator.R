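test_that("phantom defaults are self-consistent and placement hits the target", {
  spec <- phantom_spec()
  implied <- spec$density * (pi / 6) * (spec$sphere_diameter / 10)^3
  expect_lt(abs(implied - spec$volume_fraction) / spec$volume_fraction, 0.05)
  expect_error(phantom_spec(density = 30), class = "rhsp_config_error")
  expect_error(phantom_spec(contrast_db = 5), class = "rhsp_config_error")

  # ~10 mL region: about 480 spheres, achieved fraction within 1% absolute
  spec10 <- phantom_spec(size_cm = c(depth = 2, width = 2, length = 2.5))
  tr <- place_spheres(spec10, seed = 1)
  expect_equal(nrow(tr$centers), 480, tolerance = 0.02)
  expect_lt(abs(tr$achieved_fraction - 0.20), 0.01)
  # solid spheres: no two centres closer than one diameter
  dmin <- min(dist(as.matrix(tr$centers[, 1:3])))
  expect_gte(dmin, spec10$sphere_diameter)

  none <- place_spheres(phantom_spec(volume_fraction = 0, density = 0))
  expect_equal(nrow(none$centers), 0L)

  tr2 <- place_spheres(spec10, seed = 1)
  expect_identical(tr$centers, tr2$centers)
})

test_that("rendering is seed-deterministic and obeys its preconditions", {
  spec <- phantom_spec(size_cm = c(depth = 1, width = 1, length = 1.5))
  prof <- scan_profile(n_frames = 12, coverage_cm = 0.8)
  s1 <- simulate_acquisition(spec, prof, seed = 3)
  s2 <- simulate_acquisition(spec, prof, seed = 3)
  expect_identical(s1$volume$voxels, s2$volume$voxels)
  expect_identical(s1$truth$frame_positions_mm, s2$truth$frame_positions_mm)
  s3 <- simulate_acquisition(spec, prof, seed = 4)
  expect_false(identical(s1$volume$voxels, s3$volume$voxels))

  expect_error(scan_profile(n_frames = 2), class = "rhsp_input_error")
  expect_error(scan_profile(coverage_cm = 0), class = "rhsp_input_error")
  expect_error(
    render_acquisition(place_spheres(spec, 1),
                       scan_profile(n_frames = 12, coverage_cm = 9)),
    class = "rhsp_input_error"
  )
  # frame positions are strictly increasing and span the coverage
  pos <- s1$truth$frame_positions_mm
  expect_true(all(diff(pos) > 0))
  expect_equal(max(pos) - min(pos), 8)
})

test_that("near-zero contrast leaves no detectable spheres", {
  spec <- phantom_spec(size_cm = c(depth = 1.2, width = 1, length = 1.6),
                       contrast_db = -1e-9)
  sim <- simulate_acquisition(spec, scan_profile(n_frames = 20,
                                                 coverage_cm = 0.9), seed = 5)
  a <- suppressWarnings(analyze(sim$volume))
  expect_equal(sum(a$spheres$eligible), 0L)
  expect_equal(nrow(a$curve), 0L)
})

test_that("slab mean intensity decreases with depth before bias correction", {
  spec <- phantom_spec(size_cm = c(depth = 2, width = 1, length = 1.5))
  sim <- simulate_acquisition(spec, scan_profile(n_frames = 12,
                                                 coverage_cm = 0.8), seed = 6)
  x0 <- extract_fov(sim$volume)
  parts <- slab_partition(dim(x0$voxels)[1], 10)
  means <- purrr::map2_dbl(parts$row_start, parts$row_end,
                           function(a, b) mean(x0$voxels[a:b, , ]))
  expect_true(all(diff(means) < 0))
})

test_that("speed jitter makes the per-frame area profile asymmetric", {
  spec <- phantom_spec()
  jit <- simulate_acquisition(spec, scan_profile(coverage_cm = 2,
                                                 speed_jitter = 0.5),
                              seed = 9)$truth
  frame_stats <- function(truth) {
    cs <- truth_cross_sections(truth)
    dplyr::filter(
      dplyr::summarise(
        dplyr::group_by(cs, .data$sphere),
        argmax = .data$frame[which.max(.data$area_mm2)],
        centroid = sum(.data$frame * .data$area_mm2) / sum(.data$area_mm2),
        n = dplyr::n(), .groups = "drop"
      ),
      n >= 3
    )
  }
  fj <- frame_stats(jit)
  frac_jit <- mean(fj$argmax != round(fj$centroid))
  expect_gte(frac_jit, 0.3)

  uni <- simulate_acquisition(spec, scan_profile(coverage_cm = 2,
                                                 speed_jitter = 0),
                              seed = 9)$truth
  fu <- frame_stats(uni)
  frac_uni <- mean(fu$argmax != round(fu$centroid))
  expect_lt(frac_uni, frac_jit / 2)
})
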