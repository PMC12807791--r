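test_that("slab_partition follows the rounding rule and covers all rows", {
  p <- slab_partition(700, 10)
  expect_equal(p$row_end - p$row_start + 1L, rep(70L, 10))

  # oracle: boundaries at round(k * 705 / 10), half-up
  bounds <- floor((0:10) * 705 / 10 + 0.5)
  p2 <- slab_partition(705, 10)
  expect_equal(p2$row_start, bounds[-11] + 1L)
  expect_equal(p2$row_end, bounds[-1])
  expect_equal(sum(p2$row_end - p2$row_start + 1L), 705L)

  p3 <- slab_partition(25, 25)
  expect_equal(p3$row_end, p3$row_start)
  expect_error(slab_partition(9, 10), class = "rhsp_input_error")
})

test_that("the histogram peak tracks the background mode, not the mixture mean", {
  set.seed(101)
  bg <- rnorm(8e4, 100, 10)
  h <- rhsp:::slab_histogram(bg, 256)
  mu <- background_peak(h$counts, h$mids)
  expect_lt(abs(mu - 100), 1)

  # 20% sphere voxels drag the mean to ~92 but not the peak
  mix <- c(rnorm(8e4, 100, 10), rnorm(2e4, 60, 10))
  hm <- rhsp:::slab_histogram(mix, 256)
  mum <- background_peak(hm$counts, hm$mids)
  expect_lt(abs(mum - 100), 2)
  expect_gt(mum - mean(mix), 4)  # mean is pulled down by ~8, the peak is not

  # ties break toward the lowest intensity bin
  expect_equal(background_peak(c(1, 5, 2, 5), c(80, 90, 100, 110)), 90)
  expect_error(background_peak(integer(0), numeric(0)),
               class = "rhsp_input_error")
})

test_that("mirrored_std matches hand computations and recovers a Gaussian SD", {
  expect_equal(mirrored_std(c(100, 101), 100), sqrt(0.5))
  expect_equal(mirrored_std(rep(42, 10), 42), 0)
  set.seed(102)
  x <- rnorm(1e6, 0, 5)
  expect_lt(abs(mirrored_std(x, 0) - 5) / 5, 0.01)
  expect_error(mirrored_std(c(1, 2, 3), 10), class = "rhsp_input_error")
})

test_that("slab_threshold is mu - 2 sigma and passes the normal tail", {
  expect_equal(slab_threshold(100, 10), 80)
  expect_equal(slab_threshold(55, 0), 55)
  set.seed(103)
  bg <- rnorm(2e5, 100, 10)
  h <- rhsp:::slab_histogram(bg, 256)
  mu <- background_peak(h$counts, h$mids)
  tk <- slab_threshold(mu, mirrored_std(bg, mu))
  expect_equal(mean(bg < tk), pnorm(-2), tolerance = 0.15)
})

test_that("mirrored background model beats naive statistics at 20% sphere fraction", {
  set.seed(104)
  vals <- c(rnorm(6.4e5, 100, 10), rnorm(1.6e5, 60, 10))
  h <- rhsp:::slab_histogram(vals, 256)
  mu <- background_peak(h$counts, h$mids)
  sigma <- mirrored_std(vals, mu)
  err_mu <- abs(mu - 100) / 100
  err_sigma <- abs(sigma - 10) / 10
  expect_lt(err_mu, 0.05)
  expect_lt(err_sigma, 0.05)
  naive_mu_err <- abs(mean(vals) - 100) / 100
  naive_sd_err <- abs(sd(vals) - 10) / 10
  expect_gt(naive_mu_err, 5 * err_mu)
  expect_gt(naive_sd_err, 5 * err_sigma)
})

test_that("segment thresholds per slab, strictly below, and opening cleans speckle", {
  set.seed(105)
  vox <- array(rnorm(60 * 40 * 8, 200, 5), c(60, 40, 8))
  # a bright-background volume with one dark noisy ball and one dark voxel
  ball <- digital_ball(c(60, 40, 8), c(30, 20, 4), 7)
  vox[ball] <- rnorm(sum(ball), 60, 5)
  vox[5, 5, 2] <- 10
  v <- cine_volume(pmax(vox, 0), 0.1, 0.1)
  thr <- slab_thresholds(v)
  masks <- segment(v, thr)
  expect_true(all(masks$m1 <= masks$m0))          # opening never adds voxels
  expect_true(masks$m0[5, 5, 2])                  # speckle voxel in m0 ...
  expect_false(masks$m1[5, 5, 2])                 # ... removed from m1
  expect_gte(sum(masks$m1 & ball) / sum(ball), 0.9)  # ball survives opening

  # boundary voxels exactly at the threshold are background
  thr_row <- thr$threshold[1]
  vx <- v
  vx$voxels[1, 1, 1] <- thr_row
  m <- segment(vx, thr)
  expect_false(m$m0[1, 1, 1])

  # everything above all thresholds: empty masks
  hi <- cine_volume(array(1000, c(60, 40, 8)), 0.1, 0.1)
  mh <- segment(hi, thr)
  expect_false(any(mh$m0))
  expect_false(any(mh$m1))
})

test_that("lowering a slab threshold can only shrink the raw mask", {
  set.seed(106)
  vox <- array(runif(50 * 30 * 6, 0, 255), c(50, 30, 6))
  v <- cine_volume(vox, 0.1, 0.1)
  thr <- slab_thresholds(v)
  m_hi <- segment(v, thr)
  thr_lo <- dplyr::mutate(thr, threshold = threshold - 20)
  m_lo <- segment(v, thr_lo)
  expect_true(all(m_lo$m0 <= m_hi$m0))
})
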