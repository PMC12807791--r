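#' Partition depth rows into contiguous slabs
#'
#' The slab boundary between slab `k` and `k+1` sits at
#' `round(k * n_rows / n_slabs)`; the resulting half-open ranges cover the
#' depth extent exactly with no overlap.
#'
#' @param n_rows Number of depth rows.
#' @param n_slabs Number of slabs (default 10).
#' @return A tibble with columns `slab`, `row_start`, `row_end`
#'   (1-based, inclusive).
#' @export
slab_partition <- function(n_rows, n_slabs = 10L) {
  n_rows <- as.integer(n_rows)
  n_slabs <- as.integer(n_slabs)
  if (n_rows < n_slabs)
    stop_input("fewer depth rows than slabs")
  bounds <- floor(seq(0L, n_slabs) * n_rows / n_slabs + 0.5)
  tibble(
    slab = seq_len(n_slabs),
    row_start = bounds[-(n_slabs + 1L)] + 1L,
    row_end = bounds[-1L]
  )
}

#' Histogram peak as the background mean
#'
#' The mode of the slab histogram is taken as the mean of the background
#' Gaussian: the background dominates the slab and is brighter than the
#' spheres, so the all-pixel mean would be dragged down by the sphere voxels
#' while the histogram peak is not. Ties are broken toward the lowest
#' intensity bin.
#'
#' @param counts Histogram bin counts.
#' @param mids Histogram bin centres (same length as `counts`).
#' @return The intensity of the peak bin centre.
#' @export
background_peak <- function(counts, mids) {
  if (length(counts) == 0L || sum(counts) == 0)
    stop_input("empty histogram")
  mids[which.max(counts)]
}

slab_histogram <- function(values, n_bins = 256L) {
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) {
    return(list(counts = length(values), mids = lo,
                breaks = c(lo, lo)))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
       breaks = breaks)
}

#' Mirrored-background standard deviation
#'
#' Every voxel at or above the background peak is assumed to belong to the
#' background. Mirroring that right half-sample around the peak reconstructs
#' the full background Gaussian, whose population standard deviation is
#' returned. The mirrored set has mean exactly `mu`, so the computation
#' reduces to the root mean square deviation of the right half around `mu`.
#'
#' @param slab_voxels Intensities of all voxels in the slab.
#' @param mu Background peak from [background_peak()].
#' @return The background standard deviation (>= 0).
#' @export
mirrored_std <- function(slab_voxels, mu) {
  s <- slab_voxels[slab_voxels >= mu]
  if (length(s) == 0L)
    stop_input("no voxels at or above the background peak")
  sqrt(mean((s - mu)^2))
}

#' Slab threshold from the background model
#'
#' @param mu Background mean.
#' @param sigma Background standard deviation.
#' @param k_sigma Multiplier (default 2): the threshold is `mu - k_sigma * sigma`.
#' @return The segmentation threshold for the slab.
#' @export
slab_threshold <- function(mu, sigma, k_sigma = 2) {
  if (sigma < 0) stop_input("`sigma` must be non-negative")
  mu - k_sigma * sigma
}

#' Depth-adaptive thresholds for a segmentation volume
#'
#' Splits the preprocessed volume into `n_slabs` depth slabs and derives a
#' background-Gaussian threshold for each: histogram peak as the mean,
#' mirrored right half for the standard deviation, threshold at
#' `mu - k_sigma * sigma`.
#'
#' @param x1 The preprocessed [cine_volume()].
#' @param n_slabs Number of depth slabs (default 10).
#' @param n_bins Histogram bins (default 256).
#' @param k_sigma Threshold multiplier (default 2).
#' @return A tibble with one row per slab: `slab`, `row_start`, `row_end`,
#'   `mu`, `sigma`, `threshold`.
#' @export
slab_thresholds <- function(x1, n_slabs = 10L, n_bins = 256L, k_sigma = 2) {
  stopifnot(inherits(x1, "cine_volume"))
  parts <- slab_partition(dim(x1$voxels)[1], n_slabs)
  stats <- purrr::pmap(parts, function(slab, row_start, row_end) {
    vals <- as.numeric(x1$voxels[row_start:row_end, , ])
    h <- slab_histogram(vals, n_bins)
    mu <- background_peak(h$counts, h$mids)
    sigma <- mirrored_std(vals, mu)
    tibble(mu = mu, sigma = sigma,
           threshold = slab_threshold(mu, sigma, k_sigma))
  })
  dplyr::bind_cols(parts, dplyr::bind_rows(stats))
}

#' Segment sphere voxels with per-slab thresholds
#'
#' Voxels strictly below their slab's threshold form the raw sphere mask
#' `m0`; three iterations of binary opening remove speckle-sized responses,
#' giving the cleaned mask `m1`. `m0` (not `m1`) is what the LSNR background
#' exclusion uses later, so both are returned.
#'
#' @param x1 The preprocessed [cine_volume()].
#' @param thresholds Output of [slab_thresholds()]; must cover every depth
#'   row exactly once.
#' @param opening_iterations Opening passes applied to `m0` (default 3).
#' @return A list with logical arrays `m0` and `m1`.
#' @export
segment <- function(x1, thresholds, opening_iterations = 3L) {
  stopifnot(inherits(x1, "cine_volume"))
  d <- dim(x1$voxels)
  rows_covered <- unlist(purrr::map2(thresholds$row_start, thresholds$row_end, seq))
  if (!identical(sort(rows_covered), seq_len(d[1])))
    stop_input("thresholds must cover every depth row exactly once")
  thr_by_row <- numeric(d[1])
  for (i in seq_len(nrow(thresholds))) {
    thr_by_row[thresholds$row_start[i]:thresholds$row_end[i]] <-
      thresholds$threshold[i]
  }
  m0 <- sweep(x1$voxels, 1, thr_by_row, `<`)
  m1 <- binary_opening_inplane(m0, opening_iterations)
  list(m0 = m0, m1 = m1)
}
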