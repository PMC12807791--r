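#' Sphere signal at the maximum cross-section
#'
#' The sphere's in-plane mask in its maximum cross-section frame is eroded
#' by `erosion` pixels (4-connected) so the boundary, blurred by the point
#' spread function, does not contaminate the lesion mean. The signal is the
#' mean raw intensity over the eroded mask. If erosion empties the mask the
#' sphere cannot be measured and `NA` is returned.
#'
#' @param x0 The raw cropped [cine_volume()].
#' @param m2 Label array from [split_connected()].
#' @param label Sphere label.
#' @param zi Frame index of the maximum cross-section.
#' @param erosion Erosion passes (default 3).
#' @return Mean sphere intensity, or `NA` if the eroded mask is empty.
#' @export
sphere_signal <- function(x0, m2, label, zi, erosion = 3L) {
  mask <- m2[, , zi] == label
  er <- binary_erode2d(mask, erosion)
  if (!any(er)) return(NA_real_)
  mean(x0$voxels[, , zi][er])
}

#' Background signal and noise around a sphere
#'
#' A cylinder of diameter `4 d` centred at the sphere's in-plane position is
#' extended along the whole elevational axis: the background at a given
#' depth is the same in every frame, and pooling frames shrinks the
#' uncertainty of the background estimates. Voxels inside the raw sphere
#' mask `m0` dilated by one voxel are excluded so sphere tails do not bias
#' the background down. Returns the mean and the population standard
#' deviation over the remaining voxels.
#'
#' @param x0 The raw cropped [cine_volume()].
#' @param m0_dilated Raw sphere mask dilated by 1 voxel (6-connected).
#' @param xi,yi Sphere centre, columns and rows (pixels).
#' @param d Designed sphere diameter, mm.
#' @param min_background_voxels Minimum usable background sample
#'   (default 100); below it the sphere is unmeasurable and `NA`s are
#'   returned.
#' @return A list with `Sb`, `sigma_b`, and the background voxel count `n`.
#' @export
background_stats <- function(x0, m0_dilated, xi, yi, d,
                             min_background_voxels = 100L) {
  dm <- dim(x0$voxels)
  r_mm <- 2 * d  # radius of the 4d-diameter cylinder
  dy <- (seq_len(dm[1]) - yi) * x0$axial_spacing
  dx <- (seq_len(dm[2]) - xi) * x0$lateral_spacing
  cyl <- outer(dy^2, dx^2, `+`) <= r_mm^2
  sel <- which(cyl)
  if (length(sel) == 0L) return(list(Sb = NA_real_, sigma_b = NA_real_, n = 0L))
  plane <- dm[1] * dm[2]
  full <- rep(sel, times = dm[3]) + rep((seq_len(dm[3]) - 1L) * plane,
                                        each = length(sel))
  keep <- !m0_dilated[full]
  vals <- x0$voxels[full][keep]
  if (length(vals) < min_background_voxels)
    return(list(Sb = NA_real_, sigma_b = NA_real_, n = length(vals)))
  Sb <- mean(vals)
  list(Sb = Sb, sigma_b = sqrt(mean((vals - Sb)^2)), n = length(vals))
}

#' Lesion signal-to-noise ratio
#'
#' `(Sf - Sb) / sigma_b`: negative for hypoechoic lesions, with larger
#' magnitude meaning better detectability. Invariant under any affine
#' rescaling `a * x + b` (a > 0) of the image intensities, which is why gain
#' changes leave it unchanged.
#'
#' @param Sf Sphere signal.
#' @param Sb Background signal.
#' @param sigma_b Background noise (> 0).
#' @return The LSNR, or `NA` if `sigma_b` is not positive.
#' @export
lsnr <- function(Sf, Sb, sigma_b) {
  out <- (Sf - Sb) / sigma_b
  out[!is.na(sigma_b) & sigma_b <= 0] <- NA_real_
  out
}

#' Measure LSNR for every eligible sphere
#'
#' Runs [sphere_signal()] and [background_stats()] on the raw volume for
#' each eligible sphere and appends `Sf`, `Sb`, `sigma_b`, `lsnr` and a
#' `drop_reason` (`NA` when measured; `"empty_erosion"`,
#' `"insufficient_background"` or `"zero_noise"` otherwise).
#'
#' @param x0 The raw cropped [cine_volume()].
#' @param m0 Raw sphere mask from [segment()].
#' @param m2 Label array from [split_connected()].
#' @param spheres Tibble from [area_filter()].
#' @param d Designed sphere diameter, mm.
#' @param erosion In-plane erosion for the sphere mask (default 3).
#' @param dilation Dilation of `m0` for background exclusion (default 1).
#' @param min_background_voxels Minimum background sample (default 100).
#' @return The sphere tibble with measurement columns added.
#' @export
measure_lsnr <- function(x0, m0, m2, spheres, d, erosion = 3L, dilation = 1L,
                         min_background_voxels = 100L) {
  m0d <- binary_dilate3d(m0, dilation)
  n <- nrow(spheres)
  Sf <- Sb <- sigma_b <- lsnr_i <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!spheres$eligible[i]) next
    sf <- sphere_signal(x0, m2, spheres$label[i], spheres$zi[i], erosion)
    if (is.na(sf)) {
      reason[i] <- "empty_erosion"
      next
    }
    bg <- background_stats(x0, m0d, spheres$xi[i], spheres$yi[i], d,
                           min_background_voxels)
    if (is.na(bg$Sb)) {
      reason[i] <- "insufficient_background"
      next
    }
    if (bg$sigma_b <= 0) {
      reason[i] <- "zero_noise"
      next
    }
    Sf[i] <- sf
    Sb[i] <- bg$Sb
    sigma_b[i] <- bg$sigma_b
    lsnr_i[i] <- lsnr(sf, bg$Sb, bg$sigma_b)
  }
  dropped <- !is.na(reason)
  if (any(dropped))
    warn(sprintf("%d sphere(s) dropped from LSNR: %s", sum(dropped),
                 paste(unique(reason[dropped]), collapse = ", ")))
  dplyr::mutate(spheres, Sf = Sf, Sb = Sb, sigma_b = sigma_b, lsnr = lsnr_i,
                drop_reason = reason)
}

#' LSNR-versus-depth curve
#'
#' Divides the analyzed depth extent into `n_slabs` uniform slabs and
#' averages the sphere LSNRs whose centre depth falls in each half-open slab
#' `[yk, yk+1)` (the deepest edge is closed). The per-slab uncertainty is
#' the standard error `sd / sqrt(N)` (sample SD), defined for slabs with at
#' least two spheres. Slabs without spheres contribute no curve point.
#'
#' @param spheres Tibble from [measure_lsnr()]; rows with `NA` LSNR are
#'   ignored.
#' @param depth_range_cm Length-2 numeric, the analyzed depth extent in cm.
#' @param n_slabs Number of depth slabs (default 25).
#' @return A tibble of class `rhsp_lsnr_curve` with `slab`, `depth_cm`
#'   (slab midpoint), `lsnr`, `sigma_lsnr`, `epsilon`, `n_spheres`. The full
#'   slab-edge grid is kept in the `edges` attribute.
#' @export
lsnr_curve <- function(spheres, depth_range_cm, n_slabs = 25L) {
  edges <- seq(depth_range_cm[1], depth_range_cm[2], length.out = n_slabs + 1L)
  ok <- !is.na(spheres$lsnr)
  sub <- spheres[ok, , drop = FALSE]
  slab <- findInterval(sub$depth_cm, edges, rightmost.closed = TRUE)
  in_range <- slab >= 1L & slab <= n_slabs
  sub <- sub[in_range, , drop = FALSE]
  slab <- slab[in_range]
  curve <- dplyr::summarise(
    dplyr::group_by(tibble(slab = slab, lsnr_i = sub$lsnr), .data$slab),
    lsnr = mean(.data$lsnr_i),
    sigma_lsnr = sd(.data$lsnr_i),  # sample SD; NA for single-sphere slabs
    n_spheres = dplyr::n(),
    .groups = "drop"
  )
  curve <- dplyr::mutate(
    curve,
    depth_cm = (edges[.data$slab] + edges[.data$slab + 1L]) / 2,
    epsilon = .data$sigma_lsnr / sqrt(.data$n_spheres)
  )
  curve <- dplyr::arrange(
    dplyr::select(curve, "slab", "depth_cm", "lsnr", "sigma_lsnr",
                  "epsilon", "n_spheres"),
    .data$slab
  )
  structure(curve, edges = edges, n_slabs = n_slabs,
            class = c("rhsp_lsnr_curve", class(curve)))
}

curve_grid_matrix <- function(curves, what) {
  n_slabs <- attr(curves[[1]], "n_slabs")
  edges <- attr(curves[[1]], "edges")
  for (cv in curves) {
    if (!isTRUE(all.equal(attr(cv, "edges"), edges)))
      stop_input("curves are not on identical slab grids")
  }
  m <- matrix(NA_real_, nrow = n_slabs, ncol = length(curves))
  for (j in seq_along(curves)) {
    cv <- curves[[j]]
    m[cv$slab, j] <- cv[[what]]
  }
  if (what == "n_spheres") m[is.na(m)] <- 0  # absent slab means zero spheres
  m
}

rsd_by_slab <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- 100 * s / abs(mu)
  out[is.nan(out) | is.infinite(out)] <- NA_real_
  complete <- rowSums(is.na(m)) == 0
  out[!complete] <- NA_real_
  list(rsd = out, mean = mu, complete = complete)
}

#' Repeatability of LSNR and sphere-count curves
#'
#' Relative standard deviation (sample SD across acquisitions divided by the
#' absolute mean, in percent) of the per-slab LSNR and sphere counts, plus
#' their unweighted averages over the slabs where every acquisition has a
#' defined value. Optionally also reports the RSDs at the slab containing a
#' named depth.
#'
#' @param curves List of at least two [lsnr_curve()] results on identical
#'   slab grids.
#' @param at_depth Optional depth (cm) for a single-point report.
#' @return A list of class `rhsp_variability`: `per_depth` tibble
#'   (`slab`, `depth_cm`, `rsd_lsnr`, `rsd_counts`), `overall_rsd_lsnr`,
#'   `overall_rsd_counts`, and (when `at_depth` is given) `point_rsd_lsnr`,
#'   `point_rsd_counts`, `at_depth`.
#' @export
variability <- function(curves, at_depth = NULL) {
  if (length(curves) < 2L)
    stop_input("variability needs at least two acquisitions")
  lsnr_m <- curve_grid_matrix(curves, "lsnr")
  cnt_m <- curve_grid_matrix(curves, "n_spheres")
  rl <- rsd_by_slab(lsnr_m)
  rc <- rsd_by_slab(cnt_m)
  zero_mean <- (rl$complete & !is.na(rl$mean) & rl$mean == 0) |
    (rc$mean == 0 & rowSums(cnt_m) > 0)
  if (any(zero_mean))
    warn("slab(s) with zero mean excluded from the overall RSD")
  edges <- attr(curves[[1]], "edges")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  per_depth <- tibble(slab = seq_along(mids), depth_cm = mids,
                      rsd_lsnr = rl$rsd, rsd_counts = rc$rsd)
  out <- list(
    per_depth = per_depth,
    overall_rsd_lsnr = mean(rl$rsd, na.rm = TRUE),
    overall_rsd_counts = mean(rc$rsd[rowSums(cnt_m) > 0], na.rm = TRUE),
    n_acquisitions = length(curves)
  )
  if (!is.null(at_depth)) {
    k <- findInterval(at_depth, edges, rightmost.closed = TRUE)
    if (k < 1 || k > length(mids))
      stop_input("`at_depth` lies outside the analyzed depth range")
    out$at_depth <- at_depth
    out$point_rsd_lsnr <- rl$rsd[k]
    out$point_rsd_counts <- rc$rsd[k]
  }
  structure(out, class = "rhsp_variability")
}

#' @export
print.rhsp_variability <- function(x, ...) {
  cat(sprintf("<rhsp_variability> %d acquisitions\n", x$n_acquisitions))
  cat(sprintf("  overall RSD: LSNR %.2f%%, sphere counts %.2f%%\n",
              x$overall_rsd_lsnr, x$overall_rsd_counts))
  if (!is.null(x$at_depth))
    cat(sprintf("  at %.2f cm:  LSNR %.2f%%, sphere counts %.2f%%\n",
                x$at_depth, x$point_rsd_lsnr, x$point_rsd_counts))
  invisible(x)
}
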