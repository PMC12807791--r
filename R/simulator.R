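#' Phantom specification
#'
#' Physical description of the random hypoechoic sphere phantom: 2 mm
#' spheres at roughly 48 per mL (a 20% volume fraction) with a backscatter
#' of -40 dB relative to the tissue-mimicking background, which attenuates
#' at 0.5 dB/cm/MHz. Defaults reproduce that design.
#'
#' @param sphere_diameter Sphere diameter, mm (default 2).
#' @param volume_fraction Target total sphere volume over phantom volume
#'   (default 0.20).
#' @param density Spheres per mL (default 48); must be consistent with
#'   `volume_fraction` within 5%.
#' @param contrast_db Sphere backscatter relative to background, dB
#'   (negative = hypoechoic; default -40).
#' @param attenuation_slope Attenuation coefficient slope, dB/cm/MHz
#'   (default 0.5).
#' @param frequency Imaging frequency, MHz (default 15).
#' @param size_cm Phantom extent `(depth, width, length)` in cm; the length
#'   axis is the elevational sweep direction.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(sphere_diameter = 2, volume_fraction = 0.20,
                         density = 48, contrast_db = -40,
                         attenuation_slope = 0.5, frequency = 15,
                         size_cm = c(depth = 2, width = 1.6, length = 4)) {
  if (sphere_diameter <= 0) stop_config("sphere_diameter must be positive")
  if (contrast_db >= 0) stop_config("spheres must be hypoechoic (contrast_db < 0)")
  if (volume_fraction < 0 || volume_fraction > 0.35)
    stop_config("volume_fraction must be in [0, 0.35]")
  sphere_ml <- (pi / 6) * (sphere_diameter / 10)^3  # mL per sphere
  implied <- density * sphere_ml
  if (volume_fraction > 0 &&
      abs(implied - volume_fraction) / volume_fraction > 0.05)
    stop_config(sprintf(
      "density (%g/mL) implies volume fraction %.3f, inconsistent with %.3f",
      density, implied, volume_fraction))
  structure(
    list(sphere_diameter = sphere_diameter, volume_fraction = volume_fraction,
         density = density, contrast_db = contrast_db,
         attenuation_slope = attenuation_slope, frequency = frequency,
         size_cm = size_cm),
    class = "phantom_spec"
  )
}

#' Freehand scan profile
#'
#' Describes one cine sweep: how many frames, over what elevational
#' coverage, and how uneven the hand motion is. `speed_jitter` is the
#' fractional standard deviation of the per-step frame spacing; 0 gives the
#' uniform spacing of a mechanical guide.
#'
#' @param n_frames Number of frames (default 62).
#' @param duration Loop duration, s (default 4.13).
#' @param coverage_cm Elevational sweep extent, cm.
#' @param speed_jitter Fractional SD of the frame-to-frame spacing
#'   (default 0).
#' @param slice_thickness Elevational slice thickness, mm (default 1).
#' @return A list of class `scan_profile`.
#' @export
scan_profile <- function(n_frames = 62L, duration = 4.13, coverage_cm = 3,
                         speed_jitter = 0, slice_thickness = 1) {
  if (n_frames < 3L) stop_input("a cine sweep needs at least 3 frames")
  if (coverage_cm <= 0) stop_input("coverage must be positive")
  structure(
    list(n_frames = as.integer(n_frames), duration = duration,
         coverage_cm = coverage_cm, speed_jitter = speed_jitter,
         slice_thickness = slice_thickness),
    class = "scan_profile"
  )
}

#' Place spheres in the phantom
#'
#' Dart-throwing placement of sphere centres, uniform over the phantom box,
#' rejecting proposals closer than `min_separation` to an accepted centre.
#' The default separation of one diameter reflects solid gel spheres, which
#' can touch but not interpenetrate. Placement stops once the target volume
#' fraction is reached.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @param min_separation Minimum centre-to-centre distance, mm (default: the
#'   sphere diameter).
#' @return A list of class `phantom_truth`: `centers` tibble
#'   (`depth_mm`, `lat_mm`, `elev_mm`, `radius_mm`), `achieved_fraction`,
#'   `spec`, `seed`.
#' @export
place_spheres <- function(spec, seed = 1L,
                          min_separation = spec$sphere_diameter) {
  box <- spec$size_cm * 10  # mm: depth, width, length
  r <- spec$sphere_diameter / 2
  v_sphere <- 4 / 3 * pi * r^3
  v_box <- prod(box)
  n_target <- round(spec$volume_fraction * v_box / v_sphere)
  centers <- matrix(numeric(0), ncol = 3)
  if (n_target > 0) {
    set.seed(seed)
    max_attempts <- 400L * n_target
    min2 <- min_separation^2
    attempts <- 0L
    while (nrow(centers) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- runif(3) * box
      if (min_separation > 0 && nrow(centers) > 0L &&
          min(colSums((t(centers) - p)^2)) < min2) next
      centers <- rbind(centers, p)
    }
    if (nrow(centers) < n_target)
      stop_numeric(sprintf(
        "sphere packing failed: placed %d of %d after %d attempts",
        nrow(centers), n_target, attempts))
  }
  structure(
    list(
      centers = tibble(
        depth_mm = centers[, 1], lat_mm = centers[, 2],
        elev_mm = centers[, 3],
        radius_mm = rep(r, nrow(centers))
      ),
      achieved_fraction = nrow(centers) * v_sphere / v_box,
      spec = spec,
      seed = seed
    ),
    class = "phantom_truth"
  )
}

# 1D Gaussian kernel, unit sum
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable 2D Gaussian blur with edge replication
gauss_blur2d <- function(m, sigma_row, sigma_col) {
  kr <- gauss_kernel(sigma_row)
  kc <- gauss_kernel(sigma_col)
  pad_conv <- function(x, k) {
    # convolve each column of x with k, replicating edges
    r <- (length(k) - 1L) %/% 2L
    if (r == 0L) return(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x,
                x[rep(nrow(x), r), , drop = FALSE])
    out <- matrix(0, nrow(x), ncol(x))
    for (t in seq_along(k)) {
      out <- out + k[t] * xp[t:(t + nrow(x) - 1L), , drop = FALSE]
    }
    out
  }
  m <- pad_conv(m, kr)
  t(pad_conv(t(m), kc))
}

#' Render a freehand cine acquisition
#'
#' Image-domain B-mode simulation of one sweep over the phantom. Each frame
#' at elevational position z gets a scattering amplitude map (background 1,
#' `10^(contrast_db/20)` inside spheres, partial-volume weighted over the
#' slice thickness), two-way depth attenuation, multiplicative Rayleigh
#' speckle blurred by an anisotropic in-plane point spread function, additive
#' electronic noise, and logarithmic compression to 8-bit display values.
#' Frame positions are uniform over the coverage, perturbed by
#' `speed_jitter` and renormalised so the total extent equals the coverage.
#'
#' @param truth A [place_spheres()] result.
#' @param profile A [scan_profile()].
#' @param axial_spacing,lateral_spacing Pixel size, mm (defaults 0.14).
#' @param seed RNG seed for frame positions, speckle and noise.
#' @param psf_sigma In-plane PSF standard deviations in pixels,
#'   `c(axial, lateral)`; axial < lateral as in a focused linear array.
#'   Defaults correspond to roughly 0.16 mm axial and 0.36 mm lateral
#'   resolution (FWHM) at 0.14 mm pixels, typical of a 15 MHz linear array.
#' @param noise_sd Additive electronic noise SD on the amplitude scale
#'   (constant with depth, so deep-region SNR falls).
#' @param dynamic_range Displayed dynamic range, dB (default 60).
#' @param x_ref Amplitude mapped to the top of the display range.
#' @param tgc Apply exact inverse time-gain compensation for the attenuation
#'   (default FALSE).
#' @param n_subslices Elevational quadrature points across the slice
#'   thickness for partial-volume weighting (default 5).
#' @return A list: `volume` ([cine_volume()]), `truth` (the input truth with
#'   `frame_positions_mm` added).
#' @export
render_acquisition <- function(truth, profile, axial_spacing = 0.14,
                               lateral_spacing = 0.14, seed = 1L,
                               psf_sigma = c(axial = 0.5, lateral = 1.1),
                               noise_sd = 0.005, dynamic_range = 60,
                               x_ref = 1.5, tgc = FALSE, n_subslices = 5L) {
  spec <- truth$spec
  box <- spec$size_cm * 10
  coverage <- profile$coverage_cm * 10
  if (coverage > box[3])
    stop_input("coverage exceeds the phantom length")
  nf <- profile$n_frames
  set.seed(seed)

  # frame positions: uniform steps perturbed by speed_jitter, renormalised
  steps <- rep(1, nf - 1L) + profile$speed_jitter * rnorm(nf - 1L)
  steps <- pmax(steps, 0.05)
  pos <- c(0, cumsum(steps))
  pos <- pos / pos[nf] * coverage + (box[3] - coverage) / 2

  nr <- floor(box[1] / axial_spacing)
  nc <- floor(box[2] / lateral_spacing)
  depth_mm <- (seq_len(nr) - 0.5) * axial_spacing
  lat_mm <- (seq_len(nc) - 0.5) * lateral_spacing
  c_amp <- 10^(spec$contrast_db / 20)
  att <- 10^(-2 * spec$attenuation_slope * spec$frequency *
               (depth_mm / 10) / 20)
  if (tgc) att <- att * 0 + 1  # exact inverse gain curve cancels attenuation

  ctr <- truth$centers
  st <- profile$slice_thickness
  sub_off <- if (n_subslices > 1L)
    seq(-st / 2, st / 2, length.out = n_subslices) else 0

  vox <- array(0, dim = c(nr, nc, nf))
  for (f in seq_len(nf)) {
    z <- pos[f]
    inside_n <- matrix(0L, nr, nc)
    if (nrow(ctr) > 0) {
      active <- abs(ctr$elev_mm - z) <= ctr$radius_mm + st / 2
      for (s in which(active)) {
        for (dz0 in sub_off) {
          dz <- ctr$elev_mm[s] - (z + dz0)
          r2 <- ctr$radius_mm[s]^2 - dz^2
          if (r2 <= 0) next
          re <- sqrt(r2)
          ri <- which(abs(depth_mm - ctr$depth_mm[s]) <= re)
          ci <- which(abs(lat_mm - ctr$lat_mm[s]) <= re)
          if (length(ri) == 0L || length(ci) == 0L) next
          dmat <- outer((depth_mm[ri] - ctr$depth_mm[s])^2,
                        (lat_mm[ci] - ctr$lat_mm[s])^2, `+`)
          hit <- dmat <= r2
          inside_n[ri, ci][hit] <- inside_n[ri, ci][hit] + 1L
        }
      }
    }
    frac <- inside_n / length(sub_off)
    amp <- (1 - frac) + frac * c_amp
    amp <- amp * att
    speckle <- matrix(sqrt(2 / pi) * sqrt(-2 * log(runif(nr * nc))), nr, nc)
    field <- gauss_blur2d(amp * speckle, psf_sigma[1], psf_sigma[2])
    field <- field + rnorm(nr * nc, sd = noise_sd)
    db <- 20 * log10(pmax(field, 1e-12) / x_ref)
    y <- 255 * (db + dynamic_range) / dynamic_range
    vox[, , f] <- round(pmin(pmax(y, 0), 255))
  }

  truth$frame_positions_mm <- pos
  truth$slice_thickness_mm <- st
  vol <- cine_volume(vox, axial_spacing, lateral_spacing,
                     frame_rate = nf / profile$duration,
                     acquisition_id = sprintf("sim-seed%d", seed))
  list(volume = vol, truth = truth)
}

#' Simulate a complete acquisition
#'
#' Convenience wrapper: [place_spheres()] then [render_acquisition()]. The
#' placement seed and the rendering seed are derived from `seed` so that
#' repeated sweeps of the *same* phantom can reuse one placement with
#' different rendering seeds via `placement_seed`.
#'
#' @param spec A [phantom_spec()].
#' @param profile A [scan_profile()].
#' @param seed RNG seed for rendering.
#' @param placement_seed RNG seed for sphere placement (defaults to `seed`).
#' @param ... Passed to [render_acquisition()].
#' @return See [render_acquisition()].
#' @export
simulate_acquisition <- function(spec, profile, seed = 1L,
                                 placement_seed = seed, ...) {
  truth <- place_spheres(spec, seed = placement_seed)
  render_acquisition(truth, profile, seed = seed, ...)
}

#' Analytic per-frame cross-section areas of every sphere
#'
#' From the ground truth alone: the in-plane cross-section area of sphere
#' `i` in the frame at elevational position `z` is
#' `pi * (r^2 - (z - z_i)^2)` where the frame plane intersects the sphere.
#' Used to study the freehand asymmetry mechanism (the frame of maximum
#' area versus the area-weighted centroid frame) without rendering.
#'
#' @param truth A [place_spheres()] result with `frame_positions_mm`.
#' @return A tibble: `sphere`, `frame`, `area_mm2` (intersected frames only).
#' @export
truth_cross_sections <- function(truth) {
  pos <- truth$frame_positions_mm
  if (is.null(pos)) stop_input("truth carries no frame positions; render first")
  ctr <- truth$centers
  purrr::map_dfr(seq_len(nrow(ctr)), function(i) {
    dz2 <- (pos - ctr$elev_mm[i])^2
    hit <- dz2 < ctr$radius_mm[i]^2
    if (!any(hit)) return(NULL)
    tibble(sphere = i, frame = which(hit),
           area_mm2 = pi * (ctr$radius_mm[i]^2 - dz2[hit]))
  })
}

#' Score an analysis against the simulator ground truth
#'
#' Greedy one-to-one matching of eligible sphere measurements to the true
#' sphere centres. Only interior truth spheres count: spheres clipped by the
#' analyzed depth/lateral extent or reaching past the first or last frame
#' cannot be recovered by construction (their maximum cross-section lies
#' outside the acquired stack, mirroring the analysis' own edge exclusion).
#'
#' @param analysis An [analyze()] result for a rendered acquisition.
#' @param truth The truth returned by [render_acquisition()] (with
#'   `frame_positions_mm`).
#' @param tolerance_mm Maximum centre distance for a match (default half the
#'   sphere diameter).
#' @return A list: `recall`, `n_truth_interior`, `n_matched`, `n_eligible`,
#'   and `matches` (tibble of truth index, measurement label, distance).
#' @export
truth_recovery <- function(analysis, truth,
                           tolerance_mm = truth$spec$sphere_diameter / 2) {
  x0 <- analysis$x0
  pos <- truth$frame_positions_mm
  if (is.null(pos)) stop_input("truth carries no frame positions; render first")
  d <- dim(x0$voxels)
  ctr <- truth$centers
  r <- ctr$radius_mm
  # the rendered support extends half a slice thickness past the sphere
  # along the sweep, so a sphere that close to the boundary frames is
  # edge-flagged by the analysis and cannot count as recoverable
  re <- r + (truth$slice_thickness_mm %||% 0) / 2
  depth_lo <- x0$depth_offset
  depth_hi <- x0$depth_offset + d[1] * x0$axial_spacing
  width <- d[2] * x0$lateral_spacing
  interior <- ctr$depth_mm >= depth_lo + r & ctr$depth_mm <= depth_hi - r &
    ctr$lat_mm >= r & ctr$lat_mm <= width - r &
    ctr$elev_mm >= pos[1] + re & ctr$elev_mm <= pos[length(pos)] - re
  idx_int <- which(interior)

  el <- analysis$spheres[analysis$spheres$eligible, , drop = FALSE]
  matches <- tibble(truth_index = integer(0), label = integer(0),
                    distance_mm = numeric(0))
  if (nrow(el) > 0 && length(idx_int) > 0) {
    meas <- cbind(
      depth = x0$depth_offset + (el$yi - 0.5) * x0$axial_spacing,
      lat = (el$xi - 0.5) * x0$lateral_spacing,
      elev = pos[el$zi]
    )
    tru <- cbind(ctr$depth_mm[idx_int], ctr$lat_mm[idx_int],
                 ctr$elev_mm[idx_int])
    dmat <- outer(tru[, 1], meas[, 1], `-`)^2 +
      outer(tru[, 2], meas[, 2], `-`)^2 +
      outer(tru[, 3], meas[, 3], `-`)^2
    dmat <- sqrt(dmat)
    # greedy nearest-pair assignment
    while (TRUE) {
      m <- which.min(dmat)
      if (length(m) == 0L || min(dmat, na.rm = TRUE) > tolerance_mm) break
      ti <- (m - 1L) %% nrow(dmat) + 1L
      mi <- (m - 1L) %/% nrow(dmat) + 1L
      matches <- dplyr::bind_rows(matches, tibble(
        truth_index = idx_int[ti], label = el$label[mi],
        distance_mm = dmat[ti, mi]))
      dmat[ti, ] <- Inf
      dmat[, mi] <- Inf
      if (all(is.infinite(dmat))) break
    }
  }
  list(
    recall = if (length(idx_int)) nrow(matches) / length(idx_int) else NA_real_,
    n_truth_interior = length(idx_int),
    n_matched = nrow(matches),
    n_eligible = nrow(el),
    matches = matches
  )
}
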