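#' Preprocessing configuration
#'
#' Parameters for the two-step preprocessing that produces the segmentation
#' volume: 3D non-local-means denoising followed by B-spline bias-field
#' correction. The denoise strength defaults to one eighth of the global
#' intensity standard deviation of the input volume.
#'
#' @param search_window Full width of the isotropic NLM search window in
#'   pixels (odd, default 9).
#' @param patch_size Full width of the NLM comparison patch in pixels
#'   (odd, default 3).
#' @param strength_divisor Denoise strength is `sd(x0) / strength_divisor`
#'   (default 8) unless `denoise_strength` overrides it.
#' @param denoise_strength Optional explicit strength in intensity units.
#' @param control_points B-spline control points for the bias field along
#'   (depth, lateral, elevational); default `c(8, 4, 4)` puts most of the
#'   flexibility along depth where attenuation acts.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(search_window = 9L, patch_size = 3L,
                              strength_divisor = 8, denoise_strength = NULL,
                              control_points = c(8L, 4L, 4L)) {
  search_window <- as.integer(search_window)
  patch_size <- as.integer(patch_size)
  if (search_window %% 2L == 0L || patch_size %% 2L == 0L)
    stop_config("`search_window` and `patch_size` must be odd")
  if (search_window <= patch_size)
    stop_config("`search_window` must exceed `patch_size`")
  if (length(control_points) != 3L || any(control_points < 4L))
    stop_config("`control_points` must be 3 counts, each >= 4 (cubic B-splines)")
  structure(
    list(search_window = search_window, patch_size = patch_size,
         strength_divisor = strength_divisor,
         denoise_strength = denoise_strength,
         control_points = as.integer(control_points)),
    class = "preprocess_config"
  )
}

#' 3D non-local-means denoising
#'
#' Replaces every voxel by a patch-similarity-weighted average of the voxels
#' in its search window. Weights are `exp(-D / h^2)` where `D` is the mean
#' squared difference between the comparison patches and `h` is the denoise
#' strength. Deterministic; the window is clipped at volume borders.
#'
#' @param x0 A [cine_volume()].
#' @param cfg A [preprocess_config()].
#' @return A denoised [cine_volume()] of identical shape and spacing.
#' @export
nlm_denoise <- function(x0, cfg = preprocess_config()) {
  stopifnot(inherits(x0, "cine_volume"))
  h <- cfg$denoise_strength %||% (sd(x0$voxels) / cfg$strength_divisor)
  out <- x0
  if (h <= 0) return(out)  # constant volume: nothing to denoise
  out$voxels <- nlm3d_cpp(
    x0$voxels, dim(x0$voxels),
    search_radius = (cfg$search_window - 1L) %/% 2L,
    patch_radius = (cfg$patch_size - 1L) %/% 2L,
    h = h
  )
  out
}

# cubic B-spline basis over 1..n with k basis functions
bspline_basis <- function(n, k) {
  splines::bs(seq_len(n), df = k, intercept = TRUE, degree = 3)
}

# least-squares fit of a separable tensor-product B-spline surface to a 3D
# array; the complete-grid problem factorises mode by mode
tensor_spline_fit <- function(y, k) {
  d <- dim(y)
  bases <- lapply(seq_along(d), function(a) bspline_basis(d[a], k[a]))
  proj <- lapply(bases, function(B) solve(crossprod(B), t(B)))
  ttm <- function(a, m, mode) {
    d <- dim(a)
    perm <- c(mode, setdiff(seq_along(d), mode))
    am <- matrix(aperm(a, perm), nrow = d[mode])
    res <- m %*% am
    d2 <- d
    d2[mode] <- nrow(m)
    aperm(array(res, dim = d2[perm]), order(perm))
  }
  coefs <- y
  for (mode in seq_along(d)) coefs <- ttm(coefs, proj[[mode]], mode)
  fit <- coefs
  for (mode in seq_along(d)) fit <- ttm(fit, bases[[mode]], mode)
  fit
}

#' Bias-field (inhomogeneity) correction
#'
#' Estimates a smooth multiplicative bias field on a coarse B-spline control
#' grid in the log-intensity domain, divides it out, and rescales so the
#' global mean intensity is preserved. The fit must not chase the hypoechoic
#' spheres (a fifth of the voxels), so it is made robust to them: after each
#' least-squares pass, voxels whose log residual is below `-2` times the
#' background residual scale (estimated by mirroring the non-negative
#' residuals, which belong to the bright, dominant background) are imputed
#' from the current fit and the surface is refitted. Dark lesions thus stop
#' deflecting the field while the background shading drives it.
#'
#' @param x A positive [cine_volume()] (zero voxels are shifted by a small
#'   epsilon before the log).
#' @param cfg A [preprocess_config()].
#' @param robust_iterations Impute-and-refit passes (default 4).
#' @return A bias-corrected [cine_volume()] with strictly positive voxels.
#' @export
bias_correct <- function(x, cfg = preprocess_config(),
                         robust_iterations = 4L) {
  stopifnot(inherits(x, "cine_volume"))
  v <- x$voxels
  mu <- mean(v)
  if (mu <= 0) stop_numeric("volume is non-positive; cannot fit a multiplicative bias field")
  eps <- 1e-3 * mu
  v[v < eps] <- eps
  logv <- log(v)
  z <- logv
  fit <- tensor_spline_fit(z, cfg$control_points)
  for (it in seq_len(robust_iterations)) {
    resid <- logv - fit
    upper <- resid[resid >= 0]
    if (length(upper) == 0L) break
    scale <- sqrt(mean(upper^2))
    if (scale <= 0) break
    dark <- resid < -2 * scale
    if (!any(dark)) break
    z <- ifelse(dark, fit, logv)
    fit <- tensor_spline_fit(z, cfg$control_points)
  }
  field <- exp(fit - mean(fit))  # smooth, positive, geometric mean 1
  out_v <- v / field
  out_v <- out_v * (mean(v) / mean(out_v))
  out <- x
  out$voxels <- out_v
  out
}

#' Run the full preprocessing chain
#'
#' Non-local-means denoising followed by bias-field correction, in that
#' order. The result is used only for segmentation; all LSNR statistics are
#' computed on the raw cropped volume.
#'
#' @inheritParams bias_correct
#' @return The segmentation volume as a [cine_volume()].
#' @export
preprocess <- function(x, cfg = preprocess_config()) {
  bias_correct(nlm_denoise(x, cfg), cfg)
}
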