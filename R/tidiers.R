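#' Tidy the per-sphere table of an analysis
#' @param x An [analyze()] result.
#' @param ... Unused.
#' @return The per-sphere tibble.
#' @export
tidy.rhsp_analysis <- function(x, ...) {
  x$spheres
}

#' One-row summary of an analysis
#'
#' Peak LSNR is the most negative slab mean (hypoechoic spheres: larger
#' magnitude means better detectability).
#'
#' @param x An [analyze()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_eligible`, `n_measured`, `peak_lsnr`,
#'   `peak_depth_cm`, `mean_equiv_diameter_mm`.
#' @export
glance.rhsp_analysis <- function(x, ...) {
  sp <- x$spheres
  measured <- sp[!is.na(sp$lsnr), , drop = FALSE]
  cv <- x$curve
  peak <- if (nrow(cv) > 0) which.min(cv$lsnr) else integer(0)
  el <- sp[sp$eligible, , drop = FALSE]
  tibble(
    n_eligible = sum(sp$eligible),
    n_measured = nrow(measured),
    peak_lsnr = if (length(peak)) cv$lsnr[peak] else NA_real_,
    peak_depth_cm = if (length(peak)) cv$depth_cm[peak] else NA_real_,
    mean_equiv_diameter_mm = if (nrow(el)) mean(2 * sqrt(el$si_mm2 / pi))
                             else NA_real_
  )
}

#' Tidy a variability report
#' @param x A [variability()] result.
#' @param ... Unused.
#' @return The per-depth tibble of RSDs.
#' @export
tidy.rhsp_variability <- function(x, ...) {
  x$per_depth
}

#' One-row summary of a variability report
#' @param x A [variability()] result.
#' @param ... Unused.
#' @return A one-row tibble of the overall (and, if present, single-depth)
#'   RSDs in percent.
#' @export
glance.rhsp_variability <- function(x, ...) {
  tibble(
    overall_rsd_lsnr = x$overall_rsd_lsnr,
    overall_rsd_counts = x$overall_rsd_counts,
    point_rsd_lsnr = x$point_rsd_lsnr %||% NA_real_,
    point_rsd_counts = x$point_rsd_counts %||% NA_real_,
    at_depth = x$at_depth %||% NA_real_,
    n_acquisitions = x$n_acquisitions
  )
}
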