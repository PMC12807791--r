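#' Plot an LSNR-versus-depth curve
#'
#' Slab means with standard-error bars; more negative is more detectable.
#'
#' @param object An [lsnr_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhsp_lsnr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_cm, y = .data$lsnr)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lsnr - .data$epsilon,
                   ymax = .data$lsnr + .data$epsilon),
      width = 0.05, na.rm = TRUE
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Depth (cm)", y = "LSNR",
                  title = "LSNR vs. depth") +
    ggplot2::theme_minimal()
}

#' Plot sphere counts versus depth
#' @param curve An [lsnr_curve()] tibble.
#' @return A ggplot.
#' @export
plot_sphere_counts <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$depth_cm, y = .data$n_spheres)) +
    ggplot2::geom_col(width = diff(attr(curve, "edges"))[1] * 0.9) +
    ggplot2::labs(x = "Depth (cm)", y = "Spheres detected",
                  title = "Sphere count vs. depth") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rhsp_analysis <- function(object, ...) {
  autoplot(object$curve, ...)
}
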