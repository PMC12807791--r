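#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one nested list that
#' round-trips losslessly through YAML/JSON. Defaults are the values used
#' throughout: 9/3-pixel NLM window/patch at strength sd/8, an 8x4x4
#' bias-field control grid, 10 threshold slabs at mu - 2 sigma with 256
#' histogram bins, 3 opening iterations, 5-voxel seed separation, a
#' [0.5, 1.25] x (pi d^2/4) area band for d = 2 mm spheres, and a 25-slab
#' LSNR curve.
#'
#' @param ... Named overrides of nested fields, e.g.
#'   `threshold = list(n_slabs = 8)` (partial lists are merged over the
#'   defaults).
#' @return A nested list of class `rhsp_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    fov = list(min_offset = 50L, trim_rows = 10L, overlay_value = 0),
    nlm = list(search_window = 9L, patch_size = 3L, strength_divisor = 8),
    bias = list(control_points = c(8L, 4L, 4L)),
    threshold = list(n_slabs = 10L, k_sigma = 2, n_bins = 256L),
    morphology = list(opening_iterations = 3L),
    separation = list(min_seed_distance = 5),
    spheres = list(diameter_mm = 2, alpha1 = 0.5, alpha2 = 1.25,
                   exclude_edge_spheres = TRUE),
    lsnr = list(erosion = 3L, dilation = 1L, min_background_voxels = 100L,
                n_curve_slabs = 25L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("rhsp_config", "list"))
}

#' Read / write an analysis configuration
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return For `read_config`, an `rhsp_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config An `rhsp_config`.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Field-of-view extraction, denoising, bias correction, depth-adaptive
#' thresholding, watershed sphere separation, area filtering, per-sphere
#' LSNR measurement on the raw volume, and the LSNR-versus-depth curve.
#' Fully deterministic given the input and configuration.
#'
#' @param input A [cine_volume()] or any source [read_cine()] accepts.
#' @param config An [analysis_config()].
#' @param extract Run [extract_fov()] on the input (default TRUE; set FALSE
#'   when the input is already the cropped analysis volume).
#' @param ... Passed to [read_cine()] when `input` is a path.
#' @return An object of class `rhsp_analysis`: a list with `spheres` (tibble
#'   of every labelled object with measurements), `curve`
#'   ([lsnr_curve()] tibble), `thresholds`, `config`, `x0`, `m0`, `m2`, and
#'   `depth_range_cm`.
#' @export
analyze <- function(input, config = analysis_config(), extract = TRUE, ...) {
  vol <- if (inherits(input, "cine_volume")) input else read_cine(input, ...)
  x0 <- if (extract) {
    extract_fov(vol, config$fov$min_offset, config$fov$trim_rows,
                config$fov$overlay_value)
  } else {
    vol
  }
  pcfg <- preprocess_config(
    search_window = config$nlm$search_window,
    patch_size = config$nlm$patch_size,
    strength_divisor = config$nlm$strength_divisor,
    control_points = config$bias$control_points
  )
  x1 <- bias_correct(nlm_denoise(x0, pcfg), pcfg)
  thr <- slab_thresholds(x1, config$threshold$n_slabs,
                         config$threshold$n_bins, config$threshold$k_sigma)
  masks <- segment(x1, thr, config$morphology$opening_iterations)
  m2 <- split_connected(masks$m1, config$separation$min_seed_distance)
  spheres <- max_cross_sections(m2, x0)
  spheres <- area_filter(spheres, config$spheres$diameter_mm,
                         config$spheres$alpha1, config$spheres$alpha2,
                         config$spheres$exclude_edge_spheres)
  spheres <- measure_lsnr(x0, masks$m0, m2, spheres,
                          config$spheres$diameter_mm,
                          config$lsnr$erosion, config$lsnr$dilation,
                          config$lsnr$min_background_voxels)
  depth_range <- c(x0$depth_offset,
                   x0$depth_offset + dim(x0$voxels)[1] * x0$axial_spacing) / 10
  curve <- lsnr_curve(spheres, depth_range, config$lsnr$n_curve_slabs)
  structure(
    list(spheres = spheres, curve = curve, thresholds = thr,
         config = config, x0 = x0, m0 = masks$m0, m2 = m2,
         depth_range_cm = depth_range),
    class = "rhsp_analysis"
  )
}

#' Re-measure LSNR on a transformed raw volume
#'
#' Keeps the segmentation (masks and sphere table) of an existing analysis
#' fixed and recomputes every intensity statistic — sphere signal,
#' background signal and noise, LSNR, curve — on a transformed copy of the
#' raw volume. This isolates how display transforms (gain, dynamic-range
#' clipping) propagate into the LSNR, which is exactly where the raw volume
#' enters the computation.
#'
#' @param analysis An [analyze()] result.
#' @param transform Function applied to the raw voxel array.
#' @return A new `rhsp_analysis` with remeasured spheres and curve.
#' @export
remeasure <- function(analysis, transform = identity) {
  x0 <- analysis$x0
  x0$voxels <- transform(x0$voxels)
  cfg <- analysis$config
  spheres <- dplyr::select(analysis$spheres, -dplyr::any_of(
    c("Sf", "Sb", "sigma_b", "lsnr", "drop_reason")))
  spheres <- measure_lsnr(x0, analysis$m0, analysis$m2, spheres,
                          cfg$spheres$diameter_mm, cfg$lsnr$erosion,
                          cfg$lsnr$dilation, cfg$lsnr$min_background_voxels)
  out <- analysis
  out$x0 <- x0
  out$spheres <- spheres
  out$curve <- lsnr_curve(spheres, analysis$depth_range_cm,
                          cfg$lsnr$n_curve_slabs)
  out
}

#' @export
print.rhsp_analysis <- function(x, ...) {
  n_el <- sum(x$spheres$eligible)
  cat(sprintf("<rhsp_analysis> %d labelled objects, %d eligible spheres\n",
              nrow(x$spheres), n_el))
  g <- glance(x)
  if (!is.na(g$peak_lsnr))
    cat(sprintf("  peak LSNR %.2f at %.2f cm; depth range %.2f-%.2f cm\n",
                g$peak_lsnr, g$peak_depth_cm,
                x$depth_range_cm[1], x$depth_range_cm[2]))
  invisible(x)
}

#' Persist an analysis as CSV/JSON
#'
#' Writes `spheres.csv` (per-sphere table), `curve.csv` (per-slab curve),
#' `summary.json` (headline numbers plus the resolved configuration) into
#' `dir`. Every number in the summary is recomputable from the CSVs.
#'
#' @param analysis An [analyze()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(analysis$spheres, file.path(dir, "spheres.csv"),
            row.names = FALSE)
  curve_out <- as.data.frame(analysis$curve)
  write.csv(curve_out, file.path(dir, "curve.csv"), row.names = FALSE)
  g <- glance(analysis)
  summary <- list(
    n_objects = nrow(analysis$spheres),
    n_eligible = g$n_eligible,
    n_measured = g$n_measured,
    peak_lsnr = g$peak_lsnr,
    peak_depth_cm = g$peak_depth_cm,
    depth_range_cm = analysis$depth_range_cm,
    curve_edges_cm = as.numeric(attr(analysis$curve, "edges")),
    config = unclass(analysis$config)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a persisted analysis
#' @param dir Directory written by [write_analysis()].
#' @return An `rhsp_analysis` (tables only; volumes are not persisted).
#' @export
read_analysis <- function(dir) {
  spheres <- as_tibble(read.csv(file.path(dir, "spheres.csv")))
  curve <- as_tibble(read.csv(file.path(dir, "curve.csv")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  edges <- summ$curve_edges_cm
  curve <- structure(curve, edges = edges, n_slabs = length(edges) - 1L,
                     class = c("rhsp_lsnr_curve", class(curve)))
  structure(
    list(spheres = spheres, curve = curve,
         config = do.call(analysis_config, as.list(summ$config)),
         depth_range_cm = summ$depth_range_cm),
    class = "rhsp_analysis"
  )
}

#' Compare repeated acquisitions
#'
#' Repeatability report across two or more analyses of the same depth
#' setting: overall and single-depth relative standard deviations of the
#' LSNR and sphere-count curves.
#'
#' @param analyses A list of [analyze()] results (or directories written by
#'   [write_analysis()]).
#' @param at_depth Depth (cm) for the single-point report (default 2.2).
#' @return A [variability()] report.
#' @export
compare_acquisitions <- function(analyses, at_depth = 2.2) {
  if (length(analyses) < 2L)
    stop_input("comparison needs at least two analyses")
  analyses <- lapply(analyses, function(a) {
    if (is.character(a)) read_analysis(a) else a
  })
  curves <- lapply(analyses, function(a) a$curve)
  variability(curves, at_depth = at_depth)
}
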