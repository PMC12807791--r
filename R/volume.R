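#' Cine-loop volume container
#'
#' A `cine_volume` holds a stack of B-mode frames as a 3D array indexed
#' (depth row, lateral column, elevational frame) together with the physical
#' in-plane pixel spacing. Elevational spacing is deliberately absent: with
#' freehand sweeps the frame-to-frame distance is unknown and non-uniform,
#' so all elevational operations downstream work in frame units.
#'
#' @param voxels 3D numeric array of non-negative intensities,
#'   `(depth, lateral, frame)`.
#' @param axial_spacing Axial (depth) pixel size in mm.
#' @param lateral_spacing Lateral pixel size in mm.
#' @param depth_offset Physical depth of the first retained row, mm.
#' @param frame_rate Optional acquisition frame rate, frames/s.
#' @param acquisition_id Free-text identifier.
#'
#' @return An object of class `cine_volume`.
#' @export
cine_volume <- function(voxels, axial_spacing, lateral_spacing,
                        depth_offset = 0, frame_rate = NULL,
                        acquisition_id = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_input("`voxels` must be a 3D array (depth, lateral, frame)")
  if (dim(voxels)[3] < 3L)
    stop_input("a cine volume needs at least 3 frames")
  if (anyNA(voxels) || min(voxels) < 0)
    stop_input("voxel intensities must be non-negative and non-missing")
  if (!is.numeric(axial_spacing) || length(axial_spacing) != 1L ||
      is.na(axial_spacing) || axial_spacing <= 0)
    stop_config("`axial_spacing` must be a single positive number (mm)")
  if (!is.numeric(lateral_spacing) || length(lateral_spacing) != 1L ||
      is.na(lateral_spacing) || lateral_spacing <= 0)
    stop_config("`lateral_spacing` must be a single positive number (mm)")
  structure(
    list(
      voxels = voxels,
      axial_spacing = axial_spacing,
      lateral_spacing = lateral_spacing,
      depth_offset = depth_offset,
      frame_rate = frame_rate,
      acquisition_id = acquisition_id
    ),
    class = "cine_volume"
  )
}

#' @export
print.cine_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<cine_volume> %d rows x %d cols x %d frames\n  pixel %.4g x %.4g mm, depth offset %.3g mm%s\n",
    d[1], d[2], d[3], x$axial_spacing, x$lateral_spacing, x$depth_offset,
    if (nzchar(x$acquisition_id)) paste0("\n  id: ", x$acquisition_id) else ""
  ))
  invisible(x)
}

#' @export
dim.cine_volume <- function(x) dim(x$voxels)

#' Physical depth (cm) of each row of a volume
#' @param volume A [cine_volume()].
#' @return Numeric vector, one depth per row, cm.
#' @export
row_depths_cm <- function(volume) {
  (volume$depth_offset + (seq_len(dim(volume$voxels)[1]) - 1) *
     volume$axial_spacing) / 10
}

read_frame_file <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop_input(paste0("unsupported frame format: ", path))
  )
  if (length(dim(img)) == 3L) {
    # grayscale stored with channels; require identical channels
    ch <- dim(img)[3]
    for (c2 in seq_len(ch - 1L) + 1L) {
      if (max(abs(img[, , 1] - img[, , c2])) > 0)
        stop_input(paste0("frame is not grayscale: ", path))
    }
    img <- img[, , 1]
  }
  if (ext == "png") {
    # readPNG rescales to [0,1]; restore stored integer code values
    img <- round(img * (2^bit_depth - 1))
  }
  img
}

#' Read a cine loop into a volume
#'
#' Accepts a directory of same-shape single-frame PNG/TIFF images (stacked
#' in lexicographic filename order), an ordered character vector of frame
#' paths, a NIfTI volume, a list of matrices, or a 3D array. Frames are
#' stacked along the elevational axis in acquisition order with intensities
#' preserved bit-exactly.
#'
#' @param source Directory, file path(s), list of matrices, or 3D array.
#' @param axial_spacing,lateral_spacing Pixel spacing in mm. Required unless
#'   the source carries spacing metadata (NIfTI).
#' @param bit_depth Bit depth assumed for PNG frames (8 or 16).
#' @param acquisition_id Identifier stored on the volume.
#' @return A [cine_volume()].
#' @export
read_cine <- function(source, axial_spacing = NULL, lateral_spacing = NULL,
                      bit_depth = 8L, acquisition_id = "") {
  frames <- NULL
  if (is.array(source) && length(dim(source)) == 3L) {
    vox <- source
  } else if (is.list(source) && !is.data.frame(source)) {
    frames <- source
  } else if (is.character(source)) {
    if (length(source) == 1L && dir.exists(source)) {
      paths <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(paths) == 0L)
        stop_input(paste0("no PNG/TIFF frames found in ", source))
      paths <- paths[order(basename(paths))]
      frames <- lapply(paths, read_frame_file, bit_depth = bit_depth)
    } else if (length(source) == 1L &&
               grepl("\\.nii(\\.gz)?$", source, ignore.case = TRUE)) {
      if (!file.exists(source))
        stop_input(paste0("volume not found: ", source))
      nii <- RNifti::readNifti(source)
      vox <- unclass(nii)[, , , drop = FALSE]
      pd <- RNifti::pixdim(nii)
      if (is.null(axial_spacing)) axial_spacing <- pd[1]
      if (is.null(lateral_spacing)) lateral_spacing <- pd[2]
    } else {
      if (!all(file.exists(source)))
        stop_input("frame path(s) not found")
      frames <- lapply(source, read_frame_file, bit_depth = bit_depth)
    }
  } else {
    stop_input("unsupported cine source")
  }

  if (!is.null(frames)) {
    if (length(frames) < 3L)
      stop_input("a cine loop needs at least 3 frames")
    shp <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), shp),
                 logical(1))
    if (!all(ok))
      stop_input("all frames must be matrices of identical shape")
    vox <- array(as.numeric(unlist(frames, use.names = FALSE)),
                 dim = c(shp, length(frames)))
  }

  if (is.null(axial_spacing) || is.null(lateral_spacing) ||
      !isTRUE(axial_spacing > 0) || !isTRUE(lateral_spacing > 0))
    stop_config("pixel spacing missing or zero: supply `axial_spacing` and `lateral_spacing` (mm)")

  cine_volume(vox, axial_spacing, lateral_spacing,
              acquisition_id = acquisition_id)
}

#' Write a volume as NIfTI with spacing metadata
#' @param volume A [cine_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(volume$axial_spacing, volume$lateral_spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

scan_zero_line <- function(is_zero, center, min_offset, n, direction) {
  # first all-zero line scanning outward from center +/- min_offset;
  # returns the index of that zero line or 0/n+1 if none found
  if (direction < 0) {
    from <- center - min_offset
    if (from < 1) return(0L)
    hits <- which(is_zero[seq_len(from)])
    if (length(hits) == 0L) return(0L)
    max(hits)
  } else {
    from <- center + min_offset
    if (from > n) return(n + 1L)
    hits <- which(is_zero[from:n])
    if (length(hits) == 0L) return(n + 1L)
    from + min(hits) - 1L
  }
}

#' Extract the analysis field of view
#'
#' Strips the overlay surrounding the imaging field of view and removes the
#' unreliable first and last depth rows, producing the raw analysis volume
#' (the volume every LSNR statistic is later computed on). For each in-plane
#' direction the crop is placed at the first row/column that is overlay-valued
#' in every frame, scanning outward starting `min_offset` pixels from the
#' frame centre; if none is found the frame edge is kept.
#'
#' @param volume A [cine_volume()].
#' @param min_offset Pixels from the frame centre at which the outward scan
#'   starts (default 50), so anatomy-free central lines cannot trigger a crop.
#' @param trim_rows Rows removed from top and bottom of the cropped volume
#'   (default 10), where surface reflections and poor signal dominate.
#' @param overlay_value Intensity of the overlay padding (default 0).
#' @return A cropped [cine_volume()] with `depth_offset` updated so the
#'   physical depth of every retained row is preserved.
#' @export
extract_fov <- function(volume, min_offset = 50, trim_rows = 10,
                        overlay_value = 0) {
  vox <- volume$voxels
  d <- dim(vox)
  # a line is overlay iff it equals overlay_value in every frame
  nonzero <- vox != overlay_value
  row_any <- apply(nonzero, 1, any)
  col_any <- apply(nonzero, 2, any)
  if (!any(row_any)) stop_input("volume is entirely overlay-valued")

  rc <- ceiling(d[1] / 2)
  cc <- ceiling(d[2] / 2)
  top    <- scan_zero_line(!row_any, rc, min_offset, d[1], -1L)
  bottom <- scan_zero_line(!row_any, rc, min_offset, d[1], +1L)
  left   <- scan_zero_line(!col_any, cc, min_offset, d[2], -1L)
  right  <- scan_zero_line(!col_any, cc, min_offset, d[2], +1L)

  r0 <- top + 1L + as.integer(trim_rows)
  r1 <- bottom - 1L - as.integer(trim_rows)
  c0 <- left + 1L
  c1 <- right - 1L
  if (r1 - r0 + 1L < 32L || c1 - c0 + 1L < 32L)
    stop_input("overlay detection consumed the image: FOV smaller than 32x32")

  out <- volume
  out$voxels <- vox[r0:r1, c0:c1, , drop = FALSE]
  out$depth_offset <- volume$depth_offset + (r0 - 1L) * volume$axial_spacing
  out
}
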