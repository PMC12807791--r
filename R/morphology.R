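# Binary morphology with cross-shaped structuring elements, implemented with
# array shifts (outside the volume counts as background).

erode3d_once <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ]    <- out[-1, , ]    & m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
  out[, -1, ]    <- out[, -1, ]    & m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
  out[, , -1]    <- out[, , -1]    & m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
  out[1, , ] <- FALSE
  out[d[1], , ] <- FALSE
  out[, 1, ] <- FALSE
  out[, d[2], ] <- FALSE
  out[, , 1] <- FALSE
  out[, , d[3]] <- FALSE
  out
}

dilate3d_once <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ]    <- out[-1, , ]    | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ]    <- out[, -1, ]    | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1]    <- out[, , -1]    | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Binary erosion, 6-connected 3D cross
#' @param m Logical 3D array.
#' @param iterations Number of erosion passes.
#' @return Logical array of the same shape.
#' @export
binary_erode3d <- function(m, iterations = 1L) {
  for (it in seq_len(iterations)) m <- erode3d_once(m)
  m
}

#' Binary dilation, 6-connected 3D cross
#' @inheritParams binary_erode3d
#' @return Logical array of the same shape.
#' @export
binary_dilate3d <- function(m, iterations = 1L) {
  for (it in seq_len(iterations)) m <- dilate3d_once(m)
  m
}

#' Binary opening, 6-connected 3D cross
#'
#' `iterations` erosions followed by the same number of dilations; removes
#' speckle-sized foreground without growing the mask (the result is always a
#' subset of the input).
#' @inheritParams binary_erode3d
#' @return Logical array of the same shape.
#' @export
binary_opening3d <- function(m, iterations = 3L) {
  binary_dilate3d(binary_erode3d(m, iterations), iterations)
}

dilate2d_once <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, ]    <- out[-1, ]    | m[-d[1], ]
  out[-d[1], ] <- out[-d[1], ] | m[-1, ]
  out[, -1]    <- out[, -1]    | m[, -d[2]]
  out[, -d[2]] <- out[, -d[2]] | m[, -1]
  out
}

#' In-plane binary opening of a volume, frame by frame
#'
#' `iterations` erosions then dilations with the 4-connected in-plane cross,
#' applied independently to every elevational frame. Cleans speckle-sized
#' responses from the segmentation without eroding along the elevational
#' axis, where a sphere spans only a handful of frames at typical freehand
#' frame spacings and any elevational erosion would destroy it.
#'
#' @param m Logical 3D array.
#' @param iterations Opening passes (default 3).
#' @return Logical array of the same shape; always a subset of the input.
#' @export
binary_opening_inplane <- function(m, iterations = 3L) {
  out <- m
  for (f in seq_len(dim(m)[3])) {
    fr <- m[, , f]
    for (it in seq_len(iterations)) fr <- erode2d_once(fr)
    for (it in seq_len(iterations)) fr <- dilate2d_once(fr)
    out[, , f] <- fr
  }
  out
}

erode2d_once <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, ]    <- out[-1, ]    & m[-d[1], ]
  out[-d[1], ] <- out[-d[1], ] & m[-1, ]
  out[, -1]    <- out[, -1]    & m[, -d[2]]
  out[, -d[2]] <- out[, -d[2]] & m[, -1]
  out[1, ] <- FALSE
  out[d[1], ] <- FALSE
  out[, 1] <- FALSE
  out[, d[2]] <- FALSE
  out
}

#' Binary erosion of a 2D mask, 4-connected cross
#' @param m Logical matrix.
#' @param iterations Number of erosion passes.
#' @return Logical matrix.
#' @export
binary_erode2d <- function(m, iterations = 1L) {
  for (it in seq_len(iterations)) m <- erode2d_once(m)
  m
}
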