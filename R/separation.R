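#' Distance transform of a sphere mask
#'
#' Exact Euclidean distance of every foreground voxel to its nearest
#' background voxel, in voxel units. The elevational axis is treated as
#' isotropic with the in-plane axes because the physical frame spacing is
#' unknown under freehand scanning.
#'
#' @param mask Logical 3D array.
#' @return Numeric array of distances, zero on the background.
#' @export
distance_transform <- function(mask) {
  edt3d_cpp(mask, dim(mask))
}

#' Watershed seed points from distance-map maxima
#'
#' Candidate seeds are foreground voxels whose distance equals the maximum
#' of the distance map within a `(2 * min_seed_distance + 1)^3` window.
#' Connected candidate plateaus are collapsed to one representative each,
#' and a greedy pass (strongest peak first) enforces the minimum pairwise
#' seed separation.
#'
#' @param dist Distance map from [distance_transform()].
#' @param mask Logical foreground mask.
#' @param min_seed_distance Minimum Euclidean separation between seeds in
#'   voxels (default 5).
#' @return Integer matrix of seed voxel coordinates (row, col, frame),
#'   one seed per row, ordered by decreasing distance value.
#' @export
find_seeds <- function(dist, mask, min_seed_distance = 5) {
  d <- dim(dist)
  mx <- maxfilter3d_cpp(dist, d, as.integer(ceiling(min_seed_distance)))
  cand <- mask & dist > 0 & dist >= mx
  if (!any(cand)) return(matrix(integer(0), ncol = 3))

  # one representative per connected candidate plateau: its strongest voxel
  cc <- label_components_cpp(cand, d)
  idx <- which(cand)
  comp <- cc[idx]
  val <- dist[idx]
  ord <- order(comp, -val, idx)
  first <- !duplicated(comp[ord])
  reps <- idx[ord][first]
  rep_val <- val[ord][first]

  ord2 <- order(-rep_val, reps)
  reps <- reps[ord2]
  rep_val <- rep_val[ord2]
  coords <- arrayInd(reps, d)

  keep <- logical(length(reps))
  acc <- matrix(numeric(0), ncol = 3)
  min2 <- min_seed_distance^2
  for (i in seq_along(reps)) {
    p <- coords[i, ]
    if (nrow(acc) == 0L ||
        min(colSums((t(acc) - p)^2)) >= min2) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  coords[keep, , drop = FALSE]
}

#' Split connected spheres with a seeded watershed
#'
#' Computes the distance transform of the cleaned sphere mask, places seeds
#' at its local maxima (minimum 5-voxel separation), and floods the negated
#' distance map from the seeds, restricted to the mask. Every foreground
#' voxel receives exactly one label; any component left without a seed by
#' the separation rule keeps its own label, so the labelled support equals
#' the input mask voxelwise.
#'
#' @param m1 Logical 3D sphere mask (cleaned segmentation).
#' @param min_seed_distance Minimum seed separation in voxels (default 5).
#' @return Integer 3D array: 0 background, 1..L sphere labels.
#' @export
split_connected <- function(m1, min_seed_distance = 5) {
  d <- dim(m1)
  if (!any(m1)) {
    out <- array(0L, d)
    return(out)
  }
  dist <- distance_transform(m1)
  seeds <- find_seeds(dist, m1, min_seed_distance)
  seed_vol <- array(0L, d)
  if (nrow(seeds) > 0L)
    seed_vol[seeds] <- seq_len(nrow(seeds))
  lab <- watershed3d_cpp(dist, seed_vol, m1, d)
  # components whose seeds were all suppressed: label them afresh
  leftover <- m1 & lab == 0L
  if (any(leftover)) {
    extra <- label_components_cpp(leftover, d)
    nmax <- max(lab)
    lab[leftover] <- extra[leftover] + nmax
  }
  # contiguous labels 1..L
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) > 0L && !identical(u, seq_along(u))) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Maximum elevational cross-section of every labelled sphere
#'
#' For each label, finds the frame with the largest in-plane pixel count
#' (ties broken toward the lower frame index), the area of that
#' cross-section in pixels and mm^2, and the mean in-plane coordinates of
#' its pixels. Labels touching the first or last frame are flagged: their
#' true maximum cross-section may lie outside the acquired stack.
#'
#' @param m2 Integer label array from [split_connected()].
#' @param volume The [cine_volume()] the labels live in (for spacings and
#'   depth conversion).
#' @return A tibble with one row per label: `label`, `zi` (frame of the
#'   maximum cross-section), `si_px`, `si_mm2`, `xi` (mean column), `yi`
#'   (mean row), `depth_cm`, `edge`.
#' @export
max_cross_sections <- function(m2, volume) {
  d <- dim(m2)
  idx <- which(m2 > 0L)
  if (length(idx) == 0L) {
    return(tibble(label = integer(0), zi = integer(0), si_px = integer(0),
                  si_mm2 = numeric(0), xi = numeric(0), yi = numeric(0),
                  depth_cm = numeric(0), edge = logical(0)))
  }
  lab <- m2[idx]
  n_labels <- max(lab)
  fr <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  key <- (lab - 1L) * d[3] + fr
  counts <- tabulate(key, nbins = n_labels * d[3])
  cnt_mat <- matrix(counts, nrow = d[3])  # frames x labels
  zi <- apply(cnt_mat, 2, which.max)      # first max: lower frame on ties
  si_px <- cnt_mat[cbind(zi, seq_len(n_labels))]
  edge <- cnt_mat[1, ] > 0 | cnt_mat[d[3], ] > 0

  # in-plane centroid within the max cross-section frame
  inplane <- (idx - 1L) %% (d[1] * d[2])
  row <- (inplane %% d[1]) + 1L
  col <- (inplane %/% d[1]) + 1L
  on_max <- fr == zi[lab]
  xi <- as.numeric(rowsum(col[on_max], lab[on_max]) /
                     tabulate(lab[on_max], n_labels))
  yi <- as.numeric(rowsum(row[on_max], lab[on_max]) /
                     tabulate(lab[on_max], n_labels))

  tibble(
    label = seq_len(n_labels),
    zi = as.integer(zi),
    si_px = as.integer(si_px),
    si_mm2 = si_px * volume$axial_spacing * volume$lateral_spacing,
    xi = xi,
    yi = yi,
    depth_cm = (volume$depth_offset + (yi - 1) * volume$axial_spacing) / 10,
    edge = edge
  )
}

#' Filter spheres by maximum cross-section area
#'
#' A perfectly segmented sphere of diameter `d` has a maximum cross-section
#' of `pi * d^2 / 4`. Objects outside `[alpha1, alpha2]` times that area are
#' spheres the watershed failed to split (too large) or fragments of
#' over-splitting (too small); both are excluded. Bounds are inclusive.
#'
#' @param spheres Tibble from [max_cross_sections()].
#' @param d Designed sphere diameter, mm.
#' @param alpha1,alpha2 Area band multipliers (defaults 0.5 and 1.25).
#' @param exclude_edge Also mark spheres touching the elevational boundary
#'   frames ineligible (default TRUE).
#' @return The input tibble with a logical `eligible` column added.
#' @export
area_filter <- function(spheres, d, alpha1 = 0.5, alpha2 = 1.25,
                        exclude_edge = TRUE) {
  if (!is.numeric(d) || d <= 0) stop_config("sphere diameter `d` must be positive")
  expected <- pi * d^2 / 4
  ok <- spheres$si_mm2 >= alpha1 * expected &
    spheres$si_mm2 <= alpha2 * expected
  if (exclude_edge) ok <- ok & !spheres$edge
  dplyr::mutate(spheres, eligible = ok)
}
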