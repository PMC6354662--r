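#' Segmentation parameters
#'
#' Bundles the tunables of the five-step pipeline: the air threshold `T`
#' (air is intensity `<= T`), the smoothing kernel sizes, the region-growing
#' connectivity and the seed point.
#'
#' @param threshold grayscale air threshold (air: intensity `<=` threshold).
#' @param seed numeric length-3 world mm; must land in an air voxel of the
#'   ROI after thresholding and blocking.
#' @param median_radius integer `>= 0`, half-width (voxels) of the cubic
#'   median window; default 1 (a 3x3x3 window).
#' @param gaussian_sigma Gaussian sigma in mm (`>= 0`), converted per axis to
#'   voxels; default 0.4 (one voxel at the reference 0.4 mm spacing).
#' @param connectivity 6, 18 or 26; default 6, the conservative choice that
#'   cannot leak diagonally through a one-voxel wall contact.
#' @return An object of class `nv_seg_params`.
#' @export
nv_seg_params <- function(threshold, seed, median_radius = 1L, gaussian_sigma = 0.4,
                          connectivity = 6L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    nv_stop("`threshold` must be a finite number")
  if (!is_num3(seed)) nv_stop("`seed` must be 3 finite numbers (mm)")
  if (!is.numeric(median_radius) || length(median_radius) != 1L ||
      median_radius < 0 || median_radius != round(median_radius))
    nv_stop("`median_radius` must be a non-negative integer")
  if (!is.numeric(gaussian_sigma) || length(gaussian_sigma) != 1L || gaussian_sigma < 0)
    nv_stop("`gaussian_sigma` must be >= 0 (mm)")
  if (!connectivity %in% c(6L, 18L, 26L)) nv_stop("`connectivity` must be 6, 18 or 26")
  structure(list(threshold = as.numeric(threshold), seed = as.numeric(seed),
                 median_radius = as.integer(median_radius),
                 gaussian_sigma = as.numeric(gaussian_sigma),
                 connectivity = as.integer(connectivity)),
            class = "nv_seg_params")
}

#' Smooth a grayscale volume (median, then Gaussian)
#'
#' The noise-reduction step of the pipeline: a cubic median filter of
#' half-width `median_radius` voxels, followed by a Gaussian of physical
#' sigma `gaussian_sigma` mm (converted per axis to voxel units). Zero
#' parameters are the identity; borders are handled by edge replication.
#'
#' @param volume an [nv_volume()].
#' @param median_radius integer half-width in voxels (`>= 0`).
#' @param gaussian_sigma sigma in mm (`>= 0`).
#' @return The smoothed [nv_volume()].
#' @export
smooth_volume <- function(volume, median_radius = 1L, gaussian_sigma = 0.4) {
  if (!inherits(volume, "nv_volume")) nv_stop("`volume` must be an nv_volume")
  if (median_radius < 0 || median_radius != round(median_radius))
    nv_stop("`median_radius` must be a non-negative integer")
  if (gaussian_sigma < 0) nv_stop("`gaussian_sigma` must be >= 0")
  d <- dim(volume$data)
  v <- as.numeric(volume$data)
  if (median_radius > 0)
    v <- cpp_median_filter(v, d, as.integer(median_radius))
  if (gaussian_sigma > 0)
    v <- cpp_gaussian_blur(v, d, gaussian_sigma / volume$spacing)
  nv_volume(array(v, d), volume$spacing, volume$origin)
}

#' Threshold a volume into a binary air mask
#'
#' Air is low intensity: the mask is `TRUE` where intensity `<= threshold`
#' (closed on the threshold for deterministic tie-breaking).
#'
#' @param volume an [nv_volume()].
#' @param threshold grayscale threshold `T`.
#' @return An [nv_mask()].
#' @export
binarize_air <- function(volume, threshold) {
  if (!inherits(volume, "nv_volume")) nv_stop("`volume` must be an nv_volume")
  nv_mask(volume$data <= threshold, volume$spacing, volume$origin)
}

#' Connected component of a mask containing a seed
#'
#' Returns exactly the connected component of the `TRUE` set containing the
#' voxel in which `seed` falls, under the stated connectivity. The output is
#' a subset of the input, is connected, and contains the seed voxel.
#'
#' @param mask an [nv_mask()].
#' @param seed numeric length-3 world mm; its voxel must be `TRUE`.
#' @param connectivity 6, 18 or 26.
#' @return The component as an [nv_mask()].
#' @export
region_grow <- function(mask, seed, connectivity = 6L) {
  if (!inherits(mask, "nv_mask")) nv_stop("`mask` must be an nv_mask")
  if (!connectivity %in% c(6L, 18L, 26L)) nv_stop("`connectivity` must be 6, 18 or 26")
  lin0 <- world_to_linear0(mask, seed)
  if (!mask$data[lin0 + 1])
    nv_stop(sprintf("seed voxel at (%s) mm [index %s] is not air in the mask",
                    paste(format(seed), collapse = ", "),
                    paste(world_to_index(mask, seed), collapse = ", ")),
            data = list(seed = seed))
  d <- dim(mask$data)
  comp <- cpp_flood_fill(as.logical(mask$data), d, lin0, as.integer(connectivity))
  nv_mask(array(comp, d), mask$spacing, mask$origin)
}

#' Voxel count and calibrated volume of a mask
#'
#' @param mask an [nv_mask()].
#' @return List with `voxel_count` and `volume_mm3 = voxel_count * sx*sy*sz`.
#' @export
measure_volume <- function(mask) {
  if (!inherits(mask, "nv_mask")) nv_stop("`mask` must be an nv_mask")
  n <- sum(mask$data)
  list(voxel_count = n, volume_mm3 = n * voxel_volume(mask))
}

#' Highest threshold keeping an inner cavity disconnected from outside air
#'
#' The accuracy-test threshold rule: find the largest threshold `T*` in the
#' volume's discrete intensity set such that, after `binarize_air(volume, T*)`,
#' the components containing `inner_seed` and `outer_seed` are distinct (and
#' both seeds are air). Implemented as a binary search over the sorted unique
#' intensities - both seed-airness and connectivity are monotone in `T`, so
#' the search is exact; an exhaustive scan gives the same answer.
#'
#' @param volume an [nv_volume()] (typically already smoothed the same way
#'   the segmentation pipeline will smooth before thresholding).
#' @param inner_seed,outer_seed world mm points in the cavity and in the
#'   outside air.
#' @param connectivity 6, 18 or 26.
#' @return The threshold `T*` (a value present in the volume).
#' @export
max_disconnecting_threshold <- function(volume, inner_seed, outer_seed,
                                        connectivity = 6L) {
  if (!inherits(volume, "nv_volume")) nv_stop("`volume` must be an nv_volume")
  if (!connectivity %in% c(6L, 18L, 26L)) nv_stop("`connectivity` must be 6, 18 or 26")
  d <- dim(volume$data)
  li <- world_to_linear0(volume, inner_seed)
  lo <- world_to_linear0(volume, outer_seed)
  if (li == lo) nv_stop("inner and outer seeds fall in the same voxel")
  u <- sort(unique(as.numeric(volume$data)))
  vi <- volume$data[li + 1]; vo <- volume$data[lo + 1]
  # both seeds are air from this index on
  lo_idx <- findInterval(max(vi, vo), u)
  hi_idx <- length(u)
  connected_at <- function(idx) {
    cpp_connected(as.numeric(volume$data) <= u[idx], d, li, lo,
                  as.integer(connectivity))
  }
  if (connected_at(lo_idx))
    nv_stop("no separating threshold: seeds are connected at every threshold that keeps both air",
            class = "nasovol_computation_error")
  if (!connected_at(hi_idx))
    nv_stop("seeds are not connected even with every voxel classified air; check the seeds",
            class = "nasovol_computation_error")
  # largest idx in [lo_idx, hi_idx) with disconnected(idx)
  a <- lo_idx; b <- hi_idx  # invariant: disconnected at a, connected at b
  while (b - a > 1L) {
    mid <- (a + b) %/% 2L
    if (connected_at(mid)) b <- mid else a <- mid
  }
  u[a]
}

#' Segment the nasal airway: the five-step pipeline
#'
#' Runs smoothing, air thresholding, ROI restriction, sinus blocking, seeded
#' region growing and voxel-calibrated volumetry, with full provenance in the
#' result. Left and right airways are measured by running the pipeline twice
#' with one seed per side; the nasal septum separates them in the data.
#'
#' @param volume an [nv_volume()].
#' @param landmarks an [nv_landmarks()] defining the ROI.
#' @param blocks list of [nv_block()] sealing sinus connections (may be empty).
#' @param params an [nv_seg_params()].
#' @return An object of class `nv_segmentation`: `mask`, `voxel_count`,
#'   `volume_mm3`, `params`, `blocks`, `landmarks`, `threshold`, `provenance`.
#' @export
segment_nasal_airway <- function(volume, landmarks, blocks, params) {
  if (!inherits(volume, "nv_volume")) nv_stop("`volume` must be an nv_volume")
  if (!inherits(params, "nv_seg_params")) nv_stop("`params` must be nv_seg_params")
  if (inherits(blocks, "nv_block")) blocks <- list(blocks)
  if (block_contains(blocks, params$seed))
    nv_stop("seed lies inside a blocked region")
  sm <- smooth_volume(volume, params$median_radius, params$gaussian_sigma)
  air <- binarize_air(sm, params$threshold)
  if (!any(air$data)) nv_stop("pipeline produced an empty mask at stage `binarize_air`",
                              class = "nasovol_computation_error")
  roi <- build_roi_mask(volume, landmarks)
  m <- nv_mask(air$data & roi$data, volume$spacing, volume$origin)
  if (!any(m$data)) nv_stop("pipeline produced an empty mask at stage `roi_intersection`",
                            class = "nasovol_computation_error")
  m <- apply_blocks(m, blocks)
  if (!any(m$data)) nv_stop("pipeline produced an empty mask at stage `apply_blocks`",
                            class = "nasovol_computation_error")
  comp <- region_grow(m, params$seed, params$connectivity)
  meas <- measure_volume(comp)
  structure(list(
    mask = comp,
    voxel_count = meas$voxel_count,
    volume_mm3 = meas$volume_mm3,
    threshold = params$threshold,
    params = params,
    blocks = blocks,
    landmarks = landmarks,
    provenance = list(
      volume_hash = object_hash(volume$data),
      landmarks_hash = object_hash(unclass(landmarks)),
      blocks_hash = object_hash(lapply(blocks, unclass)),
      spacing = volume$spacing,
      origin = volume$origin)),
    class = "nv_segmentation")
}

#' @export
print.nv_segmentation <- function(x, ...) {
  cat(sprintf("<nv_segmentation> %d voxels = %.2f mm^3 (T = %g, connectivity %d)\n",
              x$voxel_count, x$volume_mm3, x$threshold, x$params$connectivity))
  invisible(x)
}

#' Export a segmentation result (mask + JSON report)
#'
#' @param seg an `nv_segmentation`.
#' @param mask_path output path for the mask (`.mha` or `.nii`).
#' @param report_path output path for the JSON report.
#' @export
write_segmentation <- function(seg, mask_path, report_path) {
  if (!inherits(seg, "nv_segmentation")) nv_stop("`seg` must be nv_segmentation")
  write_mask(seg$mask, mask_path)
  rep <- list(voxel_count = seg$voxel_count,
              volume_mm3 = seg$volume_mm3,
              threshold = seg$threshold,
              connectivity = seg$params$connectivity,
              seed = seg$params$seed,
              median_radius = seg$params$median_radius,
              gaussian_sigma = seg$params$gaussian_sigma,
              blocks_hash = seg$provenance$blocks_hash,
              landmarks_hash = seg$provenance$landmarks_hash,
              volume_hash = seg$provenance$volume_hash)
  jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA)
  invisible(report_path)
}
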