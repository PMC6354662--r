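#' 3D scalar volume with voxel geometry
#'
#' A `nv_volume` is a 3D grid of signed scalar intensities (CBCT grayscale)
#' together with its voxel geometry: per-axis spacing in mm and the world
#' position of the grid corner. Voxel indexing is 0-based in world-geometry
#' terms: voxel `(i,j,k)` occupies the half-open box
#' `[origin + i*spacing, origin + (i+1)*spacing)` per axis, so its center is
#' at `origin + (i + 0.5)*spacing`. World axes follow the scanner LPS frame
#' (+x subject left, +y posterior, +z superior); a "coronal plane" is a plane
#' of constant y.
#'
#' @param data numeric 3D array of intensities (no missing values).
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of the grid corner.
#' @return An object of class `nv_volume`.
#' @examples
#' v <- nv_volume(array(0, c(4, 4, 4)), spacing = c(0.4, 0.4, 0.4))
#' voxel_volume(v)
#' @export
nv_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    nv_stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (anyNA(data)) nv_stop("volume intensities must have no missing values")
  if (!is_num3(spacing) || any(spacing <= 0))
    nv_stop("`spacing` must be 3 positive finite numbers (mm)")
  if (!is_num3(origin)) nv_stop("`origin` must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "nv_volume")
}

#' Binary mask sharing a volume's geometry
#'
#' @param data logical 3D array.
#' @param spacing,origin voxel geometry, as in [nv_volume()].
#' @return An object of class `nv_mask`.
#' @export
nv_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    nv_stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) nv_stop("mask values must be logical or 0/1")
    data <- array(data != 0, dim(data))
  }
  if (anyNA(data)) nv_stop("mask values must have no missing values")
  if (!is_num3(spacing) || any(spacing <= 0))
    nv_stop("`spacing` must be 3 positive finite numbers (mm)")
  if (!is_num3(origin)) nv_stop("`origin` must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "nv_mask")
}

#' @export
print.nv_volume <- function(x, ...) {
  cat(sprintf("<nv_volume> %s voxels @ %s mm, origin (%s), range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.nv_mask <- function(x, ...) {
  cat(sprintf("<nv_mask> %s voxels @ %s mm, origin (%s), %d set\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              sum(x$data)))
  invisible(x)
}

#' @export
dim.nv_volume <- function(x) dim(x$data)

#' @export
dim.nv_mask <- function(x) dim(x$data)

#' Volume of one voxel in cubic mm
#' @param x an `nv_volume` or `nv_mask`.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' World coordinates of voxel centers along each axis
#'
#' Returns a list with components `x`, `y`, `z`: the voxel-center coordinates
#' along each axis (mm).
#' @param x an `nv_volume` or `nv_mask`.
#' @export
voxel_centers <- function(x) {
  d <- dim(x$data)
  list(x = x$origin[1] + (seq_len(d[1]) - 0.5) * x$spacing[1],
       y = x$origin[2] + (seq_len(d[2]) - 0.5) * x$spacing[2],
       z = x$origin[3] + (seq_len(d[3]) - 0.5) * x$spacing[3])
}

#' World bounds of the grid
#'
#' @param x an `nv_volume` or `nv_mask`.
#' @return 2x3 matrix: rows are the lower and upper corner (mm).
#' @export
world_bounds <- function(x) {
  lo <- x$origin
  hi <- x$origin + dim(x$data) * x$spacing
  m <- rbind(lo, hi)
  dimnames(m) <- list(c("lower", "upper"), c("x", "y", "z"))
  m
}

# 1-based array index of the voxel whose box contains world point p
world_to_index <- function(x, p) {
  if (!is_num3(p)) nv_stop("point must be 3 finite numbers (mm)")
  idx <- floor((p - x$origin) / x$spacing) + 1
  d <- dim(x$data)
  if (any(idx < 1) || any(idx > d))
    nv_stop(sprintf("point (%s) lies outside the volume", paste(format(p), collapse = ", ")),
            data = list(point = p))
  as.integer(idx)
}

# 0-based linear index for the C++ kernels
world_to_linear0 <- function(x, p) {
  idx <- world_to_index(x, p) - 1L
  d <- dim(x$data)
  idx[1] + d[1] * (idx[2] + d[2] * idx[3])
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    nv_stop("grids have different geometry (shape, spacing or origin)")
  invisible(TRUE)
}
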