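#' Coronal boundary planes of the nasal-airway ROI
#'
#' The anterior border is the coronal plane (constant y) through the most
#' posterior point of the anterior nasal nares; the posterior border the
#' coronal plane through the most anterior point of the posterior border of
#' the nasal septum.
#'
#' @param landmarks an [nv_landmarks()].
#' @return Named numeric `c(y_anterior, y_posterior)` in mm, with
#'   `y_anterior < y_posterior`.
#' @export
coronal_bound_planes <- function(landmarks) {
  if (!inherits(landmarks, "nv_landmarks")) nv_stop("`landmarks` must be nv_landmarks")
  ya <- landmarks$nares_post[2]
  yp <- landmarks$septum_post_ant[2]
  if (!(ya < yp))
    nv_stop(sprintf("degenerate ROI: y_anterior = %g must be < y_posterior = %g", ya, yp))
  c(y_anterior = ya, y_posterior = yp)
}

#' Superior boundary curve of the ROI
#'
#' A natural cubic spline through the midsagittal (y, z) positions of nasion,
#' the posterior-inferior ethmoid point, and basion, in that (strictly
#' increasing y) order. The curve is extruded along x: the superior boundary
#' surface is `z = z_sup(y)`. Outside the knot span the curve continues
#' linearly with the boundary slope.
#'
#' @param landmarks an [nv_landmarks()].
#' @return A function `z_sup(y)` vectorized over `y` (mm in, mm out), with the
#'   knots attached as attribute `"knots"` (3x2 matrix of (y, z)).
#' @export
superior_spline <- function(landmarks) {
  if (!inherits(landmarks, "nv_landmarks")) nv_stop("`landmarks` must be nv_landmarks")
  ky <- c(landmarks$nasion[2], landmarks$ethmoid_pi[2], landmarks$ba[2])
  kz <- c(landmarks$nasion[3], landmarks$ethmoid_pi[3], landmarks$ba[3])
  if (any(diff(ky) <= 0))
    nv_stop("spline knots must have strictly increasing y (nasion < ethmoid_pi < ba)")
  f <- stats::splinefun(ky, kz, method = "natural")
  attr(f, "knots") <- cbind(y = ky, z = kz)
  f
}

#' Build the nasal-airway region-of-interest mask
#'
#' A voxel (decided by its center) belongs to the ROI iff
#' `y_anterior <= y <= y_posterior` and `z <= z_sup(y)`. There is no lateral
#' or inferior geometric cut: the palatal floor and the cavity walls bound the
#' airway naturally through the air/tissue mask downstream. Boundary ties
#' (center exactly on a plane) are included.
#'
#' @param volume an [nv_volume()].
#' @param landmarks an [nv_landmarks()] whose points lie inside `volume`.
#' @return An [nv_mask()] with the geometry of `volume`.
#' @export
build_roi_mask <- function(volume, landmarks) {
  if (!inherits(volume, "nv_volume")) nv_stop("`volume` must be an nv_volume")
  check_landmarks_in_volume(landmarks, volume)
  yb <- coronal_bound_planes(landmarks)
  z_sup <- superior_spline(landmarks)
  cc <- voxel_centers(volume)
  d <- dim(volume$data)
  in_y <- cc$y >= yb[1] & cc$y <= yb[2]          # length ny
  zroof <- z_sup(cc$y)                           # roof height per y-row
  # mask[i,j,k] = in_y[j] && cc$z[k] <= zroof[j]; x is free
  yz <- outer(ifelse(in_y, zroof, -Inf), cc$z, `>=`)   # ny x nz
  m <- aperm(array(rep(yz, d[1]), c(d[2], d[3], d[1])), c(3, 1, 2))
  if (!any(m)) nv_stop("empty ROI: no voxel center satisfies the boundary predicate")
  nv_mask(m, volume$spacing, volume$origin)
}
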