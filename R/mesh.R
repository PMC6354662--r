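#' Triangle surface mesh
#'
#' Vertices in world mm and faces as 1-based vertex-index triples,
#' consistently oriented outward (positive signed volume for a watertight
#' closed surface).
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return An object of class `nv_mesh`.
#' @export
nv_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L || !is.numeric(vertices)) nv_stop("`vertices` must be an n x 3 numeric matrix")
  if (ncol(faces) != 3L) nv_stop("`faces` must be an m x 3 index matrix")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    nv_stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "nv_mesh")
}

#' @export
print.nv_mesh <- function(x, ...) {
  cat(sprintf("<nv_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Is a mesh watertight?
#'
#' TRUE iff every undirected edge is shared by exactly two faces, once in
#' each direction (a closed, consistently oriented 2-manifold).
#'
#' @param mesh an [nv_mesh()].
#' @export
is_watertight <- function(mesh) {
  if (!inherits(mesh, "nv_mesh")) nv_stop("`mesh` must be an nv_mesh")
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])     # directed half-edges
  a <- pmin(he[, 1], he[, 2]); b <- pmax(he[, 1], he[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # each undirected edge must appear once per direction
  dirkey <- paste(he[, 1], he[, 2])
  !any(duplicated(dirkey))
}

#' Extract a watertight surface mesh from a binary mask
#'
#' Isosurface at level 0.5 of the 0/1 voxel field (sampled at voxel centers,
#' world spacing applied), computed by marching tetrahedra on a conforming
#' 6-tetrahedron cell decomposition. The mask is zero-padded by one voxel
#' layer first, so the surface is closed even when the mask touches the grid
#' boundary.
#'
#' @param mask a non-empty [nv_mask()].
#' @return An [nv_mesh()] with outward-oriented faces.
#' @export
mask_to_mesh <- function(mask) {
  if (!inherits(mask, "nv_mask")) nv_stop("`mask` must be an nv_mask")
  if (!any(mask$data)) nv_stop("cannot mesh an empty mask")
  d <- dim(mask$data)
  dp <- d + 2L
  f <- array(0, dp)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask$data)
  origin_pad <- mask$origin - mask$spacing
  res <- cpp_marching_tets(as.numeric(f), dp, mask$spacing, origin_pad, 0.5)
  nv_mesh(res$vertices, res$faces)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedron) sum. The mesh must be watertight
#' and outward-oriented; an inward-oriented (negative signed volume) mesh is
#' rejected with the signed value reported.
#'
#' @param mesh an [nv_mesh()].
#' @return Volume in cubic mm (positive).
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    nv_stop("mesh is not watertight; enclosed volume is undefined",
            class = "nasovol_computation_error")
  v <- signed_mesh_volume(mesh)
  if (v <= 0)
    nv_stop(sprintf("mesh is inward-oriented (signed volume %g mm^3); flip the faces", v),
            class = "nasovol_computation_error")
  v
}

signed_mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Scale a mesh about its centroid
#'
#' Vertices are scaled by `factor` about the vertex centroid; enclosed volume
#' scales by `factor^3`.
#'
#' @param mesh an [nv_mesh()].
#' @param factor positive scale factor.
#' @export
scale_mesh <- function(mesh, factor) {
  if (!inherits(mesh, "nv_mesh")) nv_stop("`mesh` must be an nv_mesh")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    nv_stop("`factor` must be a positive number")
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2, ctr)
  nv_mesh(sweep(v * factor, 2, ctr, `+`), mesh$faces)
}

#' Hollow shell around a cavity mask
#'
#' The shell is the morphological dilation of the mask by a ball of radius
#' `wall_mm` minus the mask itself: a printable wall of (at least) the given
#' thickness that encloses the cavity watertightly, i.e. the cavity is
#' disconnected from the exterior in the complement under 6-connectivity.
#'
#' @param mask an [nv_mask()] of the cavity.
#' @param wall_mm wall thickness in mm; must be at least the largest voxel
#'   dimension (a thinner wall cannot be rasterized watertightly).
#' @return The shell as an [nv_mask()].
#' @export
hollow_shell <- function(mask, wall_mm) {
  if (!inherits(mask, "nv_mask")) nv_stop("`mask` must be an nv_mask")
  if (!is.numeric(wall_mm) || length(wall_mm) != 1L || wall_mm < max(mask$spacing))
    nv_stop(sprintf("`wall_mm` must be at least the largest voxel dimension (%g mm)",
                    max(mask$spacing)))
  dil <- dilate_ball(mask, wall_mm)
  nv_mask(dil$data & !mask$data, mask$spacing, mask$origin)
}

# dilation by a voxelized ball of physical radius r_mm
dilate_ball <- function(mask, r_mm) {
  sp <- mask$spacing
  rv <- ceiling(r_mm / sp)
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  keep <- (g$dx * sp[1])^2 + (g$dy * sp[2])^2 + (g$dz * sp[3])^2 <= r_mm^2 + 1e-9
  offs <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(offs) <- "integer"
  d <- dim(mask$data)
  out <- cpp_dilate(as.logical(mask$data), d, offs)
  nv_mask(array(out, d), mask$spacing, mask$origin)
}
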