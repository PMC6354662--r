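#' Geometric blocks closing sinus-airway connections
#'
#' A block is a disk-slab: the set of points within `radius_mm` of the axis
#' point in the plane orthogonal to `normal` and within `thickness_mm/2`
#' along `normal`. Rasterized by voxel-center inclusion, a block forces those
#' voxels to "tissue" in the binary air mask, sealing the connection (ostium)
#' between a paranasal sinus and the nasal airway so region growing cannot
#' leak. Serialized as JSON so an editing session is a reproducible,
#' versionable artifact.
#'
#' @param center numeric length-3 world mm.
#' @param normal numeric length-3, unit vector (checked to 1e-6).
#' @param radius_mm in-plane disk radius, > 0.
#' @param thickness_mm slab extent along the normal, > 0. To guarantee a
#'   watertight rasterized seal it should be at least one voxel diagonal of
#'   the target grid (checked at application time).
#' @return An object of class `nv_block`.
#' @export
nv_block <- function(center, normal, radius_mm, thickness_mm) {
  if (!is_num3(center)) nv_stop("`center` must be 3 finite numbers (mm)")
  if (!is_num3(normal)) nv_stop("`normal` must be 3 finite numbers")
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6)
    nv_stop("`normal` must have unit length (within 1e-6)")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    nv_stop("`radius_mm` must be a positive number")
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L || thickness_mm <= 0)
    nv_stop("`thickness_mm` must be a positive number")
  structure(list(center = as.numeric(center), normal = as.numeric(normal),
                 radius_mm = as.numeric(radius_mm), thickness_mm = as.numeric(thickness_mm)),
            class = "nv_block")
}

#' Read / write a block set as JSON
#'
#' The file is a JSON array of objects with keys `center`, `normal`,
#' `radius_mm`, `thickness_mm`.
#'
#' @param path JSON file path.
#' @return `read_blocks()` returns a list of [nv_block()].
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(j) == 0L) return(list())
  if (!is.data.frame(j)) nv_stop("blocks file must be a JSON array of block objects")
  lapply(seq_len(nrow(j)), function(i)
    nv_block(unlist(j$center[i]), unlist(j$normal[i]), j$radius_mm[i], j$thickness_mm[i]))
}

#' @rdname read_blocks
#' @param blocks list of [nv_block()].
#' @export
write_blocks <- function(blocks, path) {
  jsonlite::write_json(lapply(blocks, unclass), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply blocks to a binary air mask
#'
#' Every voxel whose center lies inside any block's disk-slab is forced to
#' `FALSE` (tissue); all other voxels are unchanged. A block lying entirely
#' outside the grid triggers a warning and has no effect.
#'
#' @param mask an [nv_mask()].
#' @param blocks list of [nv_block()] (possibly empty).
#' @return The blocked [nv_mask()].
#' @export
apply_blocks <- function(mask, blocks) {
  if (!inherits(mask, "nv_mask")) nv_stop("`mask` must be an nv_mask")
  if (inherits(blocks, "nv_block")) blocks <- list(blocks)
  if (length(blocks) == 0L) return(mask)
  vdiag <- sqrt(sum(mask$spacing^2))
  m <- mask$data
  cc <- voxel_centers(mask)
  d <- dim(m)
  for (b in blocks) {
    if (!inherits(b, "nv_block")) nv_stop("`blocks` must be a list of nv_block")
    if (b$thickness_mm < vdiag - 1e-9)
      nv_stop(sprintf("block thickness %g mm is below one voxel diagonal (%g mm); the seal may leak",
                      b$thickness_mm, vdiag))
    # bounding range of the slab
    reach <- sqrt(b$radius_mm^2 + (b$thickness_mm / 2)^2)
    ir <- range_idx(cc$x, b$center[1], reach)
    jr <- range_idx(cc$y, b$center[2], reach)
    kr <- range_idx(cc$z, b$center[3], reach)
    if (is.null(ir) || is.null(jr) || is.null(kr)) {
      nv_warn("block lies entirely outside the grid; no effect")
      next
    }
    px <- cc$x[ir] - b$center[1]
    py <- cc$y[jr] - b$center[2]
    pz <- cc$z[kr] - b$center[3]
    # axial distance t = p . n and in-plane distance^2 = |p|^2 - t^2
    tax <- outer(outer(px * b$normal[1], py * b$normal[2], `+`), pz * b$normal[3], `+`)
    r2 <- outer(outer(px^2, py^2, `+`), pz^2, `+`) - tax^2
    inside <- abs(tax) <= b$thickness_mm / 2 & r2 <= b$radius_mm^2
    if (!any(inside)) {
      nv_warn("block lies entirely outside the grid; no effect")
      next
    }
    sub <- m[ir, jr, kr, drop = FALSE]
    sub[inside] <- FALSE
    m[ir, jr, kr] <- sub
  }
  nv_mask(m, mask$spacing, mask$origin)
}

# indices of centers within [c-reach, c+reach]; NULL if none
range_idx <- function(centers, c0, reach) {
  i <- which(centers >= c0 - reach & centers <= c0 + reach)
  if (length(i) == 0L) NULL else i
}

# TRUE for voxels whose center lies inside the block (used by callers that
# need point-membership, e.g. seed checks)
block_contains <- function(blocks, p) {
  if (inherits(blocks, "nv_block")) blocks <- list(blocks)
  for (b in blocks) {
    q <- p - b$center
    tax <- sum(q * b$normal)
    r2 <- sum(q^2) - tax^2
    if (abs(tax) <= b$thickness_mm / 2 && r2 <= b$radius_mm^2) return(TRUE)
  }
  FALSE
}
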