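#' Parametric cavity shapes with closed-form volumes
#'
#' Building blocks of the digital phantom: an ellipsoid (semi-axes a, b, c
#' mm), a capsule (cylinder of radius r and axis length L with hemispherical
#' caps), and a union of pairwise disjoint shapes.
#'
#' @param center,semi_axes ellipsoid pose: center (world mm) and positive
#'   semi-axes (mm), axis-aligned.
#' @return An object of class `nv_shape`.
#' @export
shape_ellipsoid <- function(center, semi_axes) {
  if (!is_num3(center) || !is_num3(semi_axes) || any(semi_axes <= 0))
    nv_stop("ellipsoid needs a 3-vector center and positive semi-axes")
  structure(list(type = "ellipsoid", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)), class = "nv_shape")
}

#' @rdname shape_ellipsoid
#' @param p1,p2 capsule axis endpoints (world mm).
#' @param radius_mm capsule radius (> 0).
#' @export
shape_capsule <- function(p1, p2, radius_mm) {
  if (!is_num3(p1) || !is_num3(p2)) nv_stop("capsule endpoints must be 3-vectors (mm)")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    nv_stop("capsule radius must be positive")
  structure(list(type = "capsule", p1 = as.numeric(p1), p2 = as.numeric(p2),
                 radius_mm = as.numeric(radius_mm)), class = "nv_shape")
}

#' @rdname shape_ellipsoid
#' @param ... member `nv_shape`s; their bounding boxes must be pairwise
#'   disjoint (otherwise no closed-form volume exists and the union is
#'   rejected).
#' @export
shape_union <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) && !inherits(members[[1]], "nv_shape"))
    members <- members[[1]]
  if (!length(members) || !all(vapply(members, inherits, TRUE, "nv_shape")))
    nv_stop("union members must be nv_shape objects")
  bb <- lapply(members, shape_bbox)
  for (i in seq_along(members)) for (j in seq_len(i - 1L)) {
    if (all(bb[[i]][1, ] <= bb[[j]][2, ] & bb[[j]][1, ] <= bb[[i]][2, ]))
      nv_stop("union members overlap (bounding boxes intersect); no closed-form volume")
  }
  structure(list(type = "union", members = members), class = "nv_shape")
}

shape_bbox <- function(s) {
  switch(s$type,
    ellipsoid = rbind(s$center - s$semi_axes, s$center + s$semi_axes),
    capsule = rbind(pmin(s$p1, s$p2) - s$radius_mm, pmax(s$p1, s$p2) + s$radius_mm),
    union = {
      bbs <- lapply(s$members, shape_bbox)
      rbind(do.call(pmin, lapply(bbs, function(b) b[1, ])),
            do.call(pmax, lapply(bbs, function(b) b[2, ])))
    })
}

shape_seed <- function(s) {
  switch(s$type,
    ellipsoid = s$center,
    capsule = (s$p1 + s$p2) / 2,
    union = shape_seed(s$members[[1]]))
}

#' Closed-form volume of a shape
#'
#' Ellipsoid `4/3*pi*a*b*c`; capsule `pi*r^2*L + 4/3*pi*r^3`; a union of
#' disjoint shapes sums. This is the phantom's analytic gold standard - it is
#' never derived from the raster.
#'
#' @param shape an `nv_shape`.
#' @return Volume in cubic mm.
#' @export
analytic_volume <- function(shape) {
  if (!inherits(shape, "nv_shape")) nv_stop("`shape` must be an nv_shape")
  switch(shape$type,
    ellipsoid = 4 / 3 * pi * prod(shape$semi_axes),
    capsule = {
      L <- sqrt(sum((shape$p2 - shape$p1)^2))
      pi * shape$radius_mm^2 * L + 4 / 3 * pi * shape$radius_mm^3
    },
    union = sum(vapply(shape$members, analytic_volume, 0)))
}

# logical array: voxel centers inside the shape
raster_shape <- function(shape, cc, d) {
  switch(shape$type,
    ellipsoid = {
      ex <- ((cc$x - shape$center[1]) / shape$semi_axes[1])^2
      ey <- ((cc$y - shape$center[2]) / shape$semi_axes[2])^2
      ez <- ((cc$z - shape$center[3]) / shape$semi_axes[3])^2
      outer(outer(ex, ey, `+`), ez, `+`) <= 1
    },
    capsule = {
      out <- array(FALSE, d)
      bb <- shape_bbox(shape)
      ir <- which(cc$x >= bb[1, 1] & cc$x <= bb[2, 1])
      jr <- which(cc$y >= bb[1, 2] & cc$y <= bb[2, 2])
      kr <- which(cc$z >= bb[1, 3] & cc$z <= bb[2, 3])
      if (!length(ir) || !length(jr) || !length(kr)) return(out)
      ax <- shape$p2 - shape$p1
      a2 <- sum(ax^2)
      X <- array(cc$x[ir], c(length(ir), length(jr), length(kr)))
      Y <- aperm(array(cc$y[jr], c(length(jr), length(ir), length(kr))), c(2, 1, 3))
      Z <- aperm(array(cc$z[kr], c(length(kr), length(ir), length(jr))), c(2, 3, 1))
      qx <- X - shape$p1[1]; qy <- Y - shape$p1[2]; qz <- Z - shape$p1[3]
      tt <- if (a2 > 0) pmin(pmax((qx * ax[1] + qy * ax[2] + qz * ax[3]) / a2, 0), 1) else 0
      d2 <- (qx - tt * ax[1])^2 + (qy - tt * ax[2])^2 + (qz - tt * ax[3])^2
      out[ir, jr, kr] <- d2 <= shape$radius_mm^2
      out
    },
    union = {
      out <- array(FALSE, d)
      for (m in shape$members) out <- out | raster_shape(m, cc, d)
      out
    })
}

#' Digital phantom specification
#'
#' Describes a CBCT-like phantom: air cavities inside a soft-tissue-mimic
#' shell of known wall thickness (optionally with thinner "weak" patches, as
#' a printed resin shell would have), optional sinus chambers connected by
#' cylindrical channels, a bone slab, partial-volume blur and detector noise.
#' The grayscale defaults follow the levels seen in CBCT of such a phantom:
#' air around -1000, soft-tissue mimic around 300, cortical bone around 800.
#'
#' @param cavities list of [shape_ellipsoid()] / [shape_capsule()] /
#'   [shape_union()] - the airway cavities with analytic gold-standard volume.
#' @param wall_mm shell wall thickness (mm), at least the largest voxel.
#' @param weak_patches list of `list(center, radius_mm, wall_mm)`: spherical
#'   regions where the shell is locally thinner.
#' @param sinuses list of shapes: air chambers outside the cavities.
#' @param channels list of `list(from_cavity, to_sinus, radius_mm)` or
#'   explicit `list(p1, p2, radius_mm)`: cylindrical air connections.
#' @param bone_boxes list of `list(lower, upper)` world-mm boxes filled with
#'   bone-level voxels (where not air or shell).
#' @param material_levels named numeric: `air`, `soft`, `bone` grayscale,
#'   strictly increasing.
#' @param noise_sd additive Gaussian noise sd (grayscale, `>= 0`).
#' @param blur_sigma_mm Gaussian blur sigma (mm) emulating partial volume.
#' @param spacing voxel spacing (mm, scalar or length 3).
#' @param margin_mm outer air margin added around the geometry.
#' @param rng_seed integer seed making the phantom deterministic.
#' @return An object of class `nv_phantom_spec`.
#' @export
nv_phantom_spec <- function(cavities, wall_mm = 2, weak_patches = list(),
                            sinuses = list(), channels = list(),
                            bone_boxes = list(),
                            material_levels = c(air = -1000, soft = 300, bone = 800),
                            noise_sd = 40, blur_sigma_mm = 0.4,
                            spacing = 0.4, margin_mm = 6, rng_seed = 20190128L) {
  if (!length(cavities) || !all(vapply(cavities, inherits, TRUE, "nv_shape")))
    nv_stop("`cavities` must be a non-empty list of nv_shape")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is_num3(spacing) || any(spacing <= 0)) nv_stop("`spacing` must be positive (mm)")
  ml <- material_levels
  if (!all(c("air", "soft", "bone") %in% names(ml)) ||
      !(ml["air"] < ml["soft"] && ml["soft"] < ml["bone"]))
    nv_stop("material levels must satisfy air < soft < bone")
  if (noise_sd < 0) nv_stop("`noise_sd` must be >= 0")
  if (blur_sigma_mm < 0) nv_stop("`blur_sigma_mm` must be >= 0")
  if (wall_mm < max(spacing))
    nv_stop("`wall_mm` must be at least the largest voxel dimension")
  structure(list(cavities = cavities, wall_mm = wall_mm, weak_patches = weak_patches,
                 sinuses = sinuses, channels = channels, bone_boxes = bone_boxes,
                 material_levels = ml, noise_sd = noise_sd,
                 blur_sigma_mm = blur_sigma_mm, spacing = spacing,
                 margin_mm = margin_mm, rng_seed = as.integer(rng_seed)),
            class = "nv_phantom_spec")
}

#' Default two-cavity accuracy phantom
#'
#' A left/right pair of ellipsoidal cavities with analytic volumes 1220 and
#' 830 cubic mm at 0.4 mm voxels: the desk-scale analogue of a printed
#' hollow left/right nasal airway pair embedded in a skull phantom. Each
#' cavity's shell has a thin patch near its apex - the weakest region of a
#' printed wall, which is what the highest-disconnecting-threshold rule keys
#' on. The thin-patch wall (2.25 voxels) and the partial-volume blur (one
#' voxel) are tied to the voxel size: the threshold-limiting weak spot of a
#' real shell is, by construction of the rule, the place where the wall is
#' barely resolved, so the phantom stays self-similar when the scan
#' resolution changes.
#'
#' @param spacing voxel spacing in mm (default 0.4).
#' @param rng_seed integer seed.
#' @return An `nv_phantom_spec`.
#' @export
nasal_pair_phantom_spec <- function(spacing = 0.4, rng_seed = 20190128L) {
  a_l <- 4; b_l <- 14; c_l <- 3 * 1220 / (4 * pi * a_l * b_l)
  a_r <- 3.5; b_r <- 13; c_r <- 3 * 830 / (4 * pi * a_r * b_r)
  left <- shape_ellipsoid(c(8, 0, 0), c(a_l, b_l, c_l))
  right <- shape_ellipsoid(c(-8, 0, 0), c(a_r, b_r, c_r))
  nv_phantom_spec(
    cavities = list(left = left, right = right),
    wall_mm = 2,
    weak_patches = list(list(center = c(8, 0, c_l), radius_mm = 3, wall_mm = 2.25 * spacing),
                        list(center = c(-8, 0, c_r), radius_mm = 3, wall_mm = 2.25 * spacing)),
    bone_boxes = list(list(lower = c(-16, -16, -12), upper = c(16, 16, -9))),
    blur_sigma_mm = spacing,
    spacing = spacing, rng_seed = rng_seed)
}

#' Segment every cavity of a generated phantom with the threshold rule
#'
#' The accuracy experiment: smooth the phantom with the edge-preserving
#' median filter only (the phantom already carries the scanner blur), find
#' each cavity's highest disconnecting threshold against the outside air,
#' run the pipeline per cavity at that threshold, and report measured vs
#' analytic volume.
#'
#' @param phantom output of [generate_phantom()].
#' @param connectivity region-growing connectivity (default 6).
#' @param median_radius median half-width in voxels (default 1).
#' @return data.frame with one row per cavity: `object`, `threshold`,
#'   `measured_mm3`, `gs_mm3`, `percent_of_gs`.
#' @export
phantom_accuracy_experiment <- function(phantom, connectivity = 6L, median_radius = 1L) {
  vol <- phantom$volume
  truth <- phantom$truth
  sm <- smooth_volume(vol, median_radius = median_radius, gaussian_sigma = 0)
  rows <- lapply(seq_along(truth$seeds), function(i) {
    tstar <- max_disconnecting_threshold(sm, truth$seeds[[i]], truth$outer_seed,
                                         connectivity)
    params <- nv_seg_params(threshold = tstar, seed = truth$seeds[[i]],
                            median_radius = median_radius, gaussian_sigma = 0,
                            connectivity = connectivity)
    seg <- segment_nasal_airway(vol, truth$landmarks, list(), params)
    data.frame(object = names(truth$seeds)[i] %||% paste0("cavity_", i),
               threshold = tstar,
               measured_mm3 = seg$volume_mm3,
               gs_mm3 = unname(truth$cavity_volumes_mm3[[i]]),
               percent_of_gs = percent_of_gs(seg$volume_mm3,
                                             truth$cavity_volumes_mm3[[i]]))
  })
  do.call(rbind, rows)
}

#' Generate a digital phantom volume with analytic ground truth
#'
#' Voxels are labeled by analytic shape membership (cavity / channel / sinus
#' interior at the air level, shell at the soft level, bone boxes at the bone
#' level, everything else outside air), then blurred (partial-volume
#' emulation) and degraded with additive Gaussian noise. Ground-truth cavity
#' volumes are computed in closed form, never from the raster. The ground
#' truth also records seed points, an outside-air seed, and a landmark set
#' whose coronal planes bracket the cavities, for running the full
#' segmentation loop.
#'
#' @param spec an [nv_phantom_spec()].
#' @return List with `volume` (an [nv_volume()]) and `truth` (analytic
#'   volumes, seeds, landmarks, recorded ROI plane coordinates, channel
#'   adjacency).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "nv_phantom_spec")) nv_stop("`spec` must be an nv_phantom_spec")
  sp <- spec$spacing
  ml <- spec$material_levels
  # grid: bounding box of all geometry + wall + margin, snapped to voxels
  bbs <- c(lapply(c(spec$cavities, spec$sinuses), shape_bbox),
           lapply(spec$bone_boxes, function(b) rbind(b$lower, b$upper)))
  lower <- do.call(pmin, lapply(bbs, function(b) b[1, ])) - spec$wall_mm - spec$margin_mm
  upper <- do.call(pmax, lapply(bbs, function(b) b[2, ])) + spec$wall_mm + spec$margin_mm
  origin <- floor(lower / sp) * sp
  d <- as.integer(ceiling((upper - origin) / sp))
  grid <- nv_mask(array(FALSE, d), sp, origin)
  cc <- voxel_centers(grid)

  cav_masks <- lapply(spec$cavities, raster_shape, cc = cc, d = d)
  air <- Reduce(`|`, cav_masks)
  for (s in spec$sinuses) air <- air | raster_shape(s, cc, d)
  channels <- lapply(spec$channels, function(ch) {
    if (!is.null(ch$p1)) shape_capsule(ch$p1, ch$p2, ch$radius_mm)
    else shape_capsule(shape_seed(spec$cavities[[ch$from_cavity]]),
                       shape_seed(spec$sinuses[[ch$to_sinus]]), ch$radius_mm)
  })
  for (ch in channels) air <- air | raster_shape(ch, cc, d)
  if (!any(air)) nv_stop("phantom has no air voxels")
  bmask <- nv_mask(air, sp, origin)
  bnd <- world_bounds(bmask)
  abb <- do.call(pmin, lapply(c(spec$cavities, spec$sinuses), function(s) shape_bbox(s)[1, ]))
  abb_u <- do.call(pmax, lapply(c(spec$cavities, spec$sinuses), function(s) shape_bbox(s)[2, ]))
  if (any(abb - spec$wall_mm < bnd["lower", ]) || any(abb_u + spec$wall_mm > bnd["upper", ]))
    nv_stop("geometry (cavities + walls) exceeds the grid")

  shell <- dilate_ball(bmask, spec$wall_mm)$data & !air
  for (wp in spec$weak_patches) {
    if (wp$wall_mm < max(sp)) nv_stop("weak-patch wall must be at least one voxel")
    thin <- dilate_ball(bmask, wp$wall_mm)$data & !air
    ex <- (cc$x - wp$center[1])^2; ey <- (cc$y - wp$center[2])^2; ez <- (cc$z - wp$center[3])^2
    ball <- outer(outer(ex, ey, `+`), ez, `+`) <= wp$radius_mm^2
    shell <- (shell & !ball) | (thin & ball)
  }

  img <- array(ml[["air"]], d)
  for (b in spec$bone_boxes) {
    ir <- which(cc$x >= b$lower[1] & cc$x <= b$upper[1])
    jr <- which(cc$y >= b$lower[2] & cc$y <= b$upper[2])
    kr <- which(cc$z >= b$lower[3] & cc$z <= b$upper[3])
    img[ir, jr, kr] <- ml[["bone"]]
  }
  img[shell] <- ml[["soft"]]
  img[air] <- ml[["air"]]

  if (spec$blur_sigma_mm > 0)
    img <- array(cpp_gaussian_blur(as.numeric(img), d, spec$blur_sigma_mm / sp), d)
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$rng_seed,
                           array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  vol <- nv_volume(img, sp, origin)

  # landmarks bracketing the cavities, roof above shell apex
  cav_bb_lo <- do.call(pmin, lapply(spec$cavities, function(s) shape_bbox(s)[1, ]))
  cav_bb_hi <- do.call(pmax, lapply(spec$cavities, function(s) shape_bbox(s)[2, ]))
  y_ant <- cav_bb_lo[2] - 1.5
  y_post <- cav_bb_hi[2] + 1.5
  z_roof <- cav_bb_hi[3] + spec$wall_mm + 1.5
  x_mid <- (cav_bb_lo[1] + cav_bb_hi[1]) / 2
  z_mid <- (cav_bb_lo[3] + cav_bb_hi[3]) / 2
  lm <- nv_landmarks(
    ba = c(x_mid, y_post + 2, z_roof),
    nasion = c(x_mid, y_ant - 2, z_roof),
    ethmoid_pi = c(x_mid, (y_ant + y_post) / 2, z_roof + 0.5),
    septum_post_ant = c(x_mid, y_post, z_mid),
    nares_post = c(x_mid, y_ant, z_mid))
  check_landmarks_in_volume(lm, vol)

  truth <- list(
    cavity_volumes_mm3 = vapply(spec$cavities, analytic_volume, 0),
    seeds = lapply(spec$cavities, shape_seed),
    outer_seed = origin + 1.5 * sp,
    landmarks = lm,
    y_anterior = unname(y_ant), y_posterior = unname(y_post),
    channel_links = lapply(seq_along(spec$channels), function(i) {
      ch <- spec$channels[[i]]
      list(channel = i, from_cavity = ch$from_cavity %||% NA, to_sinus = ch$to_sinus %||% NA)
    }),
    spec = spec)
  list(volume = vol, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shape_from_json <- function(j) {
  if (is.null(j$type)) nv_stop("shape JSON needs a `type`")
  switch(j$type,
    ellipsoid = shape_ellipsoid(unlist(j$center), unlist(j$semi_axes)),
    capsule = shape_capsule(unlist(j$p1), unlist(j$p2), j$radius_mm),
    union = shape_union(lapply(j$members, shape_from_json)),
    nv_stop(sprintf("unknown shape type: %s", j$type)))
}

shape_to_json <- function(s) {
  switch(s$type,
    ellipsoid = list(type = "ellipsoid", center = s$center, semi_axes = s$semi_axes),
    capsule = list(type = "capsule", p1 = s$p1, p2 = s$p2, radius_mm = s$radius_mm),
    union = list(type = "union", members = lapply(s$members, shape_to_json)))
}

#' Read / write a phantom specification as JSON
#'
#' @param path JSON file path.
#' @return `read_phantom_spec()` returns an [nv_phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path)
  if (is.null(j$cavities)) nv_stop("phantom spec JSON needs `cavities`")
  ml <- if (is.null(j$material_levels)) c(air = -1000, soft = 300, bone = 800)
        else c(air = j$material_levels$air, soft = j$material_levels$soft,
               bone = j$material_levels$bone)
  nv_phantom_spec(
    cavities = lapply(j$cavities, shape_from_json),
    wall_mm = j$wall_mm %||% 2,
    weak_patches = lapply(j$weak_patches %||% list(), function(w)
      list(center = unlist(w$center), radius_mm = w$radius_mm, wall_mm = w$wall_mm)),
    sinuses = lapply(j$sinuses %||% list(), shape_from_json),
    channels = lapply(j$channels %||% list(), function(ch)
      list(p1 = if (!is.null(ch$p1)) unlist(ch$p1), p2 = if (!is.null(ch$p2)) unlist(ch$p2),
           from_cavity = ch$from_cavity, to_sinus = ch$to_sinus, radius_mm = ch$radius_mm)),
    bone_boxes = lapply(j$bone_boxes %||% list(), function(b)
      list(lower = unlist(b$lower), upper = unlist(b$upper))),
    material_levels = ml,
    noise_sd = j$noise_sd %||% 40,
    blur_sigma_mm = j$blur_sigma_mm %||% 0.4,
    spacing = unlist(j$spacing %||% 0.4),
    margin_mm = j$margin_mm %||% 6,
    rng_seed = j$rng_seed %||% 20190128L)
}

#' @rdname read_phantom_spec
#' @param spec an [nv_phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  if (!inherits(spec, "nv_phantom_spec")) nv_stop("`spec` must be an nv_phantom_spec")
  j <- list(cavities = lapply(spec$cavities, shape_to_json),
            wall_mm = spec$wall_mm,
            weak_patches = spec$weak_patches,
            sinuses = lapply(spec$sinuses, shape_to_json),
            channels = spec$channels,
            bone_boxes = spec$bone_boxes,
            material_levels = as.list(spec$material_levels),
            noise_sd = spec$noise_sd,
            blur_sigma_mm = spec$blur_sigma_mm,
            spacing = spec$spacing,
            margin_mm = spec$margin_mm,
            rng_seed = spec$rng_seed)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
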