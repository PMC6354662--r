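#' Craniometric landmark set defining the nasal-airway ROI
#'
#' Five points, world mm, LPS convention (+x left, +y posterior, +z superior):
#' * `ba` - basion;
#' * `nasion` - nasion (N);
#' * `ethmoid_pi` - most posterior-inferior point of the ethmoid sinuses;
#' * `septum_post_ant` - most anterior point of the posterior border of the
#'   nasal septum (posterior ROI boundary);
#' * `nares_post` - most posterior point of the anterior nasal nares
#'   (anterior ROI boundary).
#'
#' Ordering invariants (checked): `nares_post` anterior to `septum_post_ant`;
#' `nasion.y < ethmoid_pi.y < ba.y`.
#'
#' @param ba,nasion,ethmoid_pi,septum_post_ant,nares_post numeric length-3
#'   world coordinates (mm).
#' @return An object of class `nv_landmarks`.
#' @export
nv_landmarks <- function(ba, nasion, ethmoid_pi, septum_post_ant, nares_post) {
  pts <- list(ba = ba, nasion = nasion, ethmoid_pi = ethmoid_pi,
              septum_post_ant = septum_post_ant, nares_post = nares_post)
  for (nm in names(pts)) {
    if (!is_num3(pts[[nm]])) nv_stop(sprintf("landmark `%s` must be 3 finite numbers (mm)", nm))
    pts[[nm]] <- as.numeric(pts[[nm]])
  }
  if (!(pts$nares_post[2] < pts$septum_post_ant[2]))
    nv_stop(sprintf(paste0("anterior boundary landmark must lie anterior to the posterior one: ",
                           "nares_post.y = %g, septum_post_ant.y = %g"),
                    pts$nares_post[2], pts$septum_post_ant[2]))
  if (!(pts$ba[2] > pts$nasion[2]))
    nv_stop("basion must be posterior to nasion (ba.y > nasion.y)")
  if (!(pts$ethmoid_pi[2] > pts$nasion[2] && pts$ethmoid_pi[2] < pts$ba[2]))
    nv_stop("ethmoid point must lie strictly between nasion and basion along y")
  structure(pts, class = "nv_landmarks")
}

#' @export
print.nv_landmarks <- function(x, ...) {
  cat("<nv_landmarks> (mm, LPS)\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-16s (%s)\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Read / write a landmark set as JSON
#'
#' The JSON file has keys `ba`, `nasion`, `ethmoid_pi`, `septum_post_ant`,
#' `nares_post` (each `[x, y, z]` mm) and `convention`, which must be `"LPS"`.
#'
#' @param path JSON file path.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$convention) || !identical(toupper(j$convention), "LPS"))
    nv_stop("landmark file must declare convention \"LPS\"")
  need <- c("ba", "nasion", "ethmoid_pi", "septum_post_ant", "nares_post")
  miss <- setdiff(need, names(j))
  if (length(miss))
    nv_stop(sprintf("landmark file missing key(s): %s", paste(miss, collapse = ", ")))
  nv_landmarks(j$ba, j$nasion, j$ethmoid_pi, j$septum_post_ant, j$nares_post)
}

#' @rdname read_landmarks
#' @param landmarks an [nv_landmarks()].
#' @export
write_landmarks <- function(landmarks, path) {
  if (!inherits(landmarks, "nv_landmarks")) nv_stop("`landmarks` must be nv_landmarks")
  j <- c(unclass(landmarks), list(convention = "LPS"))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# all five landmarks inside the volume's world bounds
check_landmarks_in_volume <- function(landmarks, volume) {
  b <- world_bounds(volume)
  for (nm in names(unclass(landmarks))) {
    p <- landmarks[[nm]]
    if (any(p < b["lower", ]) || any(p > b["upper", ]))
      nv_stop(sprintf("landmark `%s` (%s) lies outside the volume bounds", nm,
                      paste(format(p), collapse = ", ")))
  }
  invisible(TRUE)
}
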