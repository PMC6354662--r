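# Independent oracles and fixture builders. Everything here is deliberately
# written along a different route than the package implementation: graph
# components via igraph, splines via a direct tridiagonal solve, ANOVA mean
# squares via stats::aov, meshes from closed-form geometry.

conn_offsets_df <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- m > 0 & switch(as.character(connectivity),
                         "6" = m <= 1, "18" = m <= 2, "26" = rep(TRUE, length(m)))
  g[keep, , drop = FALSE]
}

# graph-component oracle: returns logical array of the component containing
# seed (1-based index triple), via igraph
oracle_component <- function(arr, seed_idx, connectivity) {
  d <- dim(arr)
  stopifnot(arr[seed_idx[1], seed_idx[2], seed_idx[3]])
  idx <- which(arr)                       # linear indices of true voxels
  coord <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  offs <- conn_offsets_df(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, c(offs$dx[r], offs$dy[r], offs$dz[r]), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    nb_id <- id_of[nb_lin]
    hit <- nb_id > 0L
    from <- c(from, which(ok)[hit]); to <- c(to, nb_id[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  seed_id <- id_of[seed_idx[1], seed_idx[2], seed_idx[3]]
  members <- which(comp$membership == comp$membership[seed_id])
  out <- array(FALSE, d)
  out[idx[members]] <- TRUE
  out
}

oracle_connected <- function(arr, seed_a, seed_b, connectivity) {
  comp <- oracle_component(arr, seed_a, connectivity)
  comp[seed_b[1], seed_b[2], seed_b[3]]
}

# exhaustive-scan threshold rule: largest intensity value such that both
# seeds are air and in different components
oracle_max_disconnecting_threshold <- function(vol_arr, inner, outer, connectivity) {
  u <- sort(unique(as.numeric(vol_arr)))
  best <- NULL
  for (t in u) {
    air <- vol_arr <= t
    if (!air[inner[1], inner[2], inner[3]] || !air[outer[1], outer[2], outer[3]]) next
    if (!oracle_connected(air, inner, outer, connectivity)) best <- t
  }
  best
}

# natural cubic spline by direct tridiagonal solve of the second-derivative
# system (M_1 = M_n = 0), linear extrapolation outside the knots
oracle_natural_spline <- function(kx, ky, xout) {
  n <- length(kx)
  h <- diff(kx)
  M <- numeric(n)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    rhs <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      r <- i - 1
      if (r > 1) A[r, r - 1] <- h[i - 1]
      A[r, r] <- 2 * (h[i - 1] + h[i])
      if (r < n - 2) A[r, r + 1] <- h[i]
      rhs[r] <- 6 * ((ky[i + 1] - ky[i]) / h[i] - (ky[i] - ky[i - 1]) / h[i - 1])
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  eval1 <- function(x) {
    if (x <= kx[1]) {
      s <- (ky[2] - ky[1]) / h[1] - h[1] * (2 * M[1] + M[2]) / 6
      return(ky[1] + s * (x - kx[1]))
    }
    if (x >= kx[n]) {
      s <- (ky[n] - ky[n - 1]) / h[n - 1] + h[n - 1] * (M[n - 1] + 2 * M[n]) / 6
      return(ky[n] + s * (x - kx[n]))
    }
    i <- findInterval(x, kx, rightmost.closed = TRUE)
    t1 <- kx[i + 1] - x; t2 <- x - kx[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (ky[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (ky[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }
  vapply(xout, eval1, 0)
}

# brute-force ROI predicate: plain triple loop over voxel centers
oracle_roi_count <- function(volume, landmarks) {
  sp <- volume$spacing; o <- volume$origin; d <- dim(volume$data)
  ya <- landmarks$nares_post[2]; yp <- landmarks$septum_post_ant[2]
  zf <- superior_spline(landmarks)
  n <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    y <- o[2] + (j - 0.5) * sp[2]
    z <- o[3] + (k - 0.5) * sp[3]
    if (y >= ya && y <= yp && z <= zf(y)) n <- n + 1L
  }
  n
}

# unit cube mesh with exact coordinates, 12 outward triangles
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6))   # x = 1, normal +x
  nv_mesh(v, f)
}

# icosphere: subdivided icosahedron projected on a sphere of radius r
icosphere_mesh <- function(r = 1, subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  nv_mesh(v * r, f)
}

# toy shell fixture: air box cavity inside a one-voxel soft wall, in outer
# air; air intensities carry a small deterministic ramp so the intensity set
# is rich. Optionally pinhole the wall.
make_shell_toy <- function(n = 15, wall_level = 300, pinhole = FALSE) {
  ramp <- array(seq(-1000, -900, length.out = n^3), c(n, n, n))
  arr <- ramp
  lo <- 5; hi <- n - 4
  arr[lo:hi, lo:hi, lo:hi] <- wall_level
  arr[(lo + 1):(hi - 1), (lo + 1):(hi - 1), (lo + 1):(hi - 1)] <-
    ramp[(lo + 1):(hi - 1), (lo + 1):(hi - 1), (lo + 1):(hi - 1)]
  if (pinhole) {
    mid <- (lo + hi) %/% 2
    arr[lo, mid, mid] <- -950
  }
  list(volume = nv_volume(arr, c(1, 1, 1), c(0, 0, 0)),
       inner_idx = rep((lo + hi) %/% 2, 3),
       outer_idx = c(1L, 1L, 1L),
       inner_seed = rep((lo + hi) %/% 2, 3) - 0.5,
       outer_seed = c(0.5, 0.5, 0.5),
       wall_level = wall_level)
}

# landmarks covering a whole grid: planes at the y extremes (inset by eps),
# flat roof just under the top
landmarks_covering <- function(volume, roof = NULL) {
  b <- world_bounds(volume)
  eps <- 1e-3
  if (is.null(roof)) roof <- b["upper", 3] - eps
  ymid <- mean(b[, 2])
  nv_landmarks(
    ba = c(mean(b[, 1]), b["upper", 2] - eps, roof),
    nasion = c(mean(b[, 1]), b["lower", 2] + eps, roof),
    ethmoid_pi = c(mean(b[, 1]), ymid, roof),
    septum_post_ant = c(mean(b[, 1]), b["upper", 2] - 2 * eps, mean(b[, 3])),
    nares_post = c(mean(b[, 1]), b["lower", 2] + 2 * eps, mean(b[, 3])))
}

# random blobby mask: union of random balls, guaranteed non-empty
random_blob_mask <- function(d, n_balls = 3, rmax = max(3, min(d) / 3)) {
  arr <- array(FALSE, d)
  cc <- list(x = seq_len(d[1]) - 0.5, y = seq_len(d[2]) - 0.5, z = seq_len(d[3]) - 0.5)
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, 0.25, 0.75) * d
    r <- runif(1, 2, rmax)
    ex <- (cc$x - ctr[1])^2; ey <- (cc$y - ctr[2])^2; ez <- (cc$z - ctr[3])^2
    arr <- arr | (outer(outer(ex, ey, `+`), ez, `+`) <= r^2)
  }
  nv_mask(arr)
}

# single-cavity phantom spec used for resolution studies
single_cavity_spec <- function(spacing, rng_seed = 20190128L) {
  a <- 3.5; b <- 13; cz <- 3 * 830 / (4 * pi * a * b)
  nv_phantom_spec(
    cavities = list(right = shape_ellipsoid(c(-8, 0, 0), c(a, b, cz))),
    wall_mm = 2,
    weak_patches = list(list(center = c(-8, 0, cz), radius_mm = 3,
                             wall_mm = 2.25 * spacing)),
    blur_sigma_mm = spacing, spacing = spacing, rng_seed = rng_seed)
}

# ASCII STL writer (test-only; the package writes binary STL)
write_ascii_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid oracle", con)
  for (t in seq_len(nrow(mesh$faces))) {
    p <- mesh$vertices[mesh$faces[t, ], , drop = FALSE]
    writeLines(c("  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p[1, 1], p[1, 2], p[1, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", p[2, 1], p[2, 2], p[2, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", p[3, 1], p[3, 2], p[3, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid oracle", con)
}
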