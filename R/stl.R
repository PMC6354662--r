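# STL read/write. Binary little-endian STL (80-byte header, uint32 facet
# count, 50-byte facet records) is the canonical output - that is what
# printers consume; ASCII STL is accepted on input only. STL stores a
# triangle soup in float32, so a round trip merges shared vertices back by
# exact coordinate identity and is lossless up to float32 quantization.

#' Write a mesh as binary STL
#'
#' @param mesh an [nv_mesh()].
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  if (!inherits(mesh, "nv_mesh")) nv_stop("`mesh` must be an nv_mesh")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "nasovol binary STL"))[1:80]
  writeBin(hdr, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh$vertices
  F <- mesh$faces
  for (f in seq_len(nf)) {
    p1 <- V[F[f, 1], ]; p2 <- V[F[f, 2], ]; p3 <- V[F[f, 3], ]
    u <- p2 - p1; w <- p3 - p1
    n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3], u[1] * w[2] - u[2] * w[1])
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Shared vertices are merged by exact (float32) coordinate identity so the
#' triangle soup becomes an indexed mesh again.
#'
#' @param path STL file path.
#' @return An [nv_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  sz <- file.info(path)$size
  if (sz < 15) nv_stop("file too short to be an STL")
  r <- readBin(path, "raw", n = min(sz, 512))
  head_txt <- rawToChar(r[r != as.raw(0)][1:min(80, sum(r != as.raw(0)))])
  is_binary <- FALSE
  if (sz >= 84) {
    nf <- readBin(readBin(path, "raw", n = 84)[81:84], "integer", size = 4, endian = "little")
    if (sz == 84 + 50 * nf) is_binary <- TRUE
  }
  if (is_binary) return(stl_read_binary(path))
  if (grepl("^\\s*solid", head_txt)) return(stl_read_ascii(path))
  nv_stop("malformed STL: neither a consistent binary record count nor an ASCII solid")
}

stl_read_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  if (nf < 0) nv_stop("malformed STL record count")
  tri <- matrix(0, nf * 3L, 3L)
  for (f in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) nv_stop("truncated binary STL")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tri[(3 * f - 2):(3 * f), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  soup_to_mesh(tri)
}

stl_read_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    nv_stop("malformed ASCII STL: vertex count is not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(nums)) nv_stop("malformed ASCII STL: unparsable vertex line")
  soup_to_mesh(nums)
}

# collapse a triangle soup (3 rows per face, face order preserved) into an
# indexed mesh, merging identical coordinates
soup_to_mesh <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "/")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  nv_mesh(verts, faces)
}
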