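# MetaImage (.mha, local data) reader/writer. The canonical on-disk format:
# spacing-aware, a plain ASCII header followed by raw little-endian voxel
# data, readable by ITK-based tools. MetaImage's Offset is the world position
# of the FIRST VOXEL CENTER; internally the origin is the grid corner, so
# Offset = origin + spacing/2.

mha_write <- function(x, path, element_type, values) {
  d <- dim(x$data)
  offset <- x$origin + 0.5 * x$spacing
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", offset[1], offset[2], offset[3]),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = LPS",
    sprintf("ElementSpacing = %.17g %.17g %.17g", x$spacing[1], x$spacing[2], x$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", element_type),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (element_type == "MET_DOUBLE") {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  } else if (element_type == "MET_UCHAR") {
    writeBin(as.raw(values), con)
  } else nv_stop(sprintf("unsupported ElementType for writing: %s", element_type))
  invisible(path)
}

mha_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) nv_stop("truncated MetaImage header")
    kv <- regmatches(line, regexec("^([A-Za-z]+) *= *(.*)$", line))[[1]]
    if (length(kv) != 3L) nv_stop(sprintf("malformed MetaImage header line: %s", line))
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) nv_stop(sprintf("MetaImage header missing: %s", paste(miss, collapse = ", ")))
  if (hdr$ElementDataFile != "LOCAL")
    nv_stop("only LOCAL MetaImage data is supported")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    nv_stop("compressed MetaImage data is not supported")
  if (!is.null(hdr$BinaryDataByteOrderMSB) && toupper(hdr$BinaryDataByteOrderMSB) == "TRUE")
    nv_stop("big-endian MetaImage data is not supported")
  d <- as.integer(strsplit(trimws(hdr$DimSize), "[[:space:]]+")[[1]])
  sp <- as.numeric(strsplit(trimws(hdr$ElementSpacing), "[[:space:]]+")[[1]])
  if (length(d) != 3L || length(sp) != 3L)
    nv_stop("only 3D MetaImage volumes are supported")
  off <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(trimws(hdr$Offset), "[[:space:]]+")[[1]]) else c(0, 0, 0)
  n <- prod(d)
  et <- hdr$ElementType
  vals <- switch(et,
    MET_DOUBLE = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    MET_SHORT  = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    MET_INT    = readBin(con, "integer", n = n, size = 4, endian = "little"),
    MET_UCHAR  = as.integer(readBin(con, "raw", n = n)),
    nv_stop(sprintf("unsupported ElementType: %s", et)))
  if (length(vals) != n) nv_stop("truncated MetaImage voxel data")
  list(data = array(as.numeric(vals), d), spacing = sp, origin = off - 0.5 * sp)
}
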