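# Minimal NIfTI-1 support: .nii write, .nii/.nii.gz read. Only axis-aligned
# grids (diagonal positive sform, or pixdim fallback); datatypes uint8,
# int16, int32, float32, float64; scl slope/intercept honored on read.
# NIfTI stores the position of the first voxel center; origin is the corner.

nifti_write <- function(x, path, datatype, values) {
  d <- dim(x$data)
  sp <- x$spacing
  center0 <- x$origin + 0.5 * sp
  bitpix <- switch(as.character(datatype), "2" = 8L, "4" = 16L, "64" = 64L,
                   nv_stop("unsupported NIfTI write datatype"))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(35), con)                        # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)                     # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(datatype, 2)                               # datatype
  wi(bitpix, 2)                                 # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, sp, 1, 1, 1, 1))                      # pixdim[8] (qfac 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(raw(2), con)                         # slice_code, xyzt_units
  wf(0); wf(0)                                  # cal_max, cal_min
  wf(0); wf(0)                                  # slice_duration, toffset
  wi(0L, 4); wi(0L, 4)                          # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d, qoffset x,y,z
  wf(c(sp[1], 0, 0, center0[1]))                # srow_x
  wf(c(0, sp[2], 0, center0[2]))                # srow_y
  wf(c(0, 0, sp[3], center0[3]))                # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (datatype == 64L) writeBin(as.numeric(values), con, size = 8, endian = "little")
  else if (datatype == 4L) writeBin(as.integer(values), con, size = 2, endian = "little")
  else writeBin(as.raw(values), con)
  invisible(path)
}

nifti_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  sizeof <- ri(1, 4)
  if (!identical(sizeof, 348L)) nv_stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", n = 36)                   # through dim_info
  dims <- ri(8, 2)
  if (dims[1] < 3 || any(dims[2:4] < 1) || (dims[1] > 3 && any(dims[5:(dims[1] + 1)] > 1)))
    nv_stop("only 3D NIfTI volumes are supported")
  d <- dims[2:4]
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)                            # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", n = 2)          # slice_end, slice_code, xyzt_units
  rf(2); rf(2)                                  # cal_max/min, slice_duration, toffset
  ri(1, 4); ri(1, 4)                            # glmax, glmin
  readBin(con, "raw", n = 104)                  # descrip, aux_file
  qform_code <- ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", n = 16)
  magic <- rawToChar(readBin(con, "raw", n = 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) nv_stop("bad NIfTI magic")
  if (sform_code > 0) {
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6) || any(diag(srow[, 1:3]) <= 0))
      nv_stop("only axis-aligned NIfTI grids with positive spacing are supported")
    sp <- diag(srow[, 1:3])
    center0 <- srow[, 4]
  } else {
    sp <- pixdim[2:4]
    if (any(sp <= 0)) nv_stop("NIfTI pixdim must be positive")
    center0 <- c(0, 0, 0)
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.integer(readBin(con, "raw", n = n)),
    "4"  = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "8"  = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    nv_stop(sprintf("unsupported NIfTI datatype code %d", datatype)))
  if (length(vals) != n) nv_stop("truncated NIfTI voxel data")
  vals <- as.numeric(vals)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, d), spacing = sp, origin = center0 - 0.5 * sp)
}
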