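#' Write / read volumes and masks
#'
#' `write_volume()` and `write_mask()` persist a grid losslessly; the format
#' is inferred from the file extension. MetaImage (`.mha`) is the canonical
#' output format; NIfTI (`.nii`) can be written too and `.nii.gz` is accepted
#' on read. Volumes are stored as float64 so intensities round-trip
#' bit-exactly; masks as 8-bit 0/1.
#'
#' @param x an [nv_volume()] (or [nv_mask()] for the mask variants).
#' @param path file path ending in `.mha` or `.nii` (read also `.nii.gz`).
#' @return `write_*` returns `path` invisibly; `read_*` returns the grid object.
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, "nv_volume")) nv_stop("`x` must be an nv_volume")
  switch(file_format(path),
    mha = mha_write(x, path, "MET_DOUBLE", x$data),
    nii = nifti_write(x, path, 64L, x$data))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  g <- switch(file_format(path), mha = mha_read(path), nii = nifti_read(path))
  nv_volume(g$data, g$spacing, g$origin)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  if (!inherits(x, "nv_mask")) nv_stop("`x` must be an nv_mask")
  switch(file_format(path),
    mha = mha_write(x, path, "MET_UCHAR", as.integer(x$data)),
    nii = nifti_write(x, path, 2L, as.integer(x$data)))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) nv_stop(sprintf("no such file: %s", path))
  g <- switch(file_format(path), mha = mha_read(path), nii = nifti_read(path))
  if (!all(g$data %in% c(0, 1)))
    nv_stop("file does not contain a binary 0/1 mask")
  nv_mask(array(g$data != 0, dim(g$data)), g$spacing, g$origin)
}

file_format <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nii")
  nv_stop(sprintf("unsupported file extension: %s (use .mha or .nii)", basename(path)))
}
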