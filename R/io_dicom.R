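# Minimal DICOM support for single-series axial CT-like stacks, explicit VR
# little endian only. Covers exactly what a CBCT export needs: one slice per
# file, int16 pixels, pixel spacing / slice positions / rescale. Written
# because no DICOM reader is available in the supported dependency set.

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- function() {
  paste0("1.2.826.0.1.3680043.10.1417.",
         paste(sample.int(9, 1), paste(sample.int(10, 12, replace = TRUE) - 1, collapse = ""), sep = ""))
}

dcm_pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element_raw <- function(group, elem, vr, value_raw) {
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(hdr, writeBin(as.integer(length(value_raw)), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_element_raw(group, elem, vr, dcm_pad_even(charToRaw(s), pad))
}

dcm_us <- function(group, elem, v) {
  dcm_element_raw(group, elem, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

dcm_ds_fmt <- function(v) paste(sprintf("%.10g", v), collapse = "\\")

#' Write a volume as a single-series axial DICOM stack
#'
#' One explicit-VR little-endian file per axial slice, int16 pixels with
#' rescale slope 1 / intercept 0 (intensities are rounded to integers).
#'
#' @param x an [nv_volume()].
#' @param dir output directory (created if needed).
#' @param series_uid optional series instance UID; generated when `NULL`.
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(x, dir, series_uid = NULL) {
  if (!inherits(x, "nv_volume")) nv_stop("`x` must be an nv_volume")
  if (any(abs(x$data) > 32767)) nv_stop("intensities exceed int16 range")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  if (is.null(series_uid)) series_uid <- dcm_uid()
  study_uid <- dcm_uid()
  sp <- x$spacing
  first_center <- x$origin + 0.5 * sp
  for (k in seq_len(d[3])) {
    sop_uid <- dcm_uid()
    ipp <- c(first_center[1], first_center[2], first_center[3] + (k - 1) * sp[3])
    pix <- writeBin(as.integer(round(x$data[, , k])), raw(), size = 2, endian = "little")
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0018, 0x0050, "DS", dcm_ds_fmt(sp[3])),
      dcm_str(0x0020, 0x000D, "UI", study_uid),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", sprintf("%d", k)),
      dcm_str(0x0020, 0x0032, "DS", dcm_ds_fmt(ipp)),
      dcm_str(0x0020, 0x0037, "DS", dcm_ds_fmt(c(1, 0, 0, 0, 1, 0))),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2]),      # Rows (y)
      dcm_us(0x0028, 0x0011, d[1]),      # Columns (x)
      dcm_str(0x0028, 0x0030, "DS", dcm_ds_fmt(c(sp[2], sp[1]))),  # row\col spacing
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 1L),
      dcm_str(0x0028, 0x1052, "DS", "0"),
      dcm_str(0x0028, 0x1053, "DS", "1"),
      dcm_element_raw(0x7FE0, 0x0010, "OW", pix))
    meta_body <- c(
      dcm_element_raw(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
      dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
      dcm_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.1417.1"))
    meta <- c(dcm_element_raw(0x0002, 0x0000, "UL",
                              writeBin(length(meta_body), raw(), size = 4, endian = "little")),
              meta_body)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

# string value with NUL/space padding stripped
dcm_rawstr <- function(val) {
  val <- val[val != as.raw(0)]
  sub("[ ]+$", "", rawToChar(val))
}

dcm_parse_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    nv_stop(sprintf("%s: not a DICOM part-10 file", basename(path)))
  pos <- 133L
  out <- list()
  u16 <- function(at) readBin(r[at:(at + 1)], "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function(at) readBin(r[at:(at + 3)], "integer", size = 4, endian = "little")
  while (pos + 7L <= length(r) + 1L && pos <= length(r)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      nv_stop(sprintf("%s: unsupported transfer syntax (implicit VR?)", basename(path)))
    if (vr %in% DCM_LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (vr == "SQ") nv_stop(sprintf("%s: sequences are not supported", basename(path)))
    if (len < 0 || vstart + len - 1L > length(r))
      nv_stop(sprintf("%s: truncated DICOM element", basename(path)))
    val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- switch(vr,
      UI = , CS = , LO = , SH = , IS = dcm_rawstr(val),
      DS = as.numeric(strsplit(dcm_rawstr(val), "\\\\")[[1]]),
      US = readBin(val, "integer", n = len / 2, size = 2, signed = FALSE, endian = "little"),
      UL = readBin(val, "integer", n = len / 4, size = 4, endian = "little"),
      OW = , OB = val,
      dcm_rawstr(val))
    pos <- vstart + len
  }
  out
}

dcm_req <- function(el, key, what, path) {
  if (is.null(el[[key]]))
    nv_stop(sprintf("%s: missing DICOM tag (%s) [%s]", basename(path), key, what))
  el[[key]]
}

#' Read a single-series axial DICOM stack as a volume
#'
#' Slices are sorted by their position along z; voxel spacing is taken from
#' PixelSpacing and the inter-slice interval (SliceThickness for a single
#' slice); the rescale slope/intercept transform is applied to the stored
#' pixel values. The directory must contain exactly one series: files from a
#' second series, inconsistent in-plane spacing, or a non-uniform slice gap
#' are rejected.
#'
#' @param dir directory containing the `.dcm` files (one slice per file).
#' @return An [nv_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) nv_stop(sprintf("no files in %s", dir))
  slices <- lapply(files, dcm_parse_file)
  series <- vapply(seq_along(slices), function(i)
    dcm_req(slices[[i]], "0020,000E", "SeriesInstanceUID", files[i]), "")
  if (length(unique(series)) > 1L)
    nv_stop(sprintf("directory mixes %d DICOM series: %s",
                    length(unique(series)), paste(unique(series), collapse = "; ")),
            data = list(series = unique(series)))
  info <- lapply(seq_along(slices), function(i) {
    el <- slices[[i]]; p <- files[i]
    ps <- dcm_req(el, "0028,0030", "PixelSpacing", p)
    ipp <- dcm_req(el, "0020,0032", "ImagePositionPatient", p)
    iop <- el[["0020,0037"]]
    if (!is.null(iop) && any(abs(iop - c(1, 0, 0, 0, 1, 0)) > 1e-6))
      nv_stop(sprintf("%s: only axial (identity orientation) slices are supported", basename(p)))
    rows <- dcm_req(el, "0028,0010", "Rows", p)
    cols <- dcm_req(el, "0028,0011", "Columns", p)
    bits <- dcm_req(el, "0028,0100", "BitsAllocated", p)
    if (bits != 16L) nv_stop(sprintf("%s: only 16-bit pixel data is supported", basename(p)))
    signed <- !is.null(el[["0028,0103"]]) && el[["0028,0103"]] == 1L
    pix_raw <- dcm_req(el, "7FE0,0010", "PixelData", p)
    pix <- readBin(pix_raw, "integer", n = rows * cols, size = 2,
                   signed = signed, endian = "little")
    slope <- if (is.null(el[["0028,1053"]])) 1 else el[["0028,1053"]]
    inter <- if (is.null(el[["0028,1052"]])) 0 else el[["0028,1052"]]
    thick <- el[["0018,0050"]]
    list(sy = ps[1], sx = ps[2], ipp = ipp, rows = rows, cols = cols,
         pix = pix * slope + inter, thick = thick)
  })
  sx <- vapply(info, `[[`, 0, "sx"); sy <- vapply(info, `[[`, 0, "sy")
  if (diff(range(sx)) > 1e-6 || diff(range(sy)) > 1e-6)
    nv_stop("inconsistent PixelSpacing across slices")
  rows <- vapply(info, `[[`, 0L, "rows"); cols <- vapply(info, `[[`, 0L, "cols")
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    nv_stop("inconsistent slice dimensions across series")
  z <- vapply(info, function(s) s$ipp[3], 0)
  ord <- order(z)
  info <- info[ord]; z <- z[ord]
  nz <- length(info)
  if (nz > 1L) {
    gaps <- diff(z)
    if (any(gaps <= 0)) nv_stop("duplicate or non-increasing slice positions")
    if (diff(range(gaps)) > max(1e-6, 1e-3 * stats::median(gaps)))
      nv_stop(sprintf("non-uniform slice gap: range [%g, %g] mm", min(gaps), max(gaps)))
    sz <- stats::median(gaps)
  } else {
    sz <- info[[1]]$thick
    if (is.null(sz)) nv_stop("single slice without SliceThickness: spacing unknown")
  }
  nx <- cols[1]; ny <- rows[1]
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- info[[k]]$pix  # column(x)-fastest raster
  spacing <- c(sx[1], sy[1], sz)
  origin <- c(info[[1]]$ipp[1], info[[1]]$ipp[2], z[1]) - 0.5 * spacing
  nv_volume(arr, spacing, origin)
}
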