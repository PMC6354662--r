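test_that("volume and mask constructors enforce their invariants", {
  expect_s3_class(nv_volume(array(0, c(2, 2, 2))), "nv_volume")
  expect_error(nv_volume(array(0, c(2, 2))), class = "nasovol_input_error")
  expect_error(nv_volume(array(NA_real_, c(2, 2, 2))), class = "nasovol_input_error")
  expect_error(nv_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               class = "nasovol_input_error")
  expect_error(nv_mask(array(2, c(2, 2, 2))), class = "nasovol_input_error")
  v <- nv_volume(array(1:8, c(2, 2, 2)), spacing = c(0.4, 0.5, 0.6), origin = c(-1, 0, 1))
  expect_equal(voxel_volume(v), 0.4 * 0.5 * 0.6)
  expect_equal(voxel_centers(v)$x, c(-1 + 0.2, -1 + 0.6))
  expect_equal(world_bounds(v)["upper", ], c(x = -0.2, y = 1, z = 2.2))
})

test_that("MetaImage and NIfTI round trips are lossless", {
  set.seed(11)
  vol <- nv_volume(array(rnorm(4 * 5 * 6, sd = 500), c(4, 5, 6)),
                   spacing = c(0.4, 0.5, 0.25), origin = c(-3, 2, 0.5))
  for (ext in c("mha", "nii")) {
    p <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(vol, p)
    back <- read_volume(p)
    expect_identical(back$data, vol$data)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  }
})

test_that("mask round trip preserves voxel count exactly; degenerate 1x1x1 works", {
  set.seed(12)
  m <- nv_mask(array(runif(3 * 4 * 5) > 0.5, c(3, 4, 5)), spacing = c(1, 1, 2))
  for (ext in c("mha", "nii")) {
    p <- file.path(tempdir(), paste0("m.", ext))
    write_mask(m, p)
    expect_identical(sum(read_mask(p)$data), sum(m$data))
  }
  tiny <- nv_volume(array(42, c(1, 1, 1)), spacing = c(0.4, 0.4, 0.4))
  p <- file.path(tempdir(), "tiny.mha")
  write_volume(tiny, p)
  expect_equal(read_volume(p)$data[1, 1, 1], 42)
  expect_error(write_volume(tiny, file.path(tempdir(), "x.foo")),
               class = "nasovol_input_error")
})

test_that("gzipped NIfTI is accepted on read", {
  vol <- nv_volume(array(seq_len(24), c(2, 3, 4)), spacing = c(1, 1, 1))
  p <- file.path(tempdir(), "z.nii")
  write_volume(vol, p)
  pz <- paste0(p, ".gz")
  con_in <- file(p, "rb"); con_out <- gzfile(pz, "wb")
  writeBin(readBin(con_in, "raw", n = file.info(p)$size), con_out)
  close(con_in); close(con_out)
  expect_equal(read_volume(pz)$data, vol$data)
})

test_that("the NIfTI writer is readable by an independent implementation (nibabel)", {
  vol <- nv_volume(array(seq(-1000, 800, length.out = 3 * 4 * 5), c(3, 4, 5)),
                   spacing = c(0.4, 0.4, 0.4), origin = c(1, 2, 3))
  p <- file.path(tempdir(), "oracle.nii")
  write_volume(vol, p)
  script <- paste(
    "import nibabel",
    sprintf("img = nibabel.load('%s')", p),
    "d = img.get_fdata()",
    "print(d.shape[0], d.shape[1], d.shape[2], '%.6f' % d.sum(), '%.4f' % img.affine[0,0], '%.4f' % img.affine[0,3])",
    sep = "\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = TRUE))
  parts <- strsplit(tail(out, 1), "\\s+")[[1]]
  expect_equal(as.numeric(parts[1:3]), c(3, 4, 5))
  expect_equal(as.numeric(parts[4]), sum(vol$data), tolerance = 1e-6)
  expect_equal(as.numeric(parts[5]), 0.4)                 # affine spacing
  expect_equal(as.numeric(parts[6]), 1 + 0.5 * 0.4)       # first voxel center
})

test_that("DICOM series round trip reproduces grid, spacing and intensities", {
  set.seed(13)
  vol <- nv_volume(array(sample(-1000:800, 6 * 5 * 4, replace = TRUE), c(6, 5, 4)),
                   spacing = c(0.4, 0.4, 0.4), origin = c(-2, -1, 0))
  dir <- file.path(tempdir(), "dcm_rt")
  unlink(dir, recursive = TRUE)
  write_dicom_series(vol, dir)
  back <- read_dicom_series(dir)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(back$data, vol$data)            # integer data: exact after rescale
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
})

test_that("a 3-slice series with 0.4 mm slices reads back 0.4 mm isotropic spacing", {
  vol <- nv_volume(array(0, c(4, 4, 3)), spacing = c(0.4, 0.4, 0.4))
  dir <- file.path(tempdir(), "dcm_sp")
  unlink(dir, recursive = TRUE)
  write_dicom_series(vol, dir)
  expect_equal(read_dicom_series(dir)$spacing, c(0.4, 0.4, 0.4), tolerance = 1e-9)
})

test_that("mixed DICOM series are rejected with a series listing", {
  vol <- nv_volume(array(0, c(4, 4, 2)), spacing = c(0.4, 0.4, 0.4))
  dir <- file.path(tempdir(), "dcm_mix")
  dir2 <- file.path(tempdir(), "dcm_mix2")
  unlink(c(dir, dir2), recursive = TRUE)
  write_dicom_series(vol, dir, series_uid = "1.2.3.4")
  write_dicom_series(vol, dir2, series_uid = "1.2.3.5")
  file.copy(file.path(dir2, "slice_0001.dcm"), file.path(dir, "intruder.dcm"))
  err <- expect_error(read_dicom_series(dir), class = "nasovol_input_error")
  expect_match(conditionMessage(err), "1.2.3.4")
  expect_match(conditionMessage(err), "1.2.3.5")
})

test_that("non-uniform slice gaps are rejected", {
  vol <- nv_volume(array(0, c(3, 3, 1)), spacing = c(0.4, 0.4, 0.4))
  dir <- file.path(tempdir(), "dcm_gap")
  unlink(dir, recursive = TRUE)
  write_dicom_series(vol, dir, series_uid = "9.9.9")
  # second and third slice at z = 0.4 and 1.2 mm gaps
  v2 <- nv_volume(array(0, c(3, 3, 1)), spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0.4))
  v3 <- nv_volume(array(0, c(3, 3, 1)), spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 1.6))
  d2 <- file.path(tempdir(), "dcm_gap2"); d3 <- file.path(tempdir(), "dcm_gap3")
  unlink(c(d2, d3), recursive = TRUE)
  write_dicom_series(v2, d2, series_uid = "9.9.9")
  write_dicom_series(v3, d3, series_uid = "9.9.9")
  file.copy(file.path(d2, "slice_0001.dcm"), file.path(dir, "s2.dcm"))
  file.copy(file.path(d3, "slice_0001.dcm"), file.path(dir, "s3.dcm"))
  expect_error(read_dicom_series(dir), "non-uniform slice gap")
})
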