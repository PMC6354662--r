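# voxels within r of a point (used by the channel/block test below)
raster_in_chamber <- function(volume, center, r) {
  cc <- voxel_centers(volume)
  ex <- (cc$x - center[1])^2; ey <- (cc$y - center[2])^2; ez <- (cc$z - center[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) <= r^2
}

test_that("T* on a watertight shell is the largest air intensity below the wall level", {
  toy <- make_shell_toy()
  tstar <- max_disconnecting_threshold(toy$volume, toy$inner_seed, toy$outer_seed, 6)
  u <- sort(unique(as.numeric(toy$volume$data)))
  expect_equal(tstar, max(u[u < toy$wall_level]))
  # and equals the exhaustive scan
  expect_equal(tstar, oracle_max_disconnecting_threshold(
    toy$volume$data, toy$inner_idx, toy$outer_idx, 6))
})

test_that("binary search equals the exhaustive scan on random shell fixtures", {
  set.seed(41)
  for (rep in 1:5) {
    toy <- make_shell_toy(n = sample(11:15, 1), wall_level = sample(200:400, 1))
    # roughen the wall so the barrier is not a single level
    w <- which(toy$volume$data == toy$wall_level)
    toy$volume$data[w] <- toy$wall_level + sample(0:80, length(w), replace = TRUE)
    for (conn in c(6L, 26L)) {
      expect_equal(
        max_disconnecting_threshold(toy$volume, toy$inner_seed, toy$outer_seed, conn),
        oracle_max_disconnecting_threshold(toy$volume$data, toy$inner_idx,
                                           toy$outer_idx, conn))
    }
  }
})

test_that("a pinholed shell has no separating threshold", {
  toy <- make_shell_toy(pinhole = TRUE)
  err <- expect_error(
    max_disconnecting_threshold(toy$volume, toy$inner_seed, toy$outer_seed, 6),
    class = "nasovol_computation_error")
  expect_match(conditionMessage(err), "no separating threshold")
  # the exhaustive scan agrees: no disconnecting threshold exists
  expect_null(oracle_max_disconnecting_threshold(toy$volume$data, toy$inner_idx,
                                                 toy$outer_idx, 6))
})

test_that("raising the wall intensity never decreases T*", {
  set.seed(42)
  for (rep in 1:5) {
    toy <- make_shell_toy(n = 13, wall_level = 250)
    w <- which(toy$volume$data == 250)
    toy$volume$data[w] <- 250 + sample(0:60, length(w), replace = TRUE)
    t1 <- max_disconnecting_threshold(toy$volume, toy$inner_seed, toy$outer_seed, 6)
    up <- toy$volume
    up$data[w] <- up$data[w] + 100
    t2 <- max_disconnecting_threshold(up, toy$inner_seed, toy$outer_seed, 6)
    expect_gte(t2, t1)
  }
})

test_that("the full pipeline recovers an ellipsoidal cavity volume", {
  # weak-patch shell world: recovery within 10%, biased high (never low)
  spec <- nv_phantom_spec(
    cavities = list(cav = shape_ellipsoid(c(0, 0, 0), c(6, 9, 5))),
    wall_mm = 2, weak_patches = list(list(center = c(0, 0, 5), radius_mm = 3,
                                          wall_mm = 0.9)),
    blur_sigma_mm = 0.4, spacing = 0.4, margin_mm = 4)
  ph <- generate_phantom(spec)
  truth <- 4 / 3 * pi * 6 * 9 * 5
  expect_equal(ph$truth$cavity_volumes_mm3[["cav"]], truth)
  acc <- phantom_accuracy_experiment(ph)
  expect_gte(acc$measured_mm3, truth)
  expect_lt((acc$measured_mm3 - truth) / truth, 0.10)
  seg_params <- nv_seg_params(threshold = acc$threshold, seed = c(0, 0, 0),
                              gaussian_sigma = 0)
  seg <- segment_nasal_airway(ph$volume, ph$truth$landmarks, list(), seg_params)
  expect_equal(seg$volume_mm3, acc$measured_mm3)
  expect_identical(seg$volume_mm3, seg$voxel_count * prod(ph$volume$spacing))
  # result mask is one connected component containing the seed
  expect_identical(seg$mask$data,
                   region_grow(seg$mask, c(0, 0, 0), 6)$data)
})

test_that("segmented volume is monotone in threshold and anti-monotone in blocks", {
  spec <- nv_phantom_spec(
    cavities = list(cav = shape_ellipsoid(c(0, 0, 0), c(5, 7, 4))),
    wall_mm = 1.2, noise_sd = 20, blur_sigma_mm = 0.4, spacing = 0.4, margin_mm = 4)
  ph <- generate_phantom(spec)
  lm <- ph$truth$landmarks
  vols <- vapply(c(-700, -500, -300), function(t) {
    segment_nasal_airway(ph$volume, lm, list(),
                         nv_seg_params(threshold = t, seed = c(0, 0, 0),
                                       gaussian_sigma = 0))$volume_mm3
  }, 0)
  expect_true(all(diff(vols) >= 0))
  blk <- nv_block(center = c(0, 0, 3), normal = c(0, 0, 1), radius_mm = 3, thickness_mm = 1.5)
  with_blk <- segment_nasal_airway(ph$volume, lm, list(blk),
                                   nv_seg_params(threshold = -500, seed = c(0, 0, 0),
                                                 gaussian_sigma = 0))
  expect_lte(with_blk$volume_mm3, vols[2])
})

test_that("a channelled side chamber is included unless blocked; blocked seeds are rejected", {
  spec <- nv_phantom_spec(
    cavities = list(cav = shape_ellipsoid(c(0, 0, 0), c(4, 5, 4))),
    sinuses = list(sin = shape_ellipsoid(c(10, 0, 0), c(2.5, 2.5, 2.5))),
    channels = list(list(from_cavity = 1, to_sinus = 1, radius_mm = 0.9)),
    wall_mm = 1.2, noise_sd = 0, blur_sigma_mm = 0, spacing = 0.4, margin_mm = 4)
  ph <- generate_phantom(spec)
  lm <- landmarks_covering(ph$volume)
  p_open <- nv_seg_params(threshold = -400, seed = c(0, 0, 0), gaussian_sigma = 0,
                          median_radius = 0)
  open_seg <- segment_nasal_airway(ph$volume, lm, list(), p_open)
  blk <- nv_block(center = c(6.5, 0, 0), normal = c(1, 0, 0), radius_mm = 2.5,
                  thickness_mm = 1.2)
  closed_seg <- segment_nasal_airway(ph$volume, lm, list(blk), p_open)
  # chamber volume ~ 65 mm^3: open includes it, closed does not
  expect_gt(open_seg$volume_mm3 - closed_seg$volume_mm3, 40)
  expect_false(any(closed_seg$mask$data & raster_in_chamber(ph$volume, c(10, 0, 0), 2)))
  # seed placed inside the blocked slab is a precondition violation
  p_bad <- nv_seg_params(threshold = -400, seed = c(6.5, 0, 0), gaussian_sigma = 0)
  expect_error(segment_nasal_airway(ph$volume, lm, list(blk), p_bad), "blocked")
})
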