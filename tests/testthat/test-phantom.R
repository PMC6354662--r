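test_that("analytic volumes match their closed forms and unions must be disjoint", {
  expect_equal(analytic_volume(shape_ellipsoid(c(0, 0, 0), c(10, 10, 10))),
               4188.79, tolerance = 1e-5)
  expect_equal(analytic_volume(shape_capsule(c(0, 0, 0), c(0, 0, 10), 2)),
               pi * 4 * 10 + 4 / 3 * pi * 8)
  expect_equal(analytic_volume(shape_capsule(c(0, 0, 0), c(0, 0, 10), 2)),
               159.17, tolerance = 1e-4)
  u <- shape_union(shape_ellipsoid(c(-3, 0, 0), c(1, 1, 1)),
                   shape_ellipsoid(c(3, 0, 0), c(1, 1, 1)))
  expect_equal(analytic_volume(u), 2 * 4.18879, tolerance = 1e-4)
  expect_error(shape_union(shape_ellipsoid(c(0, 0, 0), c(2, 2, 2)),
                           shape_ellipsoid(c(1, 0, 0), c(2, 2, 2))),
               "overlap")
})

test_that("a clean rasterized sphere cavity matches the closed form within 1%", {
  spec <- nv_phantom_spec(
    cavities = list(s = shape_ellipsoid(c(0, 0, 0), c(10, 10, 10))),
    wall_mm = 1.2, noise_sd = 0, blur_sigma_mm = 0, spacing = 0.4, margin_mm = 3)
  ph <- generate_phantom(spec)
  # with no blur/noise the cavity is exactly the enclosed air component
  cavity <- region_grow(binarize_air(ph$volume, -400), c(0, 0, 0), 6)
  expect_equal(sum(cavity$data) * 0.4^3, 4188.79, tolerance = 0.01)
})

test_that("phantom generation is deterministic given the seed", {
  s1 <- generate_phantom(single_cavity_spec(0.8, rng_seed = 7L))
  s2 <- generate_phantom(single_cavity_spec(0.8, rng_seed = 7L))
  expect_identical(s1$volume$data, s2$volume$data)
  s3 <- generate_phantom(single_cavity_spec(0.8, rng_seed = 8L))
  expect_false(identical(s1$volume$data, s3$volume$data))
})

test_that("channels connect the cavity to its sinus chamber until blocked", {
  spec <- nv_phantom_spec(
    cavities = list(cav = shape_ellipsoid(c(0, 0, 0), c(4, 4, 4))),
    sinuses = list(sin = shape_ellipsoid(c(9, 0, 0), c(2, 2, 2))),
    channels = list(list(from_cavity = 1, to_sinus = 1, radius_mm = 0.8)),
    wall_mm = 1.2, noise_sd = 0, blur_sigma_mm = 0, spacing = 0.4, margin_mm = 3)
  ph <- generate_phantom(spec)
  air <- binarize_air(ph$volume, -400)
  grown <- region_grow(air, c(0, 0, 0), 6)
  chamber_idx <- world_to_index(ph$volume, c(9, 0, 0))
  expect_true(grown$data[chamber_idx[1], chamber_idx[2], chamber_idx[3]])
  blk <- nv_block(center = c(5.5, 0, 0), normal = c(1, 0, 0),
                  radius_mm = 2, thickness_mm = 1.2)
  blocked <- region_grow(apply_blocks(air, list(blk)), c(0, 0, 0), 6)
  expect_false(blocked$data[chamber_idx[1], chamber_idx[2], chamber_idx[3]])
})

test_that("phantom specs survive a JSON round trip and reject bad material levels", {
  spec <- nasal_pair_phantom_spec()
  p <- file.path(tempdir(), "spec.json")
  write_phantom_spec(spec, p)
  back <- read_phantom_spec(p)
  expect_equal(back$wall_mm, spec$wall_mm)
  expect_equal(back$material_levels, spec$material_levels)
  expect_equal(vapply(back$cavities, analytic_volume, 0),
               vapply(spec$cavities, analytic_volume, 0))
  expect_equal(length(back$weak_patches), 2L)
  expect_error(nv_phantom_spec(cavities = spec$cavities,
                               material_levels = c(air = 300, soft = -1000, bone = 800)),
               "air < soft < bone")
})

test_that("simulated sessions reproduce their stated bias and error structure", {
  tv <- c(1200, 830, 950)
  exact <- simulate_measurement_sessions(tv, bias = 0, error_sd = 0, rng_seed = 1)
  expect_equal(exact$value, rep(tv, 2))
  # sd(d) = sigma * sqrt(2) identity at large n
  tv_big <- rep(1000, 4000)
  tab <- simulate_measurement_sessions(tv_big, bias = 0, error_sd = 50, rng_seed = 2)
  xy <- nasovol:::sessions_wide(tab)
  expect_equal(stats::sd(xy$x - xy$y), 50 * sqrt(2), tolerance = 0.05)
  expect_equal(random_error(xy$x, xy$y), 50, tolerance = 0.05 * 50)
  # a structural session bias is detected by the paired t-test at large n
  tabb <- simulate_measurement_sessions(rep(1000, 1000), bias = c(0, 10),
                                        error_sd = 50, rng_seed = 3)
  xyb <- nasovol:::sessions_wide(tabb)
  expect_lt(paired_t_test(xyb$x, xyb$y)$p, 0.05)
  expect_equal(mean(xyb$x - xyb$y), -10, tolerance = 5)
  # determinism
  t2 <- simulate_measurement_sessions(tv, bias = 0, error_sd = 25, rng_seed = 9)
  t3 <- simulate_measurement_sessions(tv, bias = 0, error_sd = 25, rng_seed = 9)
  expect_identical(t2$value, t3$value)
})

test_that("measurement tables round-trip through CSV", {
  tab <- simulate_measurement_sessions(c(100, 200), bias = 0, error_sd = 5,
                                       rng_seed = 4, unit = "voxel")
  p <- file.path(tempdir(), "meas.csv")
  write_measurements(tab, p)
  back <- read_measurements(p)
  expect_equal(back$value, tab$value)
  expect_identical(attr(back, "unit"), "voxel")
})
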