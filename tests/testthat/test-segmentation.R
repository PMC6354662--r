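test_that("smooth_volume: identity at zero parameters, constants preserved, impulses removed", {
  set.seed(31)
  vol <- nv_volume(array(rnorm(9^3), c(9, 9, 9)), spacing = c(0.4, 0.4, 0.4))
  expect_identical(smooth_volume(vol, 0, 0)$data, vol$data)
  const <- nv_volume(array(7, c(9, 9, 9)))
  expect_equal(smooth_volume(const, 2, 1.5)$data, const$data)
  imp <- nv_volume(array(0, c(9, 9, 9)))
  imp$data[5, 5, 5] <- 100
  expect_equal(smooth_volume(imp, 1, 0)$data, array(0, c(9, 9, 9)))
})

test_that("binarize_air classifies the phantom material levels and is monotone in T", {
  air <- nv_volume(array(-1000, c(4, 4, 4)))
  bone <- nv_volume(array(800, c(4, 4, 4)))
  expect_true(all(binarize_air(air, -400)$data))
  expect_false(any(binarize_air(bone, -400)$data))
  set.seed(32)
  vol <- nv_volume(array(rnorm(10^3, 0, 500), c(10, 10, 10)))
  counts <- vapply(seq(-1000, 800, length.out = 10),
                   function(t) sum(binarize_air(vol, t)$data), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("apply_blocks: identity on empty set, exact brute-force rasterization", {
  set.seed(33)
  m <- nv_mask(array(runif(20^3) > 0.3, c(20, 20, 20)), spacing = c(1, 1, 1))
  expect_identical(apply_blocks(m, list())$data, m$data)
  for (rep in 1:5) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    b <- nv_block(center = runif(3, 4, 16), normal = nrm,
                  radius_mm = runif(1, 2, 6), thickness_mm = runif(1, 2, 5))
    blocked <- apply_blocks(m, list(b))
    # brute-force point-in-slab over every voxel center
    cc <- voxel_centers(m)
    removed <- 0L
    for (k in 1:20) for (j in 1:20) for (i in 1:20) {
      p <- c(cc$x[i], cc$y[j], cc$z[k]) - b$center
      tax <- sum(p * b$normal)
      if (abs(tax) <= b$thickness_mm / 2 && sum(p^2) - tax^2 <= b$radius_mm^2 &&
          m$data[i, j, k]) removed <- removed + 1L
    }
    expect_identical(sum(m$data) - sum(blocked$data), removed)
  }
})

test_that("a block spanning a 1-voxel channel disconnects two chambers", {
  arr <- array(FALSE, c(11, 11, 5))
  arr[2:4, 2:4, 2:4] <- TRUE
  arr[8:10, 2:4, 2:4] <- TRUE
  arr[5:7, 3, 3] <- TRUE                       # channel along x
  m <- nv_mask(arr, spacing = c(1, 1, 1))
  seedA <- c(2.5, 2.5, 2.5); seedB <- c(8.5, 2.5, 2.5)
  expect_true(sum(region_grow(m, seedA, 6)$data) == sum(arr))
  blk <- nv_block(center = c(5.5, 2.5, 2.5), normal = c(1, 0, 0),
                  radius_mm = 3, thickness_mm = 2)
  mb <- apply_blocks(m, list(blk))
  compA <- region_grow(mb, seedA, 6)
  expect_false(compA$data[9, 3, 3])
  expect_equal(sum(compA$data), 27)
  # a block fully outside the grid warns and does nothing
  far <- nv_block(center = c(100, 100, 100), normal = c(0, 0, 1),
                  radius_mm = 1, thickness_mm = 2)
  expect_warning(mf <- apply_blocks(m, list(far)), "outside")
  expect_identical(mf$data, m$data)
})

test_that("region_grow matches the component oracle on canonical cases", {
  arr <- array(FALSE, c(9, 9, 9))
  arr[1:3, 1:3, 1:3] <- TRUE
  arr[6:8, 6:8, 6:8] <- TRUE                   # disjoint cubes
  m <- nv_mask(arr)
  comp <- region_grow(m, c(1.5, 1.5, 1.5), 6)
  expect_equal(sum(comp$data), 27)
  expect_identical(comp$data, oracle_component(arr, c(2, 2, 2), 6))
  # singleton
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  expect_equal(sum(region_grow(nv_mask(s), c(2.5, 2.5, 2.5), 26)$data), 1)
  # corner-touching cubes: separate under 6, joined under 26
  ct <- array(FALSE, c(6, 6, 6))
  ct[1:3, 1:3, 1:3] <- TRUE; ct[4:6, 4:6, 4:6] <- TRUE
  expect_equal(sum(region_grow(nv_mask(ct), c(0.5, 0.5, 0.5), 6)$data), 27)
  expect_equal(sum(region_grow(nv_mask(ct), c(0.5, 0.5, 0.5), 26)$data), 54)
  expect_identical(region_grow(nv_mask(ct), c(0.5, 0.5, 0.5), 18)$data,
                   oracle_component(ct, c(1, 1, 1), 18))
  # seed on a false voxel is rejected with coordinates reported
  err <- expect_error(region_grow(nv_mask(s), c(0.5, 0.5, 0.5), 6),
                      class = "nasovol_input_error")
  expect_match(conditionMessage(err), "seed")
})

test_that("region_grow equals the graph-component oracle on random masks (property)", {
  set.seed(34)
  for (rep in 1:20) {
    d <- sample(6:20, 3, replace = TRUE)
    arr <- array(runif(prod(d)) < runif(1, 0.3, 0.7), d)
    idx <- which(arr)
    if (!length(idx)) next
    seed <- arrayInd(sample(idx, 1), d)[1, ]
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- region_grow(nv_mask(arr), seed - 0.5, conn)
    expect_identical(got$data, oracle_component(arr, seed, conn))
  }
})

test_that("measure_volume applies the voxel calibration exactly", {
  m <- nv_mask(array(TRUE, c(5, 5, 5)), spacing = c(0.4, 0.4, 0.4))
  res <- measure_volume(m)
  expect_identical(res$voxel_count, 125L)
  expect_identical(res$volume_mm3, 125 * 0.4^3)
  empty <- nv_mask(array(FALSE, c(3, 3, 3)))
  expect_equal(measure_volume(empty), list(voxel_count = 0L, volume_mm3 = 0))
})
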