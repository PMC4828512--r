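test_that("extract_voi crops exactly the declared box", {
  vol <- array(seq_len(100 * 120 * 120), c(100L, 120L, 120L))
  box <- voi_box(origin = c(10L, 20L, 30L))
  sub <- extract_voi(vol, box)
  expect_equal(length(sub), 180000L)
  expect_equal(dim(sub), c(50L, 60L, 60L))
  expect_equal(sub[1L, 1L, 1L], vol[11L, 21L, 31L])
  # identity crop
  small <- array(rnorm(4 * 5 * 6), c(4L, 5L, 6L))
  expect_equal(extract_voi(small, voi_box(shape = c(4L, 5L, 6L))), small)
  expect_error(extract_voi(small, voi_box(origin = c(1L, 0L, 0L),
                                          shape = c(4L, 5L, 6L))),
               "exceeds")
})

test_that("build_rvoi implements OR plus low-corner 2x2x2 dilation", {
  d <- c(20L, 20L, 20L)
  m1 <- array(0L, d); m1[11L, 11L, 11L] <- 1L # voxel (10,10,10), 0-based
  # unit kernel is the identity
  rv <- build_rvoi(list(m1), dilation_kernel = c(1L, 1L, 1L))
  expect_equal(rv$voxels, matrix(c(10L, 10L, 10L), 1L,
                                 dimnames = list(NULL, c("x", "y", "z"))))
  # two disjoint single-voxel masks, unit kernel: exactly 2 voxels
  m2 <- array(0L, d); m2[3L, 3L, 3L] <- 1L
  rv2 <- build_rvoi(list(m1, m2), dilation_kernel = c(1L, 1L, 1L))
  expect_equal(nrow(rv2$voxels), 2L)
  # 2x2x2 kernel: single voxel dilates to the cube {10,11}^3
  rv3 <- build_rvoi(list(m1), dilation_kernel = c(2L, 2L, 2L))
  got <- rv3$voxels[order(rv3$voxels[, 1L], rv3$voxels[, 2L],
                          rv3$voxels[, 3L]), ]
  want <- as.matrix(expand.grid(x = 10:11, y = 10:11, z = 10:11))
  want <- want[order(want[, 1L], want[, 2L], want[, 3L]), ]
  expect_equal(unname(got), unname(want))
  expect_error(build_rvoi(list(array(0L, d))), "empty")
  expect_error(build_rvoi(list(m1, array(0L, c(5L, 5L, 5L)))), "grid")
})

test_that("rVOI is monotone, contains the mask union, and grows under dilation", {
  set.seed(20)
  d <- c(15L, 15L, 15L)
  masks <- lapply(1:4, function(i) {
    m <- array(0L, d)
    m[sample.int(prod(d), 40L)] <- 1L
    m
  })
  rv12 <- build_rvoi(masks[1:2])
  rv123 <- build_rvoi(masks[1:3])
  expect_true(all(rv12$mask[rv123$mask == FALSE] == FALSE)) # superset
  expect_gte(nrow(rv123$voxels), nrow(rv12$voxels))
  un <- (masks[[1]] > 0) | (masks[[2]] > 0)
  expect_true(all(rv12$mask[un]))
  rv_unit <- build_rvoi(masks[1:2], dilation_kernel = c(1L, 1L, 1L))
  expect_gte(nrow(rv12$voxels), nrow(rv_unit$voxels))
  # raster enumeration: x fastest
  vx <- rv12$voxels
  lin <- vx[, 1L] + d[1L] * (vx[, 2L] + d[2L] * vx[, 3L])
  expect_true(all(diff(lin) > 0))
})

test_that("rvoi_stats reports size and mean minority percentage", {
  d <- c(10L, 10L, 10L)
  m <- array(0L, d); m[2:4, 2:4, 2:4] <- 1L # 27 voxels
  rv <- build_rvoi(list(m), dilation_kernel = c(1L, 1L, 1L))
  st <- rvoi_stats(rv, list(m))
  expect_equal(st$size, 27L)
  expect_equal(st$minority_pct, 100) # rVOI equals the mask
  # a mask half-covering the rVOI
  m2 <- array(0L, d); m2[2:4, 2:4, 2:4] <- 1L; m2[6L, 6L, 6L] <- 1L
  rv2 <- build_rvoi(list(m2), dilation_kernel = c(1L, 1L, 1L))
  st2 <- rvoi_stats(rv2, list(m))
  expect_equal(st2$size, 28L)
  expect_equal(st2$minority_pct, 100 * 27 / 28)
})
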