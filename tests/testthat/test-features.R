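sch <- feature_schema()

test_that("constant volumes yield the degenerate feature values", {
  vol <- array(3.5, c(11, 11, 11))
  f <- extract_feature_matrix(vol, rbind(c(5L, 5L, 5L), c(0L, 0L, 0L)), sch)
  haar <- f[, sch$group == "haar", drop = FALSE]
  mean_cols <- grepl("_mean$", colnames(haar))
  expect_true(all(haar[, mean_cols] == 3.5))     # pure averages give c
  expect_true(all(abs(haar[, !mean_cols]) < 1e-12)) # differences cancel
  har <- f[1L, sch$group == "haralick"]
  expect_true(all(har[grepl("energy", names(har))] == 1))
  expect_true(all(har[grepl("contrast", names(har))] == 0))
  expect_true(all(har[grepl("correlation", names(har))] == 0))
  expect_true(all(har[grepl("idm", names(har))] == 1))
  expect_true(all(f[, sch$group == "gradient"] == 0))
  expect_equal(unname(f[2L, sch$group == "position"]), c(0, 0, 0))
})

test_that("a hand-written 3^3 pattern matches the direct two-half-block sum", {
  set.seed(4)
  vol <- array(runif(9^3), c(9, 9, 9))
  voxel <- c(4L, 4L, 4L)
  f <- extract_feature_matrix(vol, rbind(voxel), sch)[1L, ]
  # the mirrored-halves template along x at scale 3:
  # mean(high-x slab) - mean(low-x slab), centre plane excluded
  nm <- grep("^haar_s3_.*_mir_HFF$", sch$name, value = TRUE)
  expect_length(nm, 1L)
  hi <- mean(vol[6, 4:6, 4:6]); lo <- mean(vol[4, 4:6, 4:6])
  expect_equal(unname(f[nm]), hi - lo, tolerance = 1e-12)
  # the plain block average (window mean) at scale 3
  nm2 <- grep("^haar_s3_.*_mean$", sch$name, value = TRUE)
  expect_equal(unname(f[nm2]), mean(vol[4:6, 4:6, 4:6]), tolerance = 1e-12)
})

test_that("glcm_matrix reproduces the enumerated small cases", {
  # constant subimage: a single co-occurring pair class
  P <- glcm_matrix(matrix(7, 3, 3), levels = 8L, offset = c(1L, 0L))
  expect_equal(P[1L, 1L], 1)
  expect_equal(sum(P), 1)
  # 2x2 checkerboard, two levels
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  P <- glcm_matrix(cb, levels = 2L, offset = c(1L, 0L))
  expect_equal(P[1L, 2L], 0.5)
  expect_equal(P[2L, 1L], 0.5)
  expect_equal(P[1L, 1L], 0)
  # normalization holds for arbitrary inputs and offsets
  set.seed(1)
  for (i in 1:5) {
    M <- matrix(runif(30), 5, 6)
    off <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L))[[1L + i %% 3L]]
    expect_equal(sum(glcm_matrix(M, 8L, off)), 1, tolerance = 1e-9)
  }
  expect_error(glcm_matrix(matrix(1, 1, 3), 8L, c(1L, 0L)), "degenerate")
})

test_that("haralick_stats matches the four-term hand sums", {
  # point mass
  P1 <- matrix(0, 2, 2); P1[1, 1] <- 1
  s <- haralick_stats(P1)
  expect_equal(unname(s), c(1, 0, 0, 1))
  # checkerboard GLCM
  P2 <- matrix(c(0, .5, .5, 0), 2, 2)
  s <- haralick_stats(P2)
  expect_equal(unname(s), c(0.5, 1, -1, 0.5))
  # uniform GLCM
  P3 <- matrix(0.25, 2, 2)
  s <- haralick_stats(P3)
  expect_equal(unname(s), c(0.25, 0.5, 0, 0.75))
  expect_error(haralick_stats(matrix(0.3, 2, 2)), "normalised")
})

test_that("gradients of a linear ramp are exact finite differences", {
  vol <- array(rep(0:10, times = 11 * 11), c(11, 11, 11)) # I = x
  f <- extract_feature_matrix(vol, rbind(c(5L, 5L, 5L)), sch)[1L, ]
  for (d in 1:4) {
    expect_equal(unname(f[sprintf("grad_x_d%d", d)]), 2 * d)
    expect_equal(unname(f[sprintf("grad_y_d%d", d)]), 0)
    expect_equal(unname(f[sprintf("grad_z_d%d", d)]), 0)
    expect_equal(unname(f[sprintf("grad_diag_d%d", d)]), 2 * d)
  }
})

test_that("all extractors agree with the brute-force reference on random volumes", {
  set.seed(11)
  for (rep in 1:2) {
    vol <- array(runif(11^3), c(11, 11, 11))
    voxels <- rbind(c(5L, 5L, 5L), c(0L, 0L, 0L), c(10L, 10L, 10L),
                    c(1L, 9L, 4L), c(8L, 2L, 7L))
    f <- extract_feature_matrix(vol, voxels, sch)
    for (i in seq_len(nrow(voxels))) {
      v <- voxels[i, ]
      expect_equal(unname(f[i, sch$group == "haar"]), ref_haar(vol, v),
                   tolerance = 1e-9)
      expect_equal(unname(f[i, sch$group == "haralick"]),
                   ref_haralick(vol, v), tolerance = 1e-9)
      expect_equal(unname(f[i, sch$group == "gradient"]),
                   ref_gradient(vol, v), tolerance = 1e-9)
      expect_equal(unname(f[i, sch$group == "position"]), as.numeric(v))
    }
  }
})

test_that("texture features are translation-consistent away from borders", {
  set.seed(5)
  patch <- array(runif(11^3), c(11, 11, 11))
  vol1 <- array(0, c(20, 20, 20)); vol1[1:11, 1:11, 1:11] <- patch
  vol2 <- array(0, c(20, 20, 20)); vol2[3:13, 4:14, 5:15] <- patch
  tex <- sch$group %in% c("haar", "haralick", "gradient")
  f1 <- extract_feature_matrix(vol1, rbind(c(5L, 5L, 5L)), sch)[1L, tex]
  f2 <- extract_feature_matrix(vol2, rbind(c(7L, 8L, 9L)), sch)[1L, tex]
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("extract_feature_matrix honors its shape and determinism contracts", {
  vol <- array(runif(10^3), c(10, 10, 10))
  expect_equal(dim(extract_feature_matrix(vol, rbind(c(1L, 2L, 3L)), sch)),
               c(1L, 315L))
  empty <- extract_feature_matrix(vol, matrix(integer(0), 0L, 3L), sch)
  expect_equal(dim(empty), c(0L, 315L))
  dup <- extract_feature_matrix(vol, rbind(c(2L, 2L, 2L), c(2L, 2L, 2L)), sch)
  expect_equal(dup[1L, ], dup[2L, ])
  expect_error(extract_feature_matrix(vol, rbind(c(10L, 0L, 0L)), sch),
               "out of bounds")
  expect_error(position_features(c(5L, 5L, 5L), c(5L, 10L, 10L)),
               "out of bounds")
  expect_equal(unname(position_features(c(49L, 59L, 59L), c(50L, 60L, 60L))),
               c(49, 59, 59))
})
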