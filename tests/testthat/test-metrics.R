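mk_mask <- function(idx, n = 64L) {
  m <- array(0L, c(4L, 4L, 4L))
  m[idx] <- 1L
  m
}

test_that("overlap_metrics reproduces the worked example and edge cases", {
  pred <- mk_mask(1:6)
  truth <- mk_mask(4:7) # overlap {4,5,6} = 3, |pred| 6, |truth| 4
  r <- overlap_metrics(pred, truth)
  expect_equal(r$dice, 0.6)
  expect_equal(r$relative_overlap, 3 / 7)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.75)
  expect_equal(r$TP, 3L); expect_equal(r$FP, 3L); expect_equal(r$FN, 1L)
  # identity
  r1 <- overlap_metrics(truth, truth)
  expect_equal(c(r1$dice, r1$precision, r1$recall, r1$relative_overlap),
               rep(1, 4))
  # disjoint
  r0 <- overlap_metrics(mk_mask(1:3), mk_mask(10:12))
  expect_equal(c(r0$dice, r0$precision, r0$recall, r0$relative_overlap),
               rep(0, 4))
  # empty prediction: precision 0 by convention
  r2 <- overlap_metrics(mk_mask(integer(0)), truth)
  expect_equal(r2$precision, 0)
  expect_error(overlap_metrics(pred, array(0L, c(5L, 5L, 5L))), "grid")
  expect_error(overlap_metrics(pred, mk_mask(integer(0))), "empty")
})

test_that("Dice and relative overlap obey their identity and symmetry", {
  set.seed(30)
  for (i in 1:50) {
    p <- random_mask_pair()
    a <- overlap_metrics(p$a, p$b)
    b <- overlap_metrics(p$b, p$a)
    expect_equal(a$dice, 2 * a$relative_overlap / (1 + a$relative_overlap),
                 tolerance = 1e-9)
    expect_equal(a$dice, b$dice)
    expect_equal(a$relative_overlap, b$relative_overlap)
    expect_true(all(c(a$dice, a$precision, a$recall,
                      a$relative_overlap) >= 0))
    expect_true(all(c(a$dice, a$precision, a$recall,
                      a$relative_overlap) <= 1))
  }
})

test_that("growing the intersection never decreases any metric", {
  # fixed |pred| = |truth| = 20 on 200 cells, overlap k = 5, 10, ..., 20
  vals <- sapply(c(5L, 10L, 15L, 20L), function(k) {
    pred <- array(0L, c(200L, 1L, 1L)); truth <- array(0L, c(200L, 1L, 1L))
    truth[1:20] <- 1L
    pred[c(seq_len(k), 20L + seq_len(20L - k))] <- 1L
    r <- overlap_metrics(pred, truth)
    c(r$dice, r$precision, r$recall, r$relative_overlap)
  })
  expect_true(all(apply(vals, 1L, function(v) all(diff(v) >= 0))))
})

test_that("volume agreement recovers exact linear relations", {
  v <- c(3, 5, 7, 9, 13)
  a <- volume_agreement(v, v)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$slope, 1)
  expect_equal(a$intercept, 0)
  b <- volume_agreement(v, -v + 4)
  expect_equal(b$pearson_r, -1)
  # 5-point hand data against the covariance formulas
  auto <- c(1, 2, 4, 6, 9); man <- c(2, 3, 3, 7, 8)
  g <- volume_agreement(auto, man)
  n <- 5
  sxy <- sum((auto - mean(auto)) * (man - mean(man))) / (n - 1)
  expect_equal(g$pearson_r, sxy / (sd(auto) * sd(man)), tolerance = 1e-12)
  expect_equal(g$slope, sxy / var(auto), tolerance = 1e-12)
  expect_equal(g$intercept, mean(man) - g$slope * mean(auto),
               tolerance = 1e-12)
  expect_error(volume_agreement(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(volume_agreement(1:2, 1:2), "at least 3")
})

test_that("sign test matches exhaustive enumeration and drops zeros", {
  expect_equal(sign_test(rep(1, 8)), 2^-7)
  expect_equal(sign_test(c(rep(1, 4), rep(-1, 4))), 1)
  # zeros are dropped before counting
  expect_equal(sign_test(c(rep(1, 8), 0, 0)), 2^-7)
  expect_error(sign_test(c(0, 0)), "zero")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    d <- rnorm(n)
    expect_equal(sign_test(d), ref_sign_test(d), tolerance = 1e-12)
  }
})
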