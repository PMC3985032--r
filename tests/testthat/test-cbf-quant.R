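test_that("quantification matches an independent evaluation of the formula", {
  p <- quant_params(n_slices = 1)
  dm <- array(0.01, c(2, 2, 1))
  m0 <- array(1, c(2, 2, 1))
  cbf <- quantify_cbf(dm, m0, p)
  expect_equal(cbf[1, 1, 1], oracle_cbf(0.01, n = 1), tolerance = 1e-10)
  # slice 3 of a 6-slice stack picks up two extra slice-time decay steps
  p6 <- quant_params(n_slices = 6)
  dm6 <- array(0.01, c(2, 2, 6)); m06 <- array(1, c(2, 2, 6))
  cbf6 <- quantify_cbf(dm6, m06, p6)
  expect_equal(cbf6[1, 1, 3], oracle_cbf(0.01, n = 3), tolerance = 1e-10)
})

test_that("quantification is linear in dM and scale-invariant in (dM, M0)", {
  p <- quant_params(n_slices = 2)
  set.seed(2)
  dm <- array(runif(8, 0.001, 0.02), c(2, 2, 2))
  m0 <- array(runif(8, 0.5, 2), c(2, 2, 2))
  base <- quantify_cbf(dm, m0, p)
  expect_equal(quantify_cbf(2 * dm, m0, p), 2 * base, tolerance = 1e-12)
  expect_equal(quantify_cbf(3 * dm, 3 * m0, p), base, tolerance = 1e-12)
  expect_equal(quantify_cbf(dm * 0, m0, p), base * 0)
})

test_that("CBF increases with acquisition index at fixed dM/M0", {
  p <- quant_params(n_slices = 6)
  dm <- array(0.01, c(1, 1, 6)); m0 <- array(1, c(1, 1, 6))
  cbf <- quantify_cbf(dm, m0, p)
  expect_true(all(diff(cbf[1, 1, ]) > 0))
  # a reversed slice order reverses the gradient
  p_rev <- quant_params(n_slices = 6, slice_order = 6:1)
  cbf_rev <- quantify_cbf(dm, m0, p_rev)
  expect_equal(cbf_rev[1, 1, ], rev(cbf[1, 1, ]), tolerance = 1e-12)
})

test_that("low-M0 voxels are masked as missing", {
  p <- quant_params(n_slices = 1)
  m0 <- array(1, c(3, 3, 1))
  m0[1, 1, 1] <- 0.01  # far below 5% of the median
  dm <- array(0.01, c(3, 3, 1))
  cbf <- quantify_cbf(dm, m0, p)
  expect_true(is.na(cbf[1, 1, 1]))
  expect_true(all(is.finite(cbf[-1])))
})

test_that("parameter and shape validation", {
  expect_error(quant_params(lambda_blood = -0.9), "positive")
  expect_error(quant_params(slice_order = c(1, 1, 2)), "permutation")
  p <- quant_params(n_slices = 2)
  expect_error(quantify_cbf(array(1, c(2, 2, 2)), array(1, c(2, 2, 3)), p),
               "identical dimensions")
  expect_error(quantify_cbf(array(1, c(2, 2, 3)), array(1, c(2, 2, 3)), p),
               "slice_order")
  expect_equal(ms_to_s(1680), 1.68)
})

test_that("regional means equal a brute-force voxel loop", {
  set.seed(4)
  map <- array(rnorm(4 * 4 * 2, 50, 10), c(4, 4, 2))
  mask <- array(runif(32) > 0.4, c(4, 4, 2))
  map[2, 2, 1] <- NA  # a masked-out voxel must be skipped
  out <- regional_mean_cbf(map, mask, region = "r", tissue = "gray")
  acc <- c(); cnt <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:2) {
    if (mask[i, j, k] && is.finite(map[i, j, k])) {
      acc <- c(acc, map[i, j, k]); cnt <- cnt + 1
    }
  }
  expect_equal(out$mean_cbf, mean(acc))
  expect_equal(out$voxel_count, cnt)
  # constant field and two-level field
  expect_equal(regional_mean_cbf(array(50, c(2, 2, 1)),
                                 array(TRUE, c(2, 2, 1)))$mean_cbf, 50)
  half <- array(c(40, 40, 60, 60), c(2, 2, 1))
  expect_equal(regional_mean_cbf(half, array(TRUE, c(2, 2, 1)))$mean_cbf, 50)
  expect_error(regional_mean_cbf(map, array(FALSE, c(4, 4, 2))), "empty")
  expect_error(regional_mean_cbf(map, mask[, , 1, drop = FALSE]), "shape")
})

test_that("paired tissue contrast matches the textbook formula", {
  gray <- c(60, 55, 65); white <- c(20, 22, 18)
  d <- gray - white                      # 40, 33, 47
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  out <- tissue_contrast(gray, white)
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), 2), tolerance = 1e-12)

  same <- c(50, 51, 52)
  null_out <- tissue_contrast(same, same)
  expect_equal(null_out$t, 0)
  expect_equal(null_out$p, 1)
  expect_error(tissue_contrast(1:4, 1:3), "paired")
})

test_that("gray exceeds white strongly in a synthetic cohort", {
  co <- generate_cohort(cohort_config(n_subjects = 25, seed = 12))
  out <- tissue_contrast(co$cbf_frontal_gray, co$cbf_frontal_white)
  expect_gt(out$t, 10)
  expect_lt(out$p, 0.001)
})
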