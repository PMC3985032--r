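make_series <- function(acq = tiny_acq(), cbf = tiny_cbf) {
  ser <- simulate_asl_series(cbf, acq)
  des <- build_design_matrix(ser$frame_labels, tr = acq$tr)
  list(ser = ser, des = des)
}

test_that("OLS recovers the generating dM and M0 on noise-free data", {
  s <- make_series()
  fit <- fit_ols(s$ser, s$des)
  brain <- Reduce(`|`, s$ser$masks)
  expect_equal(fit$delta_m_map[brain], s$ser$delta_m_true[brain],
               tolerance = 1e-10)
  expect_equal(fit$m0_map[brain], s$ser$m0_true[brain], tolerance = 1e-10)
  expect_true(all(fit$frame_weights == 1))
})

test_that("coefficients match an independent normal-equations solution", {
  # hand-built 4-frame, 1-voxel problem solved with explicit
  # solve(X'X) X'y, independent of the package's QR path
  y <- c(103, 96, 101, 94)
  labels <- c("control", "tag", "control", "tag")
  X <- cbind(perf = c(0.5, -0.5, 0.5, -0.5), intercept = 1)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)

  acq <- tiny_acq(n_tag = 2, n_control = 2, matrix_shape = c(8, 8),
                  n_slices = 1)
  ser <- simulate_asl_series(tiny_cbf, acq)
  vox <- which(Reduce(`|`, ser$masks), arr.ind = TRUE)[1, ]
  ser$data[vox[1], vox[2], vox[3], ] <- y
  des <- build_design_matrix(labels, tr = acq$tr)
  fit <- fit_ols(ser, des)
  expect_equal(fit$delta_m_map[vox[1], vox[2], vox[3]],
               unname(beta_oracle["perf", 1]), tolerance = 1e-10)
  # M0 is the control-image signal: intercept + dM/2
  expect_equal(fit$m0_map[vox[1], vox[2], vox[3]],
               unname(beta_oracle["intercept", 1] + beta_oracle["perf", 1] / 2),
               tolerance = 1e-10)
})

test_that("pure-noise series yields near-zero coefficient maps", {
  acq <- tiny_acq(n_tag = 30, n_control = 30, noise_sd = 5, seed = 31L)
  ser <- simulate_asl_series(tiny_cbf * 0, acq)
  ser$data <- ser$data - mean(ser$data)  # remove M0 so everything is noise
  des <- build_design_matrix(ser$frame_labels, tr = acq$tr)
  fit <- fit_ols(ser, des)
  dm <- fit$delta_m_map[fit$brain_mask]
  se <- sd(dm) / sqrt(length(dm))
  expect_lt(abs(mean(dm)), 3 * se + 1e-8)
})

test_that("OLS residuals are orthogonal to every design column", {
  acq <- tiny_acq(noise_sd = 8, seed = 13L)
  ser <- simulate_asl_series(tiny_cbf, acq)
  des <- build_design_matrix(ser$frame_labels,
                             task_onsets = c(9, 45), tr = acq$tr)
  fit <- fit_ols(ser, des)
  brain <- Reduce(`|`, ser$masks)
  n_frames <- length(ser$frame_labels)
  Y <- t(matrix(ser$data, prod(dim(brain)), n_frames)[as.vector(brain), ])
  coefs <- t(coef(fit))
  R <- Y - unclass(des) %*% coefs[colnames(des), ]
  for (j in seq_len(ncol(des))) {
    ip <- as.numeric(crossprod(des[, j], R))
    expect_lt(max(abs(ip)) / (sqrt(sum(des[, j]^2)) * max(sqrt(colSums(R^2)))),
              1e-8)
  }
})

test_that("rWLS matches OLS under homoscedastic noise", {
  acq <- tiny_acq(n_tag = 24, n_control = 24, noise_sd = 6, seed = 17L)
  ser <- simulate_asl_series(tiny_cbf, acq)
  des <- build_design_matrix(ser$frame_labels, tr = acq$tr)
  ols <- fit_ols(ser, des)
  rwls <- fit_rwls(ser, des, n_iter = 2)
  brain <- ols$brain_mask
  # per-voxel SE of dM under +/-0.5 coding: sd * sqrt(4 / n)
  se <- acq$noise_sd * sqrt(4 / length(ser$frame_labels))
  diff <- abs(rwls$delta_m_map[brain] - ols$delta_m_map[brain])
  expect_lt(stats::quantile(diff, 0.99), 2 * se)
  # weights roughly equal: max/min spread stays modest
  w <- rwls$frame_weights
  expect_lt(max(w) / min(w), 3)
})

test_that("a spiked frame receives the minimum weight", {
  acq <- tiny_acq(noise_sd = 3, spike_frames = 7L, spike_sd = 30, seed = 19L)
  ser <- simulate_asl_series(tiny_cbf, acq)
  des <- build_design_matrix(ser$frame_labels, tr = acq$tr)
  fit <- fit_rwls(ser, des)
  expect_equal(which.min(fit$frame_weights), 7L)
  # brute-force check: that frame also has the largest pooled residual MS
  expect_equal(which.max(fit$residual_variance_per_frame), 7L)
  # down-weighting pulls the estimate toward the uncorrupted OLS answer
  brain <- fit$brain_mask
  err_rwls <- mean(abs(fit$delta_m_map[brain] - ser$delta_m_true[brain]))
  err_ols <- mean(abs(fit_ols(ser, des)$delta_m_map[brain] -
                        ser$delta_m_true[brain]))
  expect_lt(err_rwls, err_ols)
})

test_that("degenerate noise-free input caps all weights equally", {
  s <- make_series()
  expect_warning(fit <- fit_rwls(s$ser, s$des), "capped")
  expect_true(length(unique(fit$frame_weights)) == 1)
  ols <- fit_ols(s$ser, s$des)
  expect_equal(fit$delta_m_map, ols$delta_m_map, tolerance = 1e-9)
})

test_that("weighted solve is invariant to a global weight rescaling", {
  set.seed(23)
  X <- cbind(1, rnorm(20), rnorm(20))
  Y <- matrix(rnorm(20 * 5), 20)
  w <- runif(20, 0.5, 2)
  c1 <- aslmediate:::wls_solve(X, Y, w)$coef
  c2 <- aslmediate:::wls_solve(X, Y, 1000 * w)$coef
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("dimension and rank errors are reported", {
  s <- make_series()
  bad_des <- build_design_matrix(rep(c("tag", "control"), 10), tr = 4.5)
  expect_error(fit_ols(s$ser, bad_des), "frames")
  expect_error(fit_rwls(s$ser, s$des, n_iter = 0), "n_iter")
  # duplicated regressor among the non-zero columns -> singular design
  X <- cbind(a = rep(1, 10), b = rep(1, 10))
  expect_error(aslmediate:::wls_solve(X, matrix(rnorm(10))), "rank deficient")
})
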