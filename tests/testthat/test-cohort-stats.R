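test_that("ICV normalization matches an explicit regression", {
  icv <- c(1.40, 1.52, 1.47, 1.61, 1.55) * 1e6
  vol <- c(21000, 23500, 22100, 24800, 23900)
  slope <- unname(coef(lm(vol ~ icv))[2])          # independent oracle
  adj_oracle <- vol - slope * (icv - mean(icv))
  adj <- normalize_volume_icv(vol, icv)
  expect_equal(adj, adj_oracle, tolerance = 1e-10)
  expect_lt(abs(cor(adj, icv)), 1e-10)             # decorrelated

  # volumes exactly proportional to ICV collapse to the mean
  expect_equal(normalize_volume_icv(0.001 * icv, icv),
               rep(mean(0.001 * icv), 5), tolerance = 1e-10)
  # uncorrelated volumes are unchanged (slope 0 by construction)
  v0 <- c(1, -1, 1, -1, 0) + 100
  icv0 <- c(1, 1, 2, 2, 1.5)
  expect_equal(normalize_volume_icv(v0, icv0), v0, tolerance = 1e-10)
  expect_warning(normalize_volume_icv(vol, rep(1e6, 5)), "zero variance")
  expect_error(normalize_volume_icv(vol, icv[1:3]), "equal length")
})

test_that("outlier screening applies the z-rule in a single pass", {
  tab <- data.frame(id = sprintf("S%02d", 1:41),
                    m1 = c(rnorm(40, 50, 1), 500),
                    m2 = rnorm(41, 10, 2))
  out <- exclude_outliers(tab, c("m1", "m2"), threshold_sd = 3)
  expect_equal(out$exclusions$id, "S41")
  expect_equal(out$exclusions$measure, "m1")
  expect_equal(nrow(out$retained), 40)

  # identical subjects: zero-SD column is skipped with a warning, none removed
  same <- data.frame(id = 1:5, m1 = rep(3, 5))
  expect_warning(res <- exclude_outliers(same, "m1"), "zero SD")
  expect_equal(nrow(res$retained), 5)

  # an infinite threshold removes nobody
  res_inf <- exclude_outliers(tab, c("m1", "m2"), threshold_sd = Inf)
  expect_equal(nrow(res_inf$retained), 41)
  expect_error(exclude_outliers(tab, "m3"), "m3")
  expect_error(exclude_outliers(tab, "m1", threshold_sd = 0), "threshold_sd")
})

test_that("stratified residual analysis recovers within-stratum structure", {
  set.seed(61)
  n <- 400
  gender <- rep(c(0, 1), each = n / 2)
  age <- 55 + 30 * runif(n)
  ecrf <- 8 - 0.05 * age + rnorm(n, 0, 1.5)
  cbf <- 45 + 1.2 * ecrf + rnorm(n, 0, 3)   # within-stratum slope > 0
  noise <- rnorm(n)
  co <- data.frame(age = age, gender_code = gender, ecrf = ecrf,
                   noise = noise, cbf_gray = cbf)
  out <- stratified_residual_sensitivity(co, c("ecrf", "noise"))
  r_ecrf <- out$r[out$measure == "ecrf"]
  expect_gt(r_ecrf, 0)
  expect_lt(out$p[out$measure == "ecrf"], 0.01)
  # independent noise: |r| below the 3/sqrt(n) null band
  expect_lt(abs(out$r[out$measure == "noise"]), 3 / sqrt(n))
})

test_that("stratification errors are raised on degenerate input", {
  set.seed(62)
  co <- data.frame(age = rep(c(60, 80), 10),
                   gender_code = rep(c(0, 1), each = 10),
                   ecrf = rnorm(20), cbf_gray = 0)
  # CBF fully determined by stratum membership -> zero residual variance
  co$cbf_gray <- with(co, 10 * gender_code + (age > 70))
  expect_error(stratified_residual_sensitivity(co, "ecrf"),
               "zero-variance CBF residuals")
  small <- data.frame(age = c(60, 61, 70, 71), gender_code = c(0, 0, 1, 1),
                      ecrf = rnorm(4), cbf_gray = rnorm(4))
  expect_error(stratified_residual_sensitivity(small, "ecrf"), "n >= 8")
  one_gender <- data.frame(age = rnorm(10, 70), gender_code = 0,
                           ecrf = rnorm(10), cbf_gray = rnorm(10))
  expect_error(stratified_residual_sensitivity(one_gender, "ecrf"),
               "both genders")
})
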