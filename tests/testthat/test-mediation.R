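test_that("residualization matches an explicit normal-equations solve", {
  x <- c(1.2, 2.1, 2.9, 4.2, 5.1, 6.3)
  v <- c(3.1, 4.9, 7.2, 9.1, 10.8, 13.2)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% v)       # independent oracle
  expect_equal(residualize(v, x), as.numeric(v - X %*% beta),
               tolerance = 1e-12)
  expect_equal(sum(residualize(v, x)), 0, tolerance = 1e-10)

  # perfect fit -> zero residuals; orthogonal covariate -> centered values
  expect_equal(residualize(2 * x + 1, x), rep(0, 6), tolerance = 1e-12)
  z <- c(-1, 1, -1, 1, -1, 1)
  v2 <- c(5, 5, 7, 7, 9, 9)
  expect_equal(residualize(v2, z), v2 - mean(v2), tolerance = 1e-12)
  expect_error(residualize(v, cbind(x, x)), "rank deficient")
  expect_error(residualize(v, x[1:3]), "equal length")
})

test_that("partial correlation equals the closed-form formula", {
  set.seed(31)
  x <- rnorm(25); z <- rnorm(25)
  y <- 0.5 * x + 0.7 * z + rnorm(25)
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  r_oracle <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  out <- partial_correlation(x, y, z)
  expect_equal(out$r, r_oracle, tolerance = 1e-10)
  expect_equal(out$df, 25 - 2 - 1)
  expect_equal(out$p_two_tailed, 2 * out$p_one_tailed, tolerance = 1e-12)

  # identical variables: r = 1 regardless of the covariate
  out1 <- partial_correlation(x, x + 0, z)
  expect_equal(out1$r, 1, tolerance = 1e-10)
  expect_error(partial_correlation(rep(1, 25), y, z), "zero-variance")
  expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "need n")
})

test_that("null partial-correlation p-values are uniform", {
  set.seed(77)
  pvals <- replicate(400, {
    x <- rnorm(41); y <- rnorm(41); z <- rnorm(41)
    partial_correlation(x, y, z)$p_two_tailed
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the OLS identity c = c' + ab holds on arbitrary data", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n); m <- rnorm(n, 0.3 * x); y <- rnorm(n, 0.5 * m - 0.2 * x)
    bk <- baron_kenny(x, m, y)
    expect_lt(abs(bk$path_c["est"] - bk$path_c_prime["est"] - bk$indirect),
              1e-10)
  }
})

test_that("classification recovers the generative structure", {
  # full mediation: strong a and b, c' = 0
  d <- make_chain(500, a = 0.8, b = 0.8, c_prime = 0, seed = 51)
  bk <- baron_kenny(d$x, d$m, d$y)
  expect_equal(bk$classification, "full")
  # no predictor-mediator path -> none
  d0 <- make_chain(500, a = 0, b = 0.8, c_prime = 0, seed = 52)
  expect_equal(baron_kenny(d0$x, d0$m, d0$y)$classification, "none")
  # direct and indirect effects both present -> partial
  dp <- make_chain(500, a = 0.8, b = 0.8, c_prime = 0.8, seed = 53)
  expect_equal(baron_kenny(dp$x, dp$m, dp$y)$classification, "partial")
  expect_error(baron_kenny(d$x, d$x, d$y), "collinear")
  expect_error(baron_kenny(d$x[1:3], d$m[1:3], d$y[1:3]), "complete cases")
})

test_that("Sobel test matches its closed form and conventions", {
  out <- sobel_test(1, 0.1, 1, 0.1)
  expect_equal(out$z, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-1 / sqrt(0.02)), tolerance = 1e-12)
  # symmetric in (a, se_a) <-> (b, se_b)
  expect_equal(sobel_test(0.4, 0.12, -1.7, 0.5)$z,
               sobel_test(-1.7, 0.5, 0.4, 0.12)$z, tolerance = 1e-12)
  expect_equal(sobel_test(0, 0.1, 2, 0.1)$z, 0)
  both0 <- sobel_test(0, 0.1, 0, 0.1)
  expect_equal(both0$z, 0)
  expect_equal(both0$p, 1)
  expect_error(sobel_test(1, 0, 1, 0.1), "standard errors")
})

test_that("bootstrap CI is deterministic, degenerate for exact relations", {
  d <- make_chain(41, a = 0.5, b = 0.6, c_prime = 0.1, seed = 61)
  b1 <- bootstrap_mediation(d$x, d$m, d$y, n_resamples = 500, seed = 5)
  b2 <- bootstrap_mediation(d$x, d$m, d$y, n_resamples = 500, seed = 5)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_mediation(d$x, d$m, d$y, n_resamples = 500, seed = 6)
  expect_false(identical(b1$ci, b3$ci))

  # exact linear relations: every resample gives the same ab, CI width 0
  x <- seq(1, 4, length.out = 30)
  m_exact <- 2 * x
  y_exact <- 3 * m_exact
  bz <- bootstrap_mediation(x, m_exact, y_exact, n_resamples = 200, seed = 1)
  expect_equal(unname(diff(bz$ci)), 0, tolerance = 1e-8)
  expect_true(all(bz$resamples == bz$resamples[1]))
  expect_equal(bz$estimate, bz$resamples[1], tolerance = 1e-8)
  expect_error(bootstrap_mediation(d$x, d$m, d$y, n_resamples = 50),
               "n_resamples")
})

test_that("two long bootstrap runs agree within Monte-Carlo error", {
  d <- make_chain(41, a = 0.5, b = 0.6, c_prime = 0, seed = 71)
  b1 <- bootstrap_mediation(d$x, d$m, d$y, n_resamples = 10000, seed = 1)
  b2 <- bootstrap_mediation(d$x, d$m, d$y, n_resamples = 10000, seed = 2)
  # Monte-Carlo SE of the 2.5% quantile from resample quantile theory:
  # se = sqrt(p(1-p)/B) / f(q), density estimated from the resamples
  for (side in 1:2) {
    p <- c(0.025, 0.975)[side]
    f <- density(b1$resamples)
    fq <- approx(f$x, f$y, xout = b1$ci[side])$y
    se <- sqrt(p * (1 - p) / 10000) / fq
    expect_lt(abs(b1$ci[side] - b2$ci[side]), 4 * se)
  }
})

test_that("mediate combines causal steps with the bootstrap CI", {
  d <- make_chain(300, a = 0.7, b = 0.7, c_prime = 0, seed = 81)
  m <- mediate(d$x, d$m, d$y, n_resamples = 1000, seed = 3)
  expect_s3_class(m, "mediation_result")
  expect_equal(m$classification, "full")
  expect_true(m$bootstrap_ci[1] > 0)
  expect_equal(unname(coef(m)["indirect"]),
               unname(coef(m)["a"] * coef(m)["b"]), tolerance = 1e-12)
  expect_equal(unname(coef(m)["c"]),
               unname(coef(m)["c_prime"] + coef(m)["indirect"]),
               tolerance = 1e-10)
  # a null chain must not be classified as mediated
  d0 <- make_chain(300, a = 0, b = 0, c_prime = 0, seed = 82)
  m0 <- mediate(d0$x, d0$m, d0$y, n_resamples = 1000, seed = 3)
  expect_equal(m0$classification, "none")
  # printing works and mentions the classification
  expect_output(print(m), "classification: full")
  expect_output(print(summary(m)), "indirect")
})

test_that("reverse mediation distinguishes directionality", {
  # true chain x -> m -> y at cohort scale: forward CI excludes 0,
  # reverse CI includes 0 (majority behavior checked over a few cohorts)
  wins <- 0
  for (s in 1:5) {
    d <- make_chain(500, a = 0.6, b = 0.6, c_prime = 0, seed = 90 + s)
    fwd <- mediate(d$x, d$m, d$y, n_resamples = 500, seed = s)
    rev <- reverse_mediation_check(d$x, d$m, d$y, n_resamples = 500,
                                   seed = s)
    if (fwd$bootstrap_significant && rev$classification == "none") {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 3)
})

test_that("mediate accepts data-frame column names and covariates", {
  co <- generate_cohort(cohort_config(n_subjects = 120, seed = 14))
  m <- mediate("age", "ecrf_true", "cbf_parietal_gray", data = co,
               covariates = "gender_code", n_resamples = 500, seed = 2)
  expect_lt(m$path_a["est"], 0)      # fitness declines with age
  expect_gt(m$path_b["est"], 0)      # fitness raises CBF
  expect_error(mediate("age", "nope", "cbf_parietal_gray", data = co),
               "nope")
})
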