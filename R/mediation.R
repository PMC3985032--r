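#' Residualize a variable on covariates
#'
#' OLS residuals of `values` on an intercept plus `covariates`. Used to
#' remove gender (or any nuisance covariate) from every variable before
#' correlation and mediation analyses, so results reflect within-gender
#' variation.
#'
#' @param values Numeric vector.
#' @param covariates Numeric vector or matrix (one column per covariate).
#' @return Residual vector (sums to zero).
#' @export
residualize <- function(values, covariates) {
  covariates <- as.matrix(covariates)
  if (length(values) != nrow(covariates)) {
    stop("values and covariates must have equal length", call. = FALSE)
  }
  X <- cbind(1, covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("covariate design is rank deficient", call. = FALSE)
  }
  as.numeric(qr.resid(qr_x, values))
}

#' Partial correlation controlling for covariates
#'
#' Correlation between `x` and `y` after each is residualized on the
#' covariates; equivalent to the closed-form first-order partial correlation.
#' Significance uses the t transform \eqn{t = r\sqrt{df/(1-r^2)}} with
#' df = n - 2 - k covariates; one-tailed tests are appropriate where the
#' direction is hypothesized in advance (e.g., CBF declines with age).
#'
#' @param x,y Numeric vectors.
#' @param covariates Vector or matrix of controls (e.g., gender).
#' @param tails `"two"` (default) or `"one"` (directional, p for the
#'   observed sign).
#' @return List with `r`, `df`, `t`, `p_one_tailed`, `p_two_tailed`, `p`
#'   (the tail requested), `tails`, `n`.
#' @export
partial_correlation <- function(x, y, covariates, tails = c("two", "one")) {
  tails <- match.arg(tails)
  covariates <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2) stop("need n > k_covariates + 2", call. = FALSE)
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  # degenerate when the residuals are zero up to round-off (constant input
  # or input fully explained by the covariates)
  degen <- function(r, v) {
    stats::sd(r) < 1e-12 * max(abs(v - mean(v)), 1)
  }
  if (degen(rx, x) || degen(ry, y)) {
    stop("zero-variance residuals: partial correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p_two <- 2 * stats::pt(-abs(t_stat), df)
  p_one <- stats::pt(-abs(t_stat), df)
  list(r = r, df = df, t = t_stat, p_one_tailed = p_one, p_two_tailed = p_two,
       p = if (tails == "one") p_one else p_two, tails = tails, n = n)
}

# slope and SE of `on` in an OLS fit of y ~ covariate set (with intercept)
ols_slope <- function(y, X, on) {
  fit <- stats::lm(y ~ ., data = as.data.frame(X))
  sm <- summary(fit)$coefficients
  c(est = sm[on, 1], se = sm[on, 2], t = sm[on, 3], p = sm[on, 4])
}

#' Baron-Kenny three-step mediation analysis
#'
#' Fits the three regressions of the classical causal-steps approach:
#' total effect c (outcome ~ predictor), path a (mediator ~ predictor), and
#' the joint model giving path b (mediator effect controlling the predictor)
#' and the direct effect c' (predictor effect controlling the mediator).
#' For OLS these satisfy the identity \eqn{c = c' + ab} exactly; the
#' indirect effect is \eqn{ab}. Two-tailed tests are used throughout.
#'
#' Classification (at `alpha`):
#' \itemize{
#'   \item `"full"` — c, a and b significant while c' is not: the mediator
#'     absorbs the whole predictor effect;
#'   \item `"partial"` — c, a, b and c' all significant;
#'   \item `"none"` — a prerequisite fails (no total effect, no
#'     predictor-mediator path, or no unique mediator effect).
#' }
#' P-values in (`alpha`, 0.10] are flagged `"marginal"` in the labels for
#' reporting, but never change the classification.
#'
#' @param predictor,mediator,outcome Numeric vectors (complete cases,
#'   n >= 5).
#' @param alpha Significance threshold (default 0.05).
#' @return List of class `baron_kenny` with per-path estimate/SE/t/p
#'   (`path_a`, `path_b`, `path_c`, `path_c_prime`), `indirect` (= ab),
#'   `sobel` (z and two-tailed p), `classification`, `labels`, `n`, `alpha`.
#' @export
baron_kenny <- function(predictor, mediator, outcome, alpha = 0.05) {
  n <- length(predictor)
  if (length(mediator) != n || length(outcome) != n) {
    stop("predictor, mediator, outcome must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(predictor, mediator, outcome)
  if (sum(ok) < 5) stop("need at least 5 complete cases", call. = FALSE)
  x <- predictor[ok]; m <- mediator[ok]; y <- outcome[ok]
  if (abs(stats::cor(x, m)) >= 1 - 1e-12) {
    stop("predictor and mediator are collinear", call. = FALSE)
  }

  c_tot <- ols_slope(y, data.frame(x = x), "x")
  a_path <- ols_slope(m, data.frame(x = x), "x")
  joint <- stats::lm(y ~ x + m)
  sm <- summary(joint)$coefficients
  c_prime <- c(est = sm["x", 1], se = sm["x", 2], t = sm["x", 3],
               p = sm["x", 4])
  b_path <- c(est = sm["m", 1], se = sm["m", 2], t = sm["m", 3],
              p = sm["m", 4])

  indirect <- unname(a_path["est"] * b_path["est"])
  sob <- sobel_test(a_path["est"], a_path["se"], b_path["est"], b_path["se"])

  sig <- function(p) p <= alpha
  label <- function(p) {
    if (p <= alpha) "significant"
    else if (p <= 0.10) "marginal"
    else "ns"
  }
  classification <- if (sig(c_tot["p"]) && sig(a_path["p"]) &&
                          sig(b_path["p"])) {
    if (sig(c_prime["p"])) "partial" else "full"
  } else {
    "none"
  }
  structure(list(path_a = a_path, path_b = b_path, path_c = c_tot,
                 path_c_prime = c_prime, indirect = indirect, sobel = sob,
                 classification = classification,
                 labels = c(path_a = label(a_path["p"]),
                            path_b = label(b_path["p"]),
                            path_c = label(c_tot["p"]),
                            path_c_prime = label(c_prime["p"])),
                 n = sum(ok), alpha = alpha),
            class = "baron_kenny")
}

#' Sobel test of an indirect effect
#'
#' Normal-theory z test of the product \eqn{ab} using the delta-method
#' standard error \eqn{\sqrt{b^2 se_a^2 + a^2 se_b^2}}. By convention
#' \eqn{a = b = 0} gives z = 0, p = 1 (no evidence either way).
#'
#' @param path_a,path_b Path estimates. @param se_a,se_b Their standard
#'   errors (> 0).
#' @return List with `z` and two-tailed `p`.
#' @export
sobel_test <- function(path_a, se_a, path_b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be > 0",
                                   call. = FALSE)
  denom <- sqrt(path_b^2 * se_a^2 + path_a^2 * se_b^2)
  if (denom == 0) return(list(z = 0, p = 1))
  z <- unname(path_a * path_b / denom)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Vectorized indirect effects over a block of bootstrap resamples.
# idx: B x n matrix of subject indices. Closed-form OLS via centered sums:
#   a = Sxm / Sxx ;  b = (Smy Sxx - Sxy Sxm) / (Smm Sxx - Sxm^2)
boot_indirect_block <- function(x, m, y, idx) {
  n <- ncol(idx)
  X <- matrix(x[idx], nrow(idx)); M <- matrix(m[idx], nrow(idx))
  Y <- matrix(y[idx], nrow(idx))
  cx <- X - rowMeans(X); cm <- M - rowMeans(M); cy <- Y - rowMeans(Y)
  sxx <- rowSums(cx * cx); smm <- rowSums(cm * cm)
  sxm <- rowSums(cx * cm); sxy <- rowSums(cx * cy); smy <- rowSums(cm * cy)
  det <- smm * sxx - sxm^2
  a <- sxm / sxx
  b <- (smy * sxx - sxy * sxm) / det
  # exactly collinear x and m: the joint model is unidentifiable; follow the
  # lm() aliasing convention and set the aliased coefficient b to zero
  scale2 <- (sxx + smm)^2 + .Machine$double.xmin
  collinear <- sxx > 0 & smm > 0 & det / scale2 < 1e-14
  b[collinear] <- 0
  # zero-variance resamples (constant x or m) are invalid and get redrawn
  bad <- sxx <= 0 | smm <= 0
  out <- a * b
  out[bad] <- NA_real_
  out
}

#' Percentile-bootstrap confidence interval for an indirect effect
#'
#' Case resampling: subjects are drawn with replacement, the indirect effect
#' \eqn{ab} is re-estimated on each resample, and the CI is the percentile
#' interval of the resampled estimates. The indirect effect is declared
#' significant when the interval excludes 0. Degenerate resamples (constant
#' predictor or mediator) are redrawn and counted; resamples where the
#' mediator is exactly collinear with the predictor keep the lm() aliasing
#' convention (the unidentifiable mediator coefficient is zero).
#'
#' @param predictor,mediator,outcome Numeric vectors.
#' @param n_resamples Number of bootstrap resamples (>= 100; 10,000 for
#'   publication-grade intervals).
#' @param confidence Confidence level (default 0.95).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return List of class `mediation_bootstrap`: `estimate` (ab on the full
#'   sample), `ci` (lo, hi), `confidence`, `n_resamples`, `significant`
#'   (CI excludes 0), `n_redrawn`, `resamples` (the resampled ab values).
#' @export
bootstrap_mediation <- function(predictor, mediator, outcome,
                                n_resamples = 10000, confidence = 0.95,
                                seed = 1L) {
  if (n_resamples < 100) stop("n_resamples must be >= 100", call. = FALSE)
  n <- length(predictor)
  ok <- stats::complete.cases(predictor, mediator, outcome)
  x <- predictor[ok]; m <- mediator[ok]; y <- outcome[ok]
  n <- length(x)
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)

  full <- boot_indirect_block(x, m, y, matrix(seq_len(n), 1))
  est <- as.numeric(full)

  vals <- numeric(0)
  n_redrawn <- 0L
  need <- n_resamples
  chunk <- 2000L
  attempts <- 0L
  while (need > 0) {
    attempts <- attempts + 1L
    if (attempts > 50L) {
      stop("could not draw enough non-degenerate resamples; ",
           "input has (near-)constant predictor or mediator", call. = FALSE)
    }
    b <- min(chunk, need + 200L)  # oversample a little to cover redraws
    idx <- matrix(sample.int(n, b * n, replace = TRUE), b, n)
    ab <- boot_indirect_block(x, m, y, idx)
    bad <- !is.finite(ab)
    n_redrawn <- n_redrawn + sum(bad & seq_along(ab) <= need)
    ab <- ab[!bad]
    take <- min(length(ab), need)
    vals <- c(vals, ab[seq_len(take)])
    need <- n_resamples - length(vals)
  }
  alpha <- 1 - confidence
  ci <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2)))
  structure(list(estimate = est, ci = ci, confidence = confidence,
                 n_resamples = n_resamples,
                 significant = ci[1] > 0 || ci[2] < 0,
                 n_redrawn = n_redrawn, resamples = vals, n = n),
            class = "mediation_bootstrap")
}

#' Full mediation analysis: causal steps + Sobel + bootstrap
#'
#' The package's main estimator. Runs the Baron-Kenny regressions, the Sobel
#' test, and the percentile-bootstrap CI of the indirect effect, and
#' combines them into a final classification: `"full"` or `"partial"`
#' require both the causal-steps pattern *and* a bootstrap CI excluding 0
#' (the combined evidence standard); otherwise `"none"`.
#'
#' @param predictor,mediator,outcome Numeric vectors, or (if `data` is
#'   given) column names in `data`.
#' @param data Optional data frame supplying the three variables by name.
#' @param covariates Optional vector/matrix (or column names in `data`) that
#'   every variable is residualized on first (e.g., gender).
#' @param n_resamples,confidence,seed Passed to [bootstrap_mediation()].
#' @param alpha Significance threshold for the causal steps.
#' @return Object of class `mediation_result` combining the `baron_kenny`
#'   fields with `bootstrap_ci`, `n_resamples`, `confidence` and the final
#'   `classification`.
#' @examples
#' cfg <- cohort_config(n_subjects = 200, seed = 7)
#' co <- generate_cohort(cfg)
#' fit <- mediate(co$age, co$ecrf_true, co$cbf_frontal_gray,
#'                n_resamples = 500, seed = 7)
#' fit
#' @export
mediate <- function(predictor, mediator, outcome, data = NULL,
                    covariates = NULL, n_resamples = 10000,
                    confidence = 0.95, seed = 1L, alpha = 0.05) {
  pick <- function(v) {
    if (is.character(v) && !is.null(data)) {
      if (!all(v %in% names(data))) {
        stop("column(s) not in data: ",
             paste(setdiff(v, names(data)), collapse = ", "), call. = FALSE)
      }
      as.matrix(data[v])
    } else {
      v
    }
  }
  x <- drop(pick(predictor)); m <- drop(pick(mediator))
  y <- drop(pick(outcome))
  if (!is.null(covariates)) {
    cv <- pick(covariates)
    x <- residualize(x, cv); m <- residualize(m, cv); y <- residualize(y, cv)
  }
  bk <- baron_kenny(x, m, y, alpha = alpha)
  boot <- bootstrap_mediation(x, m, y, n_resamples = n_resamples,
                              confidence = confidence, seed = seed)
  classification <- if (bk$classification != "none" && boot$significant) {
    bk$classification
  } else {
    "none"
  }
  out <- c(unclass(bk),
           list(bootstrap_ci = boot$ci, confidence = confidence,
                n_resamples = n_resamples,
                bootstrap_significant = boot$significant,
                n_redrawn = boot$n_redrawn,
                resamples = boot$resamples,
                steps_classification = bk$classification,
                seed = seed))
  out$classification <- classification
  class(out) <- "mediation_result"
  out
}

#' Reverse-mediation check
#'
#' Re-runs the mediation with the roles of predictor and mediator exchanged
#' (e.g., does *age* mediate the fitness effect on CBF?). A non-significant
#' reverse indirect effect alongside a significant forward one supports the
#' forward model's directionality.
#'
#' @inheritParams mediate
#' @return A `mediation_result` for the exchanged roles.
#' @export
reverse_mediation_check <- function(predictor, mediator, outcome,
                                    data = NULL, covariates = NULL,
                                    n_resamples = 10000, confidence = 0.95,
                                    seed = 1L, alpha = 0.05) {
  mediate(mediator, predictor, outcome, data = data, covariates = covariates,
          n_resamples = n_resamples, confidence = confidence, seed = seed,
          alpha = alpha)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation analysis (n =", x$n, ")\n")
  path_line <- function(nm, p, key) {
    sprintf("  %-12s b = %8.4f  SE = %7.4f  t = %7.3f  p = %.4f (%s)\n",
            nm, p["est"], p["se"], p["t"], p["p"], x$labels[[key]])
  }
  cat(path_line("a (X->M)", x$path_a, "path_a"))
  cat(path_line("b (M->Y|X)", x$path_b, "path_b"))
  cat(path_line("c (X->Y)", x$path_c, "path_c"))
  cat(path_line("c' (X->Y|M)", x$path_c_prime, "path_c_prime"))
  cat(sprintf("  indirect ab = %.4f; Sobel z = %.3f, p = %.4f\n",
              x$indirect, x$sobel$z, x$sobel$p))
  cat(sprintf("  %d%% percentile bootstrap CI (%d resamples): [%.4f, %.4f]\n",
              round(100 * x$confidence), x$n_resamples,
              x$bootstrap_ci[1], x$bootstrap_ci[2]))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @export
summary.mediation_result <- function(object, ...) {
  paths <- rbind(a = object$path_a, b = object$path_b, c = object$path_c,
                 c_prime = object$path_c_prime)
  out <- list(paths = as.data.frame(paths), indirect = object$indirect,
              sobel = object$sobel, bootstrap_ci = object$bootstrap_ci,
              confidence = object$confidence,
              classification = object$classification, n = object$n)
  class(out) <- "summary.mediation_result"
  out
}

#' @export
print.summary.mediation_result <- function(x, ...) {
  cat("Mediation paths:\n")
  print(round(x$paths, 4))
  cat(sprintf("indirect = %.4f, Sobel z = %.3f (p = %.4f), %d%% CI [%.4f, %.4f]\n",
              x$indirect, x$sobel$z, x$sobel$p, round(100 * x$confidence),
              x$bootstrap_ci[1], x$bootstrap_ci[2]))
  cat("classification:", x$classification, "\n")
  invisible(x)
}

#' @export
coef.mediation_result <- function(object, ...) {
  c(a = unname(object$path_a["est"]), b = unname(object$path_b["est"]),
    c = unname(object$path_c["est"]),
    c_prime = unname(object$path_c_prime["est"]),
    indirect = object$indirect)
}

#' @export
confint.mediation_result <- function(object, parm = "indirect",
                                     level = NULL, ...) {
  ci <- matrix(object$bootstrap_ci, 1,
               dimnames = list("indirect", c("lower", "upper")))
  ci
}

#' Histogram of the bootstrap indirect-effect distribution
#' @param x A `mediation_result`. @param ... Passed to [graphics::hist()].
#' @export
plot.mediation_result <- function(x, ...) {
  graphics::hist(x$resamples, breaks = 40, col = "grey80", border = "white",
                 main = "Bootstrap distribution of indirect effect ab",
                 xlab = "ab", ...)
  graphics::abline(v = x$bootstrap_ci, lty = 2)
  graphics::abline(v = 0, col = 2)
  invisible(x)
}
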