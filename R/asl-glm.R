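# Weighted least squares on a multi-voxel response matrix.
# X: frames x k design, Y: frames x voxels, w: per-frame weights.
# Returns k x voxels coefficients and the frames x voxels residuals.
wls_solve <- function(X, Y, w = rep(1, nrow(X))) {
  sw <- sqrt(w)
  Xw <- X * sw
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(X)) {
    stop("design matrix is rank deficient (singular design)", call. = FALSE)
  }
  coef <- qr.coef(qr_x, Y * sw)
  resid <- Y - X %*% coef
  list(coef = coef, resid = resid)
}

# Columns that are identically zero (e.g., bold/activation with no task)
# carry no information and would make the design singular; they are dropped
# from the solve and reported with zero coefficients.
active_columns <- function(design) {
  apply(design, 2, function(col) any(col != 0))
}

fit_asl_glm <- function(series, design, weights) {
  if (!inherits(series, "asl_series")) {
    stop("series must be an asl_series", call. = FALSE)
  }
  n_frames <- dim(series$data)[4]
  if (nrow(design) != n_frames) {
    stop("design has ", nrow(design), " rows but series has ", n_frames,
         " frames", call. = FALSE)
  }
  brain <- Reduce(`|`, series$masks)
  shape <- dim(brain)
  Y <- t(matrix(series$data, prod(shape), n_frames)[as.vector(brain), ,
                                                    drop = FALSE])
  X <- unclass(design)
  keep <- active_columns(X)
  sol <- wls_solve(X[, keep, drop = FALSE], Y, weights)
  coef <- matrix(0, ncol(X), ncol(Y),
                 dimnames = list(colnames(X), NULL))
  coef[keep, ] <- sol$coef

  to_map <- function(v) {
    m <- array(NA_real_, shape)
    m[brain] <- v
    m
  }
  delta_m <- coef["baseline_perfusion", ]
  baseline <- coef["baseline_signal", ]
  list(coef = coef, resid = sol$resid, brain = brain,
       maps = list(
         # with +/-0.5 coding the intercept is the tag/control mid-point;
         # M0 is the static tissue (control-image) signal = intercept + dM/2
         delta_m_map = to_map(delta_m),
         m0_map = to_map(baseline + 0.5 * delta_m),
         bold_map = to_map(coef["bold_hrf", ]),
         activation_map = to_map(coef["activation_perfusion", ])))
}

new_perfusion_fit <- function(parts, design, weights, method, n_iter = NULL,
                              capped = integer(0)) {
  rv <- rowMeans(parts$resid^2)
  structure(list(delta_m_map = parts$maps$delta_m_map,
                 m0_map = parts$maps$m0_map,
                 bold_map = parts$maps$bold_map,
                 activation_map = parts$maps$activation_map,
                 frame_weights = weights,
                 residual_variance_per_frame = rv,
                 capped_frames = capped,
                 brain_mask = parts$brain, design = design,
                 method = method, n_iter = n_iter),
            class = "perfusion_fit")
}

#' Ordinary least-squares fit of the ASL GLM
#'
#' Fits the four-regressor design voxelwise to the unsubtracted tag/control
#' series. Under the \eqn{\pm 0.5} perfusion coding, the
#' `baseline_perfusion` coefficient is directly the control-minus-tag
#' difference signal \eqn{\Delta M}, and the static-tissue map \eqn{M_0} is
#' reconstructed as the control-image signal (intercept \eqn{+ \Delta M/2}).
#'
#' @param series An [simulate_asl_series()] `asl_series` (or an ingested
#'   one).
#' @param design An [build_design_matrix()] `asl_design` with as many rows as
#'   the series has frames.
#' @return A `perfusion_fit`: coefficient maps `delta_m_map`, `m0_map`,
#'   `bold_map`, `activation_map` (NA outside the brain mask), unit
#'   `frame_weights`, and `residual_variance_per_frame` (mean squared
#'   residual over in-mask voxels, per frame).
#' @export
fit_ols <- function(series, design) {
  parts <- fit_asl_glm(series, design, rep(1, nrow(design)))
  new_perfusion_fit(parts, design, rep(1, nrow(design)), "ols")
}

#' Robust weighted least-squares fit of the ASL GLM
#'
#' Motion-corrupted volumes inflate the residual variance of their frame;
#' rather than deleting ("scrubbing") them, each frame is *soft-excluded* by
#' weighting it with the inverse of its residual variance. The variance of
#' frame t is estimated by pooling squared residuals over all in-mask voxels
#' of that volume. The fit iterates: OLS (unit weights), estimate per-frame
#' variances, set weights 1/variance, refit; `n_iter` weighted passes are
#' run (default 2).
#'
#' Frames with (near-)zero residual variance — degenerate noise-free input —
#' would receive infinite weight; their variance is floored at
#' `1e-20 * mean(signal^2)` (i.e., weights are capped at the reciprocal
#' floor) with a warning. When every frame hits the cap the weights are
#' equal and the fit reduces to OLS.
#'
#' @inheritParams fit_ols
#' @param n_iter Number of reweighting passes (>= 1).
#' @return A `perfusion_fit` (see [fit_ols()]) whose `frame_weights` are the
#'   final inverse-variance weights; `capped_frames` lists frames whose
#'   variance was floored.
#' @export
fit_rwls <- function(series, design, n_iter = 2) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  w <- rep(1, nrow(design))
  parts <- fit_asl_glm(series, design, w)
  capped <- integer(0)
  for (i in seq_len(n_iter)) {
    rv <- rowMeans(parts$resid^2)
    floor_val <- 1e-20 * mean(series$data^2) + 1e-300
    hit <- rv < floor_val
    if (any(hit)) {
      capped <- union(capped, which(hit))
      rv[hit] <- floor_val
    }
    w <- 1 / rv
    parts <- fit_asl_glm(series, design, w)
  }
  if (length(capped)) {
    warning(length(capped), " frame(s) had (near-)zero residual variance; ",
            "weights capped at ", format(1 / floor_val, digits = 3),
            call. = FALSE)
  }
  new_perfusion_fit(parts, design, w, "rwls", n_iter, sort(capped))
}

#' @export
print.perfusion_fit <- function(x, ...) {
  d <- dim(x$delta_m_map)
  cat(sprintf("Voxelwise ASL GLM fit (%s%s): %d x %d x %d grid, %d frames\n",
              toupper(x$method),
              if (!is.null(x$n_iter)) sprintf(", %d iterations", x$n_iter)
              else "",
              d[1], d[2], d[3], length(x$frame_weights)))
  dm <- x$delta_m_map[x$brain_mask]
  m0 <- x$m0_map[x$brain_mask]
  cat(sprintf("  in-mask mean dM = %.3f, mean M0 = %.1f (signal units)\n",
              mean(dm), mean(m0)))
  w <- x$frame_weights / max(x$frame_weights)
  cat(sprintf("  frame weights (relative): min %.3f, median %.3f\n",
              min(w), stats::median(w)))
  if (length(x$capped_frames)) {
    cat("  variance floor hit at frame(s):",
        paste(x$capped_frames, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.perfusion_fit <- function(object, ...) {
  brain <- object$brain_mask
  cbind(bold_hrf = object$bold_map[brain],
        baseline_perfusion = object$delta_m_map[brain],
        activation_perfusion = object$activation_map[brain],
        baseline_signal = object$m0_map[brain] -
          0.5 * object$delta_m_map[brain])
}

#' Per-frame pooled residual variance of a perfusion fit
#' @param object A `perfusion_fit`.
#' @param ... Unused.
#' @return Numeric vector, one pooled (over in-mask voxels) mean squared
#'   residual per frame.
#' @export
residuals.perfusion_fit <- function(object, ...) {
  object$residual_variance_per_frame
}

#' Diagnostic plot of frame weights and residual variance
#' @param x A `perfusion_fit`. @param ... Passed to [graphics::plot()].
#' @export
plot.perfusion_fit <- function(x, ...) {
  w <- x$frame_weights / max(x$frame_weights)
  graphics::plot(seq_along(w), w, type = "h", lwd = 2,
                 xlab = "frame", ylab = "relative weight",
                 main = sprintf("%s frame weights", toupper(x$method)), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
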