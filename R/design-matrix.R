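#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response shape 6, undershoot shape 16,
#' rate 1, undershoot ratio 1/6), normalized to unit peak; the response peaks
#' near 5 s after onset.
#'
#' @param t Time in seconds (vector); values < 0 return 0.
#' @return HRF amplitude at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  peak <- stats::dgamma(5, shape = 6, rate = 1) -
    stats::dgamma(5, shape = 16, rate = 1) / 6
  h / peak
}

# Boxcar task waveform convolved with the canonical HRF, sampled at frame
# times. Convolution on a fine grid (dt seconds) to keep the sampled values
# stable across TR choices.
convolve_task_hrf <- function(frame_times, task_onsets, task_duration,
                              dt = 0.1) {
  if (length(task_onsets) == 0) return(numeric(length(frame_times)))
  t_max <- max(frame_times) + 32
  grid <- seq(0, t_max, by = dt)
  box <- numeric(length(grid))
  for (on in task_onsets) {
    box[grid >= on & grid < on + task_duration] <- 1
  }
  kern <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(grid)] * dt
  stats::approx(grid, conv, xout = frame_times, rule = 2)$y
}

#' Build the four-regressor ASL GLM design matrix
#'
#' The unsubtracted tag/control ASL time series is modeled with exactly four
#' regressors:
#' \describe{
#'   \item{bold_hrf}{task BOLD response: canonical HRF convolved with the
#'     task blocks, sampled at frame times (all zero when `task_onsets` is
#'     empty; the column is retained for shape stability).}
#'   \item{baseline_perfusion}{the alternating tag/control waveform, coded
#'     +0.5 on control frames and -0.5 on tag frames so that its coefficient
#'     is directly the control-minus-tag difference signal \eqn{\Delta M}.}
#'   \item{activation_perfusion}{the same alternating waveform gated to
#'     task-on frames (zero elsewhere) — perfusion change during the task.}
#'   \item{baseline_signal}{constant 1: the static tissue signal level.}
#' }
#'
#' @param frame_labels Character vector of `"tag"` / `"control"`, one per
#'   frame.
#' @param task_onsets Numeric vector of task block onsets, seconds from the
#'   start of the run. May be empty.
#' @param tr Repetition time, seconds per frame.
#' @param task_duration Task block duration, seconds (default 18, a
#'   breath-hold block).
#' @return An object of class `asl_design`: the n_frames x 4 design matrix
#'   with named columns, plus `frame_labels` and `tr` attributes.
#' @export
build_design_matrix <- function(frame_labels, task_onsets = numeric(0),
                                tr = 4.5, task_duration = 18) {
  if (length(frame_labels) == 0) stop("frame_labels is empty", call. = FALSE)
  if (!all(frame_labels %in% c("tag", "control"))) {
    bad <- unique(setdiff(frame_labels, c("tag", "control")))
    stop("unknown frame label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  n <- length(frame_labels)
  frame_times <- tr * (seq_len(n) - 1)

  bold_hrf <- convolve_task_hrf(frame_times, task_onsets, task_duration)
  baseline_perfusion <- ifelse(frame_labels == "control", 0.5, -0.5)
  task_on <- logical(n)
  for (on in task_onsets) {
    task_on <- task_on | (frame_times >= on & frame_times < on + task_duration)
  }
  activation_perfusion <- baseline_perfusion * task_on
  X <- cbind(bold_hrf = bold_hrf,
             baseline_perfusion = baseline_perfusion,
             activation_perfusion = activation_perfusion,
             baseline_signal = rep(1, n))
  structure(X, frame_labels = frame_labels, tr = tr, class = "asl_design")
}

#' @export
print.asl_design <- function(x, ...) {
  cat("ASL GLM design matrix:", nrow(x), "frames x", ncol(x), "regressors\n")
  labs <- attr(x, "frame_labels")
  cat(sprintf("  %d tag / %d control frames, TR = %g s\n",
              sum(labs == "tag"), sum(labs == "control"), attr(x, "tr")))
  cat("  columns:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}
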