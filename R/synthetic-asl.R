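#' ASL acquisition configuration
#'
#' Parameters of a tag/control ASL acquisition plus the nuisance processes of
#' the synthetic signal model. Defaults follow a 3 T six-slice acquisition
#' with TR/TE = 4.5 s / 44 ms, post-labeling delay 0.5 s, and 36 tag + 36
#' control repetitions in strict alternation.
#'
#' The synthetic signal model for voxel v in frame t is
#' \deqn{S_{vt} = M_0(v)\,(1 + drift \cdot (t-1) + bold \cdot HRF(t))
#'   - [tag_t]\,\Delta M(v) + \epsilon_{vt}}
#' with thermal noise \eqn{\epsilon \sim N(0, noise\_sd^2)} and extra noise of
#' SD `spike_sd` on `spike_frames` (motion-corrupted volumes modeled through
#' their variance effect only — no rigid-body transforms).
#'
#' @param n_tag,n_control Numbers of tag and control repetitions (default 36
#'   each; must be equal for the default alternating design).
#' @param tr Repetition time, s. @param te Echo time, s.
#' @param w Post-labeling delay, s.
#' @param t1_blood,t2_blood Blood relaxation times, s.
#' @param lambda_blood Blood water content (dimensionless).
#' @param t_slc Per-slice acquisition duration, s.
#' @param n_slices Number of slices.
#' @param matrix_shape In-plane grid, length-2 integer vector.
#' @param m0 Static tissue signal level (arbitrary scanner units).
#' @param noise_sd Thermal noise SD, signal units.
#' @param drift_slope Fractional signal drift per frame.
#' @param bold_amplitude Fractional BOLD response amplitude (default 0:
#'   baseline-only analysis).
#' @param task_onsets Breath-hold block onsets, s (used when
#'   `bold_amplitude > 0` or the activation regressor should be non-trivial).
#' @param task_duration Breath-hold block length, s.
#' @param spike_frames Integer frame indices (1-based) receiving motion-spike
#'   noise. @param spike_sd Spike noise SD, signal units.
#' @param seed Integer seed.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_tag = 36, n_control = 36, tr = 4.5,
                               te = 0.044, w = 0.5, t1_blood = 1.68,
                               t2_blood = 0.275, lambda_blood = 0.9,
                               t_slc = 0.06, n_slices = 6,
                               matrix_shape = c(32, 32), m0 = 1000,
                               noise_sd = 10, drift_slope = 0,
                               bold_amplitude = 0,
                               task_onsets = seq(18, by = 54, length.out = 6),
                               task_duration = 18,
                               spike_frames = integer(0), spike_sd = 50,
                               seed = 1L) {
  times <- c(tr = tr, te = te, w = w, t1_blood = t1_blood,
             t2_blood = t2_blood, t_slc = t_slc)
  if (any(times <= 0)) stop("all times must be positive", call. = FALSE)
  if (n_tag != n_control) {
    stop("the default alternating design requires n_tag == n_control",
         call. = FALSE)
  }
  n_frames <- n_tag + n_control
  spike_frames <- as.integer(spike_frames)
  if (any(spike_frames < 1 | spike_frames > n_frames)) {
    stop("spike_frames must lie in [1, n_tag + n_control]", call. = FALSE)
  }
  if (length(matrix_shape) != 2 || any(matrix_shape < 4)) {
    stop("matrix_shape must be two in-plane dimensions >= 4", call. = FALSE)
  }
  structure(list(n_tag = as.integer(n_tag), n_control = as.integer(n_control),
                 tr = tr, te = te, w = w, t1_blood = t1_blood,
                 t2_blood = t2_blood, lambda_blood = lambda_blood,
                 t_slc = t_slc, n_slices = as.integer(n_slices),
                 matrix_shape = as.integer(matrix_shape), m0 = m0,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 bold_amplitude = bold_amplitude, task_onsets = task_onsets,
                 task_duration = task_duration, spike_frames = spike_frames,
                 spike_sd = spike_sd, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Quantification parameters matching an acquisition
#'
#' @param acq An [acquisition_config()].
#' @return The [quant_params()] whose constants match the acquisition, so the
#'   quantification stage inverts the simulator's forward model exactly.
#' @export
quant_params_from_acquisition <- function(acq) {
  quant_params(lambda_blood = acq$lambda_blood, w = acq$w,
               t1_blood = acq$t1_blood, t2_blood = acq$t2_blood,
               te = acq$te, t_slc = acq$t_slc, n_slices = acq$n_slices)
}

#' Default geometric tissue/region masks
#'
#' Builds a simple brain phantom on the acquisition grid: an elliptical brain
#' with an inner white-matter core and an outer gray-matter ring, split into
#' anterior (frontal) and posterior (parietal) halves. The four fine regions
#' (frontal/parietal x gray/white) partition the brain; `gray` and `white`
#' are their unions, hence disjoint.
#'
#' @param matrix_shape In-plane dimensions.
#' @param n_slices Number of slices.
#' @return Named list of 3-D logical arrays: `gray`, `white`, `frontal_gray`,
#'   `frontal_white`, `parietal_gray`, `parietal_white`.
#' @export
build_default_masks <- function(matrix_shape = c(32, 32), n_slices = 6) {
  nx <- matrix_shape[1]; ny <- matrix_shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r2 <- ((x - cx) / (0.45 * nx))^2 + ((y - cy) / (0.45 * ny))^2
  brain <- r2 <= 1
  white2d <- ((x - cx) / (0.25 * nx))^2 + ((y - cy) / (0.25 * ny))^2 <= 1
  gray2d <- brain & !white2d
  frontal2d <- y > cy            # anterior half of the plane
  rep_slices <- function(m) array(m, dim = c(nx, ny, n_slices))
  list(gray = rep_slices(gray2d),
       white = rep_slices(white2d),
       frontal_gray = rep_slices(gray2d & frontal2d),
       frontal_white = rep_slices(white2d & frontal2d),
       parietal_gray = rep_slices(gray2d & !frontal2d),
       parietal_white = rep_slices(white2d & !frontal2d))
}

# Ground-truth voxelwise CBF map assembled from the finest mask partition.
cbf_truth_map <- function(regional_cbf, masks) {
  fine <- c("frontal_gray", "frontal_white", "parietal_gray",
            "parietal_white")
  use <- intersect(fine, names(masks))
  if (length(use) == 0) use <- names(masks)
  cbf <- array(0, dim = dim(masks[[1]]))
  for (r in use) {
    if (!r %in% names(regional_cbf)) {
      stop("mask region '", r, "' has no ground-truth CBF value",
           call. = FALSE)
    }
    cbf[masks[[r]]] <- regional_cbf[[r]]
  }
  cbf
}

#' Simulate a tag/control ASL time series for one subject
#'
#' Forward model of the single-compartment quantification: for each voxel the
#' tag/control difference \eqn{\Delta M} is obtained by *inverting* the CBF
#' equation at the voxel's ground-truth perfusion (using the slice's
#' acquisition index), so quantification recovers the generating CBF exactly
#' in the noise-free limit. Control frames carry the static signal
#' \eqn{M_0} modulated by drift and (optionally) a BOLD response; tag frames
#' are additionally reduced by \eqn{\Delta M}; thermal noise and motion-spike
#' noise are added per frame.
#'
#' @param subject Either one row of a [generate_cohort()] data frame or a
#'   named numeric vector of regional ground-truth CBF (mL/100 g/min) for the
#'   fine mask regions.
#' @param acq An [acquisition_config()].
#' @param masks Optional mask list as from [build_default_masks()]; built
#'   from `acq` when omitted.
#' @return An object of class `asl_series`: list with `data` (4-D array
#'   x, y, slice, frame), `frame_labels` (alternating, starting with
#'   `"tag"`), `acquisition`, `masks`, and the ground-truth `cbf_true` map.
#'   Deterministic given `acq$seed`.
#' @export
simulate_asl_series <- function(subject, acq = acquisition_config(),
                                masks = NULL) {
  if (is.data.frame(subject)) {
    stopifnot(nrow(subject) == 1)
    regional_cbf <- subject_regional_cbf(subject)
  } else if (is.numeric(subject) && !is.null(names(subject))) {
    regional_cbf <- subject
  } else {
    stop("subject must be a one-row cohort data frame or a named numeric ",
         "vector of regional CBF", call. = FALSE)
  }
  if (is.null(masks)) {
    masks <- build_default_masks(acq$matrix_shape, acq$n_slices)
  }
  shape <- dim(masks[[1]])
  if (any(vapply(masks, function(m) !identical(dim(m), shape), logical(1)))) {
    stop("all masks must share one spatial shape", call. = FALSE)
  }
  restore <- set_local_seed(acq$seed)
  on.exit(restore(), add = TRUE)

  n_frames <- acq$n_tag + acq$n_control
  frame_labels <- rep(c("tag", "control"), length.out = n_frames)
  brain <- Reduce(`|`, masks)

  cbf_true <- cbf_truth_map(regional_cbf, masks)
  m0_map <- array(0, shape)
  m0_map[brain] <- acq$m0

  # invert CBF = dM/M0 * F(n): dM = M0 * CBF / F(n), slice-wise
  qp <- quant_params_from_acquisition(acq)
  delta_m <- array(0, shape)
  for (s in seq_len(shape[3])) {
    delta_m[, , s] <- m0_map[, , s] * cbf_true[, , s] /
      cbf_scale_factor(qp, s)
  }

  frame_times <- acq$tr * (seq_len(n_frames) - 1)
  bold <- if (acq$bold_amplitude != 0) {
    convolve_task_hrf(frame_times, acq$task_onsets, acq$task_duration)
  } else {
    numeric(n_frames)
  }

  data <- array(0, dim = c(shape, n_frames))
  for (t in seq_len(n_frames)) {
    gain <- 1 + acq$drift_slope * (t - 1) + acq$bold_amplitude * bold[t]
    vol <- m0_map * gain
    if (frame_labels[t] == "tag") vol <- vol - delta_m
    if (acq$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(shape), 0, acq$noise_sd), shape)
    }
    if (t %in% acq$spike_frames && acq$spike_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(shape), 0, acq$spike_sd), shape)
    }
    data[, , , t] <- vol
  }
  structure(list(data = data, frame_labels = frame_labels, acquisition = acq,
                 masks = masks, cbf_true = cbf_true, m0_true = m0_map,
                 delta_m_true = delta_m),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ASL series: %d x %d x %d voxels, %d frames (%d tag, %d control)\n",
              d[1], d[2], d[3], d[4], sum(x$frame_labels == "tag"),
              sum(x$frame_labels == "control")))
  cat("  masks:", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}
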