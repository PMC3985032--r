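#' Quantification parameters for single-compartment CBF
#'
#' Constants of the single-compartment perfusion model at 3 T. Times are all
#' in seconds internally (`ms_to_s()` converts scanner-card values); the
#' 6000 factor converts mL/g/s to mL/100 g/min.
#'
#' @param lambda_blood Water content of blood (dimensionless, default 0.9).
#' @param w Post-labeling delay, s (default 0.5).
#' @param t1_blood Longitudinal relaxation time of blood, s (default 1.68).
#' @param t2_blood Transverse relaxation time of blood, s (default 0.275).
#' @param te Echo time of the readout, s (default 0.044).
#' @param t_slc Acquisition duration of one slice, s (default 0.06).
#' @param slice_order Integer vector mapping slice position to acquisition
#'   index n (1-based); default ascending.
#' @param n_slices Number of slices (used only to build the default
#'   `slice_order`).
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(lambda_blood = 0.9, w = 0.5, t1_blood = 1.68,
                         t2_blood = 0.275, te = 0.044, t_slc = 0.06,
                         slice_order = seq_len(n_slices), n_slices = 6) {
  vals <- c(lambda_blood = lambda_blood, w = w, t1_blood = t1_blood,
            t2_blood = t2_blood, te = te, t_slc = t_slc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all quantification parameters must be positive and finite",
         call. = FALSE)
  }
  slice_order <- as.integer(slice_order)
  if (!setequal(slice_order, seq_along(slice_order))) {
    stop("slice_order must be a permutation of 1..n_slices", call. = FALSE)
  }
  structure(list(lambda_blood = lambda_blood, w = w, t1_blood = t1_blood,
                 t2_blood = t2_blood, te = te, t_slc = t_slc,
                 slice_order = slice_order),
            class = "quant_params")
}

#' Convert milliseconds to seconds
#'
#' Unit converter for scanner-card values (TE, relaxation times are usually
#' quoted in ms); the quantification equations assume seconds throughout.
#'
#' @param ms Time in milliseconds.
#' @return Time in seconds.
#' @export
ms_to_s <- function(ms) ms / 1000

# Scale factor F(n) mapping dM/M0 to CBF for acquisition index n:
#   CBF = dM/M0 * 6000 / (lambda * T1b) * exp((w + t_slc (n-1)) / T1b)
#         * exp(TE / T2b)
# The exponentials undo T1 decay of the label during the post-labeling delay
# plus the per-slice acquisition offset, and T2 decay during the echo time.
cbf_scale_factor <- function(params, n_index) {
  6000 / (params$lambda_blood * params$t1_blood) *
    exp((params$w + params$t_slc * (n_index - 1)) / params$t1_blood) *
    exp(params$te / params$t2_blood)
}

#' Quantify cerebral blood flow from GLM coefficient maps
#'
#' Converts the fitted tag/control difference map \eqn{\Delta M} and static
#' tissue signal map \eqn{M_0} into CBF in mL/100 g/min using the
#' single-compartment model (no blood-tissue exchange):
#' \deqn{CBF = \frac{\Delta M}{M_0} \cdot \frac{6000}{\lambda_{blood}
#'   T_{1,blood}} \exp\!\left(\frac{w + T_{slc}(n-1)}{T_{1,blood}}\right)
#'   \exp\!\left(\frac{TE}{T_{2,blood}}\right)}
#' where n is the (1-based) acquisition index of the voxel's slice. Voxels
#' whose \eqn{|M_0|} falls below `m0_floor_frac` times the median in-mask
#' \eqn{|M_0|} are unreliable (division blow-up) and are set to `NA`.
#'
#' @param delta_m_map,m0_map 3-D arrays (x, y, slice) of GLM coefficients in
#'   signal units, or a [fit_ols()]/[fit_rwls()] `perfusion_fit` in
#'   `delta_m_map` (then `m0_map` is taken from it).
#' @param params A [quant_params()].
#' @param m0_floor_frac Fraction of the median finite |M0| below which a
#'   voxel is masked out (default 0.05).
#' @return 3-D array of CBF in mL/100 g/min (`NA` at low-signal voxels).
#' @export
quantify_cbf <- function(delta_m_map, m0_map = NULL, params = quant_params(),
                         m0_floor_frac = 0.05) {
  if (inherits(delta_m_map, "perfusion_fit")) {
    fit <- delta_m_map
    delta_m_map <- fit$delta_m_map
    m0_map <- fit$m0_map
  }
  if (!identical(dim(delta_m_map), dim(m0_map))) {
    stop("delta_m_map and m0_map must have identical dimensions",
         call. = FALSE)
  }
  if (!inherits(params, "quant_params")) {
    stop("params must be a quant_params object", call. = FALSE)
  }
  dims <- dim(delta_m_map)
  if (length(dims) != 3) stop("maps must be 3-D arrays", call. = FALSE)
  n_slices <- dims[3]
  if (length(params$slice_order) != n_slices) {
    stop("slice_order length (", length(params$slice_order),
         ") does not match number of slices (", n_slices, ")", call. = FALSE)
  }
  abs_m0 <- abs(m0_map)
  med <- stats::median(abs_m0[is.finite(abs_m0) & abs_m0 > 0])
  floor_val <- if (is.finite(med)) m0_floor_frac * med else 0
  low <- !is.finite(abs_m0) | abs_m0 < floor_val

  cbf <- array(NA_real_, dims)
  for (s in seq_len(n_slices)) {
    f <- cbf_scale_factor(params, params$slice_order[s])
    cbf[, , s] <- delta_m_map[, , s] / m0_map[, , s] * f
  }
  cbf[low] <- NA_real_
  cbf
}

#' Mean CBF over a region mask
#'
#' Averages a CBF map over in-mask voxels, skipping missing (low-M0) voxels.
#'
#' @param cbf_map 3-D CBF array from [quantify_cbf()].
#' @param mask 3-D logical array of the same shape.
#' @param region,tissue Optional labels stored in the result.
#' @return A one-row data frame: `region`, `tissue`, `mean_cbf`,
#'   `voxel_count` (number of non-missing voxels averaged).
#' @export
regional_mean_cbf <- function(cbf_map, mask, region = "region",
                              tissue = NA_character_) {
  if (!identical(dim(cbf_map), dim(mask))) {
    stop("mask shape must equal map shape", call. = FALSE)
  }
  vals <- cbf_map[mask & is.finite(cbf_map)]
  if (length(vals) == 0) {
    stop("region '", region, "' is empty or entirely missing", call. = FALSE)
  }
  data.frame(region = region, tissue = tissue, mean_cbf = mean(vals),
             voxel_count = length(vals), stringsAsFactors = FALSE)
}

#' Paired gray-vs-white tissue contrast
#'
#' Dependent-samples t test of per-subject gray-matter CBF against
#' white-matter CBF (gray perfusion exceeds white roughly 2-3x, so this is
#' the standard sanity contrast on a quantified dataset).
#'
#' @param gray,white Numeric vectors of per-subject regional mean CBF,
#'   paired by subject.
#' @return List with `t`, `df` (n - 1), `p` (two-tailed), `mean_diff`.
#' @export
tissue_contrast <- function(gray, white) {
  if (length(gray) != length(white)) {
    stop("gray and white samples must be paired (equal length)",
         call. = FALSE)
  }
  if (length(gray) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- gray - white
  if (stats::sd(d) == 0) {
    # degenerate: all differences identical; t.test refuses constant data
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_stat, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0, mean_diff = mean(d)))
  }
  ht <- stats::t.test(gray, white, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}
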