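#' Study configuration
#'
#' Bundles the sub-configurations of a full synthetic (or ingested) study.
#' The single `seed` fans out deterministically to per-stage child seeds
#' (cohort generation, one per-subject acquisition seed, one seed per
#' bootstrap analysis) via `stage_seeds()`, so each stage is independently
#' reproducible.
#'
#' @param cohort A [cohort_config()].
#' @param acquisition An [acquisition_config()].
#' @param quant A [quant_params()]; defaults to the parameters implied by
#'   `acquisition`.
#' @param n_resamples,confidence,alpha Bootstrap and significance settings.
#' @param tails Tails for the simple partial correlations (`"one"` for the
#'   directional hypotheses; mediation tests are always two-tailed).
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         acquisition = acquisition_config(),
                         quant = NULL,
                         n_resamples = 10000, confidence = 0.95,
                         alpha = 0.05, tails = "one", seed = 1L) {
  if (is.null(quant)) quant <- quant_params_from_acquisition(acquisition)
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(acquisition, "acquisition_config"),
            inherits(quant, "quant_params"))
  structure(list(cohort = cohort, acquisition = acquisition, quant = quant,
                 n_resamples = n_resamples, confidence = confidence,
                 alpha = alpha, tails = tails, seed = as.integer(seed)),
            class = "study_config")
}

# Deterministic fan-out of one master seed into named child seeds
# (kept below 2^31 so they are valid R integer seeds).
stage_seeds <- function(seed, n_subjects) {
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  draws <- sample.int(.Machine$integer.max - 1L, 2L + n_subjects + 12L)
  list(cohort = draws[1],
       subjects = draws[2 + seq_len(n_subjects)],
       boot = draws[(2 + n_subjects) + seq_len(12)])
}

#' Run a full synthetic ASL mediation study
#'
#' End-to-end orchestration: generate a cohort with known ground truth,
#' simulate each subject's tag/control series, fit the four-regressor GLM
#' with robust inverse-variance weighting, quantify CBF, aggregate over the
#' tissue/region masks, screen outliers, compute fitness indices, and run
#' the statistical suite (tissue contrasts, gender-controlled partial
#' correlations, the three mediation analyses with reverse checks, the
#' fitness-component sensitivity analysis, and ICV-normalized volume
#' correlations). Deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built cohort (e.g., ingested real covariates);
#'   when supplied the generator is skipped.
#' @param imaging If `FALSE`, skip image simulation and use ground-truth
#'   regional CBF directly (fast covariate-only mode).
#' @return An object of class `study_report`; see the fields in the
#'   vignette. Key members: `cohort` (retained subjects with measured CBF
#'   and fitness columns), `regional_cbf` (long table), `tissue_contrasts`,
#'   `partial_correlations`, `mediation` (named list of `mediation_result`),
#'   `reverse_mediation`, `component_sensitivity`, `volume_correlations`,
#'   `exclusions`, `provenance`.
#' @export
run_study <- function(config = study_config(), cohort = NULL,
                      imaging = TRUE) {
  stopifnot(inherits(config, "study_config"))
  seeds <- stage_seeds(config$seed, config$cohort$n_subjects)

  if (is.null(cohort)) {
    cc <- config$cohort
    cc$seed <- seeds$cohort
    cohort <- generate_cohort(cc)
  }
  n <- nrow(cohort)
  acq <- config$acquisition
  masks <- build_default_masks(acq$matrix_shape, acq$n_slices)
  region_tissue <- function(r) if (grepl("white", r)) "white" else "gray"

  regional_rows <- list()
  frame_weights <- list()
  if (imaging) {
    design <- build_design_matrix(
      rep(c("tag", "control"), length.out = acq$n_tag + acq$n_control),
      task_onsets = acq$task_onsets, tr = acq$tr,
      task_duration = acq$task_duration)
    for (i in seq_len(n)) {
      acq_i <- acq
      acq_i$seed <- seeds$subjects[i]
      series <- simulate_asl_series(cohort[i, , drop = FALSE], acq_i, masks)
      fit <- tryCatch(fit_rwls(series, design),
                      error = function(e) {
                        stop("stage fit_rwls failed for subject ",
                             cohort$id[i], ": ", conditionMessage(e),
                             call. = FALSE)
                      })
      cbf_map <- quantify_cbf(fit, params = config$quant)
      frame_weights[[cohort$id[i]]] <- fit$frame_weights
      for (r in names(masks)) {
        row <- regional_mean_cbf(cbf_map, masks[[r]], region = r,
                                 tissue = region_tissue(r))
        row$id <- cohort$id[i]
        regional_rows[[length(regional_rows) + 1L]] <- row
      }
    }
    regional_cbf <- do.call(rbind, regional_rows)
    wide <- stats::reshape(
      regional_cbf[c("id", "region", "mean_cbf")],
      idvar = "id", timevar = "region", direction = "wide")
    names(wide) <- sub("^mean_cbf\\.", "cbf_meas_", names(wide))
    cohort <- merge(cohort, wide, by = "id", sort = FALSE)
  } else {
    # covariate-only mode: measured CBF = ground truth; add gray/white
    # aggregates as voxel-weighted means of the fine regions
    vx <- vapply(masks, sum, numeric(1))
    for (r in names(config$cohort$cbf_intercepts)) {
      cohort[[paste0("cbf_meas_", r)]] <- cohort[[paste0("cbf_", r)]]
    }
    for (tis in c("gray", "white")) {
      fine <- paste0(c("frontal_", "parietal_"), tis)
      wts <- vx[fine] / sum(vx[fine])
      cohort[[paste0("cbf_meas_", tis)]] <-
        as.matrix(cohort[paste0("cbf_", fine)]) %*% wts
    }
    regional_cbf <- NULL
  }

  meas_cols <- grep("^cbf_meas_", names(cohort), value = TRUE)
  screened <- exclude_outliers(cohort, meas_cols, threshold_sd = 3)
  cohort <- screened$retained
  cohort <- add_fitness_indices(cohort)

  contrasts <- list(
    global = tissue_contrast(cohort$cbf_meas_gray, cohort$cbf_meas_white),
    frontal = tissue_contrast(cohort$cbf_meas_frontal_gray,
                              cohort$cbf_meas_frontal_white),
    parietal = tissue_contrast(cohort$cbf_meas_parietal_gray,
                               cohort$cbf_meas_parietal_white))

  predictors <- c("age", "ecrf", "systolic_bp", "pulse_pressure")
  pc_rows <- list()
  for (p in predictors) {
    for (mcol in meas_cols) {
      pc <- partial_correlation(cohort[[p]], cohort[[mcol]],
                                cohort$gender_code, tails = config$tails)
      pc_rows[[length(pc_rows) + 1L]] <-
        data.frame(predictor = p, cbf = sub("^cbf_meas_", "", mcol),
                   r = pc$r, df = pc$df, p = pc$p, tails = pc$tails,
                   stringsAsFactors = FALSE)
    }
  }
  partial_correlations <- do.call(rbind, pc_rows)

  med_targets <- c(global_gray = "cbf_meas_gray",
                   parietal_gray = "cbf_meas_parietal_gray",
                   parietal_white = "cbf_meas_parietal_white")
  mediation <- list()
  reverse <- list()
  for (k in seq_along(med_targets)) {
    nm <- names(med_targets)[k]
    mediation[[nm]] <- mediate(
      "age", "ecrf", med_targets[[k]], data = cohort,
      covariates = "gender_code", n_resamples = config$n_resamples,
      confidence = config$confidence, seed = seeds$boot[2 * k - 1],
      alpha = config$alpha)
    reverse[[nm]] <- reverse_mediation_check(
      "age", "ecrf", med_targets[[k]], data = cohort,
      covariates = "gender_code", n_resamples = config$n_resamples,
      confidence = config$confidence, seed = seeds$boot[2 * k],
      alpha = config$alpha)
  }

  # the stratified analysis needs n >= 8 with both genders; small pilot
  # cohorts simply omit it
  component_sensitivity <-
    if (nrow(cohort) >= 8 && length(unique(cohort$gender_code)) == 2) {
      stratified_residual_sensitivity(
        cohort, c("ecrf", "bmi", "resting_heart_rate", "activity_score"),
        cbf_col = "cbf_meas_gray")
    } else {
      NULL
    }

  cohort$vol_superior_frontal_adj <-
    normalize_volume_icv(cohort$vol_superior_frontal, cohort$icv)
  cohort$vol_inferior_parietal_adj <-
    normalize_volume_icv(cohort$vol_inferior_parietal, cohort$icv)
  vol_rows <- list()
  for (vcol in c("vol_superior_frontal_adj", "vol_inferior_parietal_adj")) {
    for (mcol in c("cbf_meas_frontal_gray", "cbf_meas_parietal_gray")) {
      pc <- partial_correlation(cohort[[vcol]], cohort[[mcol]],
                                cohort$gender_code, tails = config$tails)
      vol_rows[[length(vol_rows) + 1L]] <-
        data.frame(volume = vcol, cbf = sub("^cbf_meas_", "", mcol),
                   r = pc$r, df = pc$df, p = pc$p, stringsAsFactors = FALSE)
    }
  }

  structure(list(cohort = cohort, regional_cbf = regional_cbf,
                 frame_weights = frame_weights,
                 tissue_contrasts = contrasts,
                 partial_correlations = partial_correlations,
                 mediation = mediation, reverse_mediation = reverse,
                 component_sensitivity = component_sensitivity,
                 volume_correlations = do.call(rbind, vol_rows),
                 exclusions = screened$exclusions,
                 provenance = list(seed = config$seed,
                                   n_subjects = config$cohort$n_subjects,
                                   imaging = imaging,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "aslmediate")),
                                   config = config)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("ASL mediation study report\n")
  cat(sprintf("  %d subjects retained (%d excluded), seed %d%s\n",
              nrow(x$cohort), length(unique(x$exclusions$id)),
              x$provenance$seed,
              if (x$provenance$imaging) "" else " (covariate-only)"))
  gc <- x$tissue_contrasts$global
  cat(sprintf("  gray vs white CBF: mean diff %.1f mL/100g/min, t(%d) = %.2f, p = %.2g\n",
              gc$mean_diff, gc$df, gc$t, gc$p))
  for (nm in names(x$mediation)) {
    m <- x$mediation[[nm]]
    cat(sprintf("  %-15s indirect = %6.3f, CI [%6.3f, %6.3f] -> %s\n",
                nm, m$indirect, m$bootstrap_ci[1], m$bootstrap_ci[2],
                m$classification))
  }
  invisible(x)
}

#' Write a study report to JSON
#'
#' Serializes the tabular and scalar content of a [run_study()] report
#' (bootstrap resample vectors and voxel maps are dropped) to a
#' machine-readable JSON file.
#'
#' @param report A `study_report`. @param path Output path.
#' @export
write_study_report <- function(report, path) {
  slim_med <- function(m) {
    list(paths = lapply(m[c("path_a", "path_b", "path_c", "path_c_prime")],
                        as.list),
         indirect = m$indirect, sobel = m$sobel,
         bootstrap_ci = m$bootstrap_ci, confidence = m$confidence,
         n_resamples = m$n_resamples, classification = m$classification,
         n = m$n, seed = m$seed)
  }
  payload <- list(
    provenance = report$provenance[c("seed", "n_subjects", "imaging",
                                     "package_version")],
    tissue_contrasts = report$tissue_contrasts,
    partial_correlations = report$partial_correlations,
    mediation = lapply(report$mediation, slim_med),
    reverse_mediation = lapply(report$reverse_mediation, slim_med),
    component_sensitivity = report$component_sensitivity,
    volume_correlations = report$volume_correlations,
    exclusions = report$exclusions,
    cohort = report$cohort)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
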