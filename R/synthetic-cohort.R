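#' Configuration for a synthetic aging cohort
#'
#' Defines the generative model for a cohort with a known
#' age -> fitness -> cerebral blood flow (CBF) mediation structure:
#' ages come from a truncated normal; estimated cardiorespiratory fitness
#' (eCRF) declines linearly with age at rate `path_a`; regional CBF responds
#' to fitness (`path_b`) and, directly, to age (`path_c_prime`). Setting
#' `path_c_prime = 0` with non-zero `path_a`, `path_b` produces a cohort in
#' which fitness fully mediates the age effect on CBF.
#'
#' Defaults emulate a cohort of 41 older adults (mean age 69.15, SD 8.31,
#' range 55-85, 22 female) with overall fitness mean 6.80 and SD 2.25
#' metabolic equivalents. The default path magnitudes are calibrated so the
#' cohort reproduces the reference correlation structure of such studies:
#' corr(age, eCRF) = -0.42 (with the truncated age SD of about 6.92 years
#' this gives |path_a| = 0.42 * 2.25 / 6.92 = 0.137 and residual fitness SD
#' 2.04), a CBF gain of 2.24 mL/100 g/min per fitness unit, and CBF residual
#' SD 4.8 so that corr(eCRF, CBF) is about 0.73 and the implied total
#' age -> CBF correlation about -0.31. Tissue CBF baselines sit near 50
#' (gray) and 20 (white) mL/100 g/min, typical of older-adult gray/white
#' perfusion.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_mean,age_sd Mean and SD of the underlying normal age
#'   distribution (years).
#' @param age_range Length-2 vector; ages outside it are rejected and
#'   redrawn.
#' @param gender_balance Proportion of subjects with `gender_code = 0`
#'   (female under the default coding), in \[0, 1\].
#' @param path_a Magnitude of the age -> eCRF slope (eCRF units per year);
#'   applied with a negative sign (fitness declines with age).
#' @param path_b eCRF -> CBF slope (mL/100 g/min per eCRF unit).
#' @param path_c_prime Direct age -> CBF slope (mL/100 g/min per year).
#' @param noise_sd_ecrf,noise_sd_cbf Residual SDs of the fitness and CBF
#'   equations.
#' @param ecrf_mean Cohort fitness intercept (value at `age_mean`).
#' @param cbf_intercepts Named numeric vector of per-region baseline CBF
#'   (mL/100 g/min) at the cohort mean age and fitness.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 41,
                          age_mean = 69.15, age_sd = 8.31,
                          age_range = c(55, 85),
                          gender_balance = 22 / 41,
                          path_a = 0.137,
                          path_b = 2.24,
                          path_c_prime = 0,
                          noise_sd_ecrf = 2.04,
                          noise_sd_cbf = 4.8,
                          ecrf_mean = 6.80,
                          cbf_intercepts = c(frontal_gray = 52,
                                             parietal_gray = 48,
                                             frontal_white = 22,
                                             parietal_white = 18),
                          seed = 1L) {
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1)
  if (n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  if (age_sd < 0 || noise_sd_ecrf < 0 || noise_sd_cbf < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("age_range must be an increasing pair", call. = FALSE)
  }
  if (gender_balance < 0 || gender_balance > 1) {
    stop("gender_balance must be in [0, 1]", call. = FALSE)
  }
  if (is.null(names(cbf_intercepts)) || any(!nzchar(names(cbf_intercepts)))) {
    stop("cbf_intercepts must be a named vector", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 gender_balance = gender_balance,
                 path_a = path_a, path_b = path_b,
                 path_c_prime = path_c_prime,
                 noise_sd_ecrf = noise_sd_ecrf, noise_sd_cbf = noise_sd_cbf,
                 ecrf_mean = ecrf_mean, cbf_intercepts = cbf_intercepts,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated-normal sampling by reject-and-redraw; exact for the stated range
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with known mediation structure
#'
#' Draws subject ages from the truncated normal in `config`, assigns gender,
#' and builds ground-truth fitness and regional CBF via the linear path
#' model:
#' \deqn{eCRF_i = \mu_{eCRF} - |a| (age_i - \mu_{age}) + \epsilon_i}
#' \deqn{CBF_{ir} = \beta_{0r} + b\,(eCRF_i - \mu_{eCRF}) +
#'       c' (age_i - \mu_{age}) + \eta_{ir}}
#' BMI, resting heart rate and blood pressures are drawn from plausible
#' marginals, and the self-report activity score is then back-solved from the
#' fitness estimating equation so that [compute_ecrf()] applied to the
#' covariates reproduces `ecrf_true` exactly. Back-solved activity scores are
#' continuous, unlike the ordinal source scale.
#'
#' Regional brain volumes (superior frontal, inferior parietal, mm^3) are
#' generated proportional to intracranial volume (ICV) plus noise so that
#' ICV-normalization routines have realistic input.
#'
#' @param config A [cohort_config()].
#' @return A data frame (one row per subject) with covariates, ground-truth
#'   paths as attributes, and one `cbf_<region>` column per configured
#'   region. Deterministic given `config$seed`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config object", call. = FALSE)
  }
  n <- config$n_subjects
  withr_seed <- set_local_seed(config$seed)
  on.exit(withr_seed(), add = TRUE)

  age <- rtruncnorm_reject(n, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2])
  # deterministic gender split closest to the requested balance, then shuffled
  n_female <- round(config$gender_balance * n)
  gender_code <- sample(rep(c(0L, 1L), c(n_female, n - n_female)))

  slope_a <- -abs(config$path_a)
  ecrf_true <- config$ecrf_mean + slope_a * (age - config$age_mean) +
    stats::rnorm(n, 0, config$noise_sd_ecrf)

  regions <- names(config$cbf_intercepts)
  cbf <- sapply(regions, function(r) {
    config$cbf_intercepts[[r]] +
      config$path_b * (ecrf_true - config$ecrf_mean) +
      config$path_c_prime * (age - config$age_mean) +
      stats::rnorm(n, 0, config$noise_sd_cbf)
  })
  cbf <- matrix(cbf, nrow = n, dimnames = list(NULL, paste0("cbf_", regions)))

  bmi <- rtruncnorm_reject(n, 27, 4, 16, 45)
  resting_heart_rate <- rtruncnorm_reject(n, 65, 8, 40, 110)
  diastolic_bp <- rtruncnorm_reject(n, 79.40, 7.62, 55, 110)
  pulse <- rtruncnorm_reject(n, 56.01, 13.58, 20, 100)
  systolic_bp <- diastolic_bp + pulse

  # invert the fitness equation for the activity score so covariates are
  # exactly consistent with ecrf_true
  activity_score <- ecrf_true - gender_code * 2.77 + age * 0.10 +
    bmi * 0.17 + resting_heart_rate * 0.03 - 18.07

  icv <- stats::rnorm(n, 1.5e6, 1.4e5)
  vol_superior_frontal <- 0.015 * icv + stats::rnorm(n, 0, 1200)
  vol_inferior_parietal <- 0.010 * icv + stats::rnorm(n, 0, 900)

  cohort <- data.frame(id = sprintf("S%03d", seq_len(n)),
                       age = age, gender_code = gender_code, bmi = bmi,
                       resting_heart_rate = resting_heart_rate,
                       activity_score = activity_score,
                       systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
                       ecrf_true = ecrf_true,
                       icv = icv,
                       vol_superior_frontal = vol_superior_frontal,
                       vol_inferior_parietal = vol_inferior_parietal,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(cbf))
  attr(cohort, "true_paths") <- c(a = slope_a, b = config$path_b,
                                  c_prime = config$path_c_prime)
  attr(cohort, "config") <- config
  cohort
}

# Restore the caller's RNG state after using a local seed, so library code
# does not clobber the session RNG.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Regional ground-truth CBF of one subject
#'
#' @param subject One row of a cohort data frame.
#' @return Named numeric vector region -> mL/100 g/min.
#' @keywords internal
subject_regional_cbf <- function(subject) {
  cols <- grep("^cbf_", names(subject), value = TRUE)
  stats::setNames(as.numeric(subject[cols]), sub("^cbf_", "", cols))
}
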