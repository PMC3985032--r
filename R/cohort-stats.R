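#' Normalize regional volumes by intracranial volume (covariance approach)
#'
#' Removes head-size differences from regional brain volumes by subtracting
#' the ICV regression slope:
#' \deqn{vol^{adj}_i = vol_i - \beta\,(ICV_i - \overline{ICV})}
#' with \eqn{\beta} from OLS of volume on ICV. Adjusted volumes are
#' uncorrelated with ICV by construction.
#'
#' @param volumes Numeric vector of regional volumes (mm^3).
#' @param icv Numeric vector of intracranial volumes (mm^3), same length.
#' @return Adjusted volumes. If ICV has zero variance the input is returned
#'   unchanged with a warning.
#' @export
normalize_volume_icv <- function(volumes, icv) {
  if (length(volumes) != length(icv)) {
    stop("volumes and icv must have equal length", call. = FALSE)
  }
  if (length(volumes) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(icv) == 0) {
    warning("icv has zero variance; volumes returned unchanged",
            call. = FALSE)
    return(volumes)
  }
  slope <- stats::cov(volumes, icv) / stats::var(icv)
  volumes - slope * (icv - mean(icv))
}

#' Screen subjects with extreme MRI measures
#'
#' Single-pass outlier rule: a subject is removed when any designated
#' measure lies more than `threshold_sd` column standard deviations from the
#' column mean, with means/SDs computed once on the full sample. Zero-SD
#' columns cannot flag anyone and are skipped with a warning.
#'
#' @param table Data frame of subject rows.
#' @param measures Character vector of numeric column names to screen.
#' @param threshold_sd Exclusion threshold in SD units (default 3).
#' @return List with `retained` (the filtered table) and `exclusions`
#'   (data frame: subject row id, offending measure, value, z score).
#' @export
exclude_outliers <- function(table, measures, threshold_sd = 3) {
  if (threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  missing <- setdiff(measures, names(table))
  if (length(missing)) {
    stop("measure(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- if ("id" %in% names(table)) table$id else seq_len(nrow(table))
  drop <- logical(nrow(table))
  log_rows <- list()
  for (mcol in measures) {
    v <- table[[mcol]]
    mu <- mean(v); s <- stats::sd(v)
    if (s == 0) {
      warning("measure '", mcol, "' has zero SD; skipped", call. = FALSE)
      next
    }
    z <- (v - mu) / s
    hit <- is.finite(z) & abs(z) > threshold_sd
    if (any(hit)) {
      log_rows[[mcol]] <- data.frame(id = ids[hit], measure = mcol,
                                     value = v[hit], z = z[hit],
                                     stringsAsFactors = FALSE)
      drop <- drop | hit
    }
  }
  exclusions <- if (length(log_rows)) {
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(0), measure = character(0),
               value = numeric(0), z = numeric(0), stringsAsFactors = FALSE)
  }
  list(retained = table[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Stratified residual sensitivity analysis
#'
#' Checks that a measure's association with CBF survives equating gender and
#' age group: the sample is split by gender, then by a median age split
#' within each gender, giving four strata. Within each stratum the stratum
#' mean is subtracted from every measure and from CBF; the pooled residuals
#' are then correlated, measure by measure, with the CBF residuals.
#'
#' @param cohort Data frame with `age`, `gender_code`, a CBF column, and the
#'   measures.
#' @param measures Character vector of measure column names.
#' @param cbf_col Name of the CBF column (default
#'   `"cbf_gray"`).
#' @return Data frame with one row per measure: `measure`, `r`, `df`, `t`,
#'   `p` (two-tailed).
#' @export
stratified_residual_sensitivity <- function(cohort, measures,
                                            cbf_col = "cbf_gray") {
  needed <- c("age", "gender_code", cbf_col, measures)
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  if (n < 8 || length(unique(cohort$gender_code)) < 2) {
    stop("need n >= 8 with both genders present", call. = FALSE)
  }
  stratum <- character(n)
  for (g in unique(cohort$gender_code)) {
    in_g <- cohort$gender_code == g
    med <- stats::median(cohort$age[in_g])
    stratum[in_g] <- paste0("g", g, ifelse(cohort$age[in_g] <= med,
                                           "_young", "_old"))
  }
  sizes <- table(stratum)
  if (any(sizes < 2)) {
    stop("stratification failed: stratum with < 2 subjects", call. = FALSE)
  }
  center_within <- function(v) v - stats::ave(v, stratum)
  cbf_res <- center_within(cohort[[cbf_col]])
  if (stats::sd(cbf_res) == 0) {
    stop("zero-variance CBF residuals: correlation undefined", call. = FALSE)
  }
  out <- lapply(measures, function(mcol) {
    m_res <- center_within(cohort[[mcol]])
    if (stats::sd(m_res) == 0) {
      stop("zero-variance residuals for measure '", mcol, "'", call. = FALSE)
    }
    r <- stats::cor(m_res, cbf_res)
    df <- n - 2
    t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(measure = mcol, r = r, df = df, t = t_stat,
               p = 2 * stats::pt(-abs(t_stat), df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
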