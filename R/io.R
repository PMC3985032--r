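#' Write an ASL series to disk
#'
#' Serializes a simulated (or ingested) series as standard neuroimaging
#' files: the 4-D data and each mask as NIfTI-1 volumes, the frame labels as
#' a one-label-per-line text sidecar, and the acquisition parameters
#' (including the RNG seed) as YAML.
#'
#' @param series An `asl_series`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Files: `asl.nii.gz`, `frame_labels.txt`,
#'   `acquisition.yaml`, `mask_<name>.nii.gz`.
#' @export
write_asl_series <- function(series, dir) {
  if (!inherits(series, "asl_series")) {
    stop("series must be an asl_series", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- series$acquisition
  RNifti::writeNifti(series$data, file.path(dir, "asl.nii.gz"))
  writeLines(series$frame_labels, file.path(dir, "frame_labels.txt"))
  for (nm in names(series$masks)) {
    RNifti::writeNifti(series$masks[[nm]] * 1L,
                       file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  yaml::write_yaml(unclass(acq), file.path(dir, "acquisition.yaml"))
  invisible(dir)
}

#' Read an ASL series written by [write_asl_series()]
#'
#' @param dir Directory containing `asl.nii.gz`, `frame_labels.txt`,
#'   `mask_*.nii.gz`, and optionally `acquisition.yaml`.
#' @return An `asl_series` (without ground-truth maps).
#' @export
read_asl_series <- function(dir) {
  data_path <- file.path(dir, "asl.nii.gz")
  label_path <- file.path(dir, "frame_labels.txt")
  for (p in c(data_path, label_path)) {
    if (!file.exists(p)) stop("missing required file: ", p, call. = FALSE)
  }
  img <- RNifti::readNifti(data_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4) {
    stop(data_path, " is not a 4-D series", call. = FALSE)
  }
  labels <- readLines(label_path)
  if (length(labels) != dim(data)[4]) {
    stop("frame label file has ", length(labels), " lines but series has ",
         dim(data)[4], " frames", call. = FALSE)
  }
  if (!all(labels %in% c("tag", "control"))) {
    stop("frame labels must be 'tag' or 'control'", call. = FALSE)
  }
  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii(\\.gz)?$",
                           full.names = TRUE)
  masks <- list()
  for (f in mask_files) {
    nm <- sub("^mask_", "", sub("\\.nii(\\.gz)?$", "", basename(f)))
    m <- RNifti::readNifti(f)
    m_arr <- array(as.numeric(m) != 0, dim = dim(m))
    if (!identical(dim(m_arr), dim(data)[1:3])) {
      stop("mask '", nm, "' shape does not match the series", call. = FALSE)
    }
    masks[[nm]] <- m_arr
  }
  if (length(masks) == 0) stop("no mask_*.nii[.gz] files in ", dir,
                               call. = FALSE)
  acq_path <- file.path(dir, "acquisition.yaml")
  acq <- if (file.exists(acq_path)) {
    vals <- yaml::read_yaml(acq_path)
    do.call(acquisition_config, vals[setdiff(names(vals), character(0))])
  } else {
    NULL
  }
  structure(list(data = data, frame_labels = labels, acquisition = acq,
                 masks = masks, cbf_true = NULL),
            class = "asl_series")
}

cohort_required_columns <- function() {
  c("id", "age", "gender_code", "bmi", "resting_heart_rate",
    "activity_score", "systolic_bp", "diastolic_bp")
}

#' Write / read a cohort covariate table
#'
#' Plain CSV with one subject per row. Required columns: id, age,
#' gender_code, bmi, resting_heart_rate, activity_score, systolic_bp,
#' diastolic_bp; any further columns (ground-truth CBF, volumes, ICV) are
#' carried through.
#'
#' @param cohort Cohort data frame. @param path CSV path.
#' @return `read_cohort_csv` returns the validated data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_columns(), names(cohort))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write perfusion-fit outputs
#'
#' Coefficient maps as NIfTI volumes and the per-frame weights as CSV.
#'
#' @param fit A `perfusion_fit`. @param dir Output directory.
#' @export
write_perfusion_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("delta_m_map", "m0_map", "bold_map", "activation_map")) {
    m <- fit[[nm]]
    m[!is.finite(m)] <- 0
    RNifti::writeNifti(m, file.path(dir, paste0(nm, ".nii.gz")))
  }
  utils::write.csv(data.frame(frame = seq_along(fit$frame_weights),
                              weight = fit$frame_weights,
                              residual_variance =
                                fit$residual_variance_per_frame),
                   file.path(dir, "frame_weights.csv"), row.names = FALSE)
  invisible(dir)
}

#' Ingest an on-disk study (cohort CSV plus per-subject series directories)
#'
#' Validates and loads study inputs written in the package's on-disk layout
#' (or produced by any converter respecting it). All shape/label/column
#' problems are reported per offending file.
#'
#' @param cohort_csv Path to the cohort covariate CSV.
#' @param series_dirs Named character vector of per-subject series
#'   directories (names = subject ids); may be empty for covariate-only
#'   analyses.
#' @return List with `cohort` and `series` (named list of `asl_series`).
#' @export
ingest_real <- function(cohort_csv, series_dirs = character(0)) {
  cohort <- read_cohort_csv(cohort_csv)
  series <- list()
  errors <- character(0)
  for (i in seq_along(series_dirs)) {
    id <- if (!is.null(names(series_dirs))) names(series_dirs)[i] else
      basename(series_dirs[i])
    res <- tryCatch(read_asl_series(series_dirs[i]), error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(id, ": ", conditionMessage(res)))
    } else {
      series[[id]] <- res
    }
  }
  if (length(errors)) {
    stop("ingestion failed for ", length(errors), " series:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  list(cohort = cohort, series = series)
}
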