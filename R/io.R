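#' Read a time-intensity curve from CSV
#'
#' Dialect: header \code{time_s,mean_hu} with an optional \code{roi}
#' column; one row per acquisition.
#'
#' @param path CSV path.
#' @return A [TimeIntensityCurve-class].
#' @export
readTICCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "mean_hu")
  if (!all(need %in% names(df)))
    stop(sprintf("TIC CSV must have columns %s", paste(need, collapse = ", ")))
  roi <- if ("roi" %in% names(df) && nrow(df) > 0) as.character(df$roi[1])
         else "roi"
  TimeIntensityCurve(df$time_s, df$mean_hu, roiName = roi)
}

#' Write a time-intensity curve to CSV
#'
#' @param curve A [TimeIntensityCurve-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeTICCSV <- function(curve, path) {
  stopifnot(is(curve, "TimeIntensityCurve"))
  df <- data.frame(time_s = curve@times, mean_hu = curve@values,
                   roi = curve@roiName)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Dialect: \code{patient_id,tumor_slope_hu_s,tumor_peak_hu,delta_peak_hu,
#' visual_phenotype}.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tumor_slope_hu_s", "tumor_peak_hu",
            "delta_peak_hu", "visual_phenotype")
  if (!all(need %in% names(df)))
    stop(sprintf("feature CSV must have columns %s",
                 paste(need, collapse = ", ")))
  df
}

#' Write the per-patient feature table
#'
#' @param features Data frame with columns patient_id, tumor_slope_hu_s,
#'   tumor_peak_hu, delta_peak_hu, visual_phenotype.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Dialect: \code{patient_id,survival_days,event,phenotype_visual}
#' with optional \code{phenotype_predicted}.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
readCohortCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "survival_days", "event", "phenotype_visual")
  if (!all(need %in% names(df)))
    stop(sprintf("cohort CSV must have columns %s",
                 paste(need, collapse = ", ")))
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort Data frame with at least patient_id, survival_days,
#'   event, phenotype_visual.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dynamic series or label map to NIfTI
#'
#' @param x A [DynamicSeries-class] or a 3D array (label map).
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeNiftiVolume <- function(x, path) {
  if (is(x, "DynamicSeries")) {
    img <- RNifti::asNifti(x@volumes)
    RNifti::pixdim(img) <- c(x@voxelSpacing, 1)
  } else {
    img <- RNifti::asNifti(x)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
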