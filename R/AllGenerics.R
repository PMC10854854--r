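#' Accessors for package classes
#'
#' Small generic accessors so user code never reaches into slots.
#'
#' @param object An object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ticTimes", function(object) standardGeneric("ticTimes"))
#' @rdname accessors
#' @export
setGeneric("ticValues", function(object) standardGeneric("ticValues"))
#' @rdname accessors
#' @export
setGeneric("roiName", function(object) standardGeneric("roiName"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))

#' @rdname accessors
#' @export
setGeneric("smoothedValues", function(object) standardGeneric("smoothedValues"))
#' @rdname accessors
#' @export
setGeneric("derivativeValues",
           function(object) standardGeneric("derivativeValues"))
#' @rdname accessors
#' @export
setGeneric("argmaxDerivative",
           function(object) standardGeneric("argmaxDerivative"))

#' @rdname accessors
#' @export
setGeneric("baselineLevel", function(object) standardGeneric("baselineLevel"))
#' @rdname accessors
#' @export
setGeneric("upslopeSlope", function(object) standardGeneric("upslopeSlope"))
#' @rdname accessors
#' @export
setGeneric("washoutSlope", function(object) standardGeneric("washoutSlope"))
#' @rdname accessors
#' @export
setGeneric("onsetTime", function(object) standardGeneric("onsetTime"))
#' @rdname accessors
#' @export
setGeneric("peakTime", function(object) standardGeneric("peakTime"))
#' @rdname accessors
#' @export
setGeneric("peakEnhancement",
           function(object) standardGeneric("peakEnhancement"))
#' @rdname accessors
#' @export
setGeneric("fitRSS", function(object) standardGeneric("fitRSS"))
#' @rdname accessors
#' @export
setGeneric("windowIndices", function(object) standardGeneric("windowIndices"))

#' @rdname accessors
#' @export
setGeneric("tumorSlope", function(object) standardGeneric("tumorSlope"))
#' @rdname accessors
#' @export
setGeneric("tumorPeak", function(object) standardGeneric("tumorPeak"))
#' @rdname accessors
#' @export
setGeneric("deltaPeak", function(object) standardGeneric("deltaPeak"))

#' @rdname accessors
#' @export
setGeneric("foldAUC", function(object) standardGeneric("foldAUC"))
#' @rdname accessors
#' @export
setGeneric("meanAUC", function(object) standardGeneric("meanAUC"))
#' @rdname accessors
#' @export
setGeneric("pooledAUC", function(object) standardGeneric("pooledAUC"))

#' @rdname accessors
#' @export
setGeneric("acquisitionTimes",
           function(object) standardGeneric("acquisitionTimes"))
#' @rdname accessors
#' @export
setGeneric("protocolTimes", function(object) standardGeneric("protocolTimes"))

#' @rdname accessors
#' @export
setMethod("ticTimes", "TimeIntensityCurve", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("ticValues", "TimeIntensityCurve", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("roiName", "TimeIntensityCurve", function(object) object@roiName)
#' @rdname accessors
#' @export
setMethod("voxelCount", "TimeIntensityCurve",
          function(object) object@voxelCount)
#' @rdname accessors
#' @export
setMethod("length", "TimeIntensityCurve", function(x) length(x@times))

#' @rdname accessors
#' @export
setMethod("ticTimes", "SplineSummary", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("smoothedValues", "SplineSummary",
          function(object) object@smoothedValues)
#' @rdname accessors
#' @export
setMethod("derivativeValues", "SplineSummary",
          function(object) object@derivative)
#' @rdname accessors
#' @export
setMethod("argmaxDerivative", "SplineSummary",
          function(object) object@argmaxIndex)

#' @rdname accessors
#' @export
setMethod("baselineLevel", "TrilinearFit",
          function(object) object@baselineLevel)
#' @rdname accessors
#' @export
setMethod("upslopeSlope", "TrilinearFit", function(object) object@upslopeSlope)
#' @rdname accessors
#' @export
setMethod("washoutSlope", "TrilinearFit", function(object) object@washoutSlope)
#' @rdname accessors
#' @export
setMethod("onsetTime", "TrilinearFit", function(object) object@onsetTime)
#' @rdname accessors
#' @export
setMethod("peakTime", "TrilinearFit", function(object) object@peakTime)
#' @rdname accessors
#' @export
setMethod("peakEnhancement", "TrilinearFit",
          function(object) object@peakEnhancement)
#' @rdname accessors
#' @export
setMethod("fitRSS", "TrilinearFit", function(object) object@rss)
#' @rdname accessors
#' @export
setMethod("windowIndices", "TrilinearFit",
          function(object) object@windowIndices)

#' @rdname accessors
#' @export
setMethod("tumorSlope", "PerfusionFeatures",
          function(object) object@tumorSlope)
#' @rdname accessors
#' @export
setMethod("tumorPeak", "PerfusionFeatures", function(object) object@tumorPeak)
#' @rdname accessors
#' @export
setMethod("deltaPeak", "PerfusionFeatures", function(object) object@deltaPeak)

#' @rdname accessors
#' @export
setMethod("foldAUC", "PhenotypeModel", function(object) object@foldAUC)
#' @rdname accessors
#' @export
setMethod("meanAUC", "PhenotypeModel", function(object) object@meanAUC)
#' @rdname accessors
#' @export
setMethod("pooledAUC", "PhenotypeModel", function(object) object@pooledAUC)
#' @rdname accessors
#' @export
setMethod("coef", "PhenotypeModel", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "DynamicSeries",
          function(object) object@acquisitionTimes)
#' @rdname accessors
#' @export
setMethod("protocolTimes", "AcquisitionProtocol",
          function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("labelCodes", function(object) standardGeneric("labelCodes"))
#' @rdname accessors
#' @export
setMethod("labelCodes", "LabelSchema", function(object) object@codes)

setMethod("show", "TimeIntensityCurve", function(object) {
  cat(sprintf(
    "TimeIntensityCurve '%s': %d samples, t = %.4g..%.4g s, %.4g..%.4g HU\n",
    object@roiName, length(object@times),
    min(object@times), max(object@times),
    min(object@values), max(object@values)))
  if (!is.na(object@voxelCount))
    cat(sprintf("  averaged over %d voxels\n", object@voxelCount))
  invisible(object)
})

setMethod("show", "SplineSummary", function(object) {
  cat(sprintf(
    "SplineSummary: %d samples, max derivative %.4g HU/s at index %d (t = %.4g s)\n",
    length(object@times), object@derivative[object@argmaxIndex],
    object@argmaxIndex, object@times[object@argmaxIndex]))
  invisible(object)
})

setMethod("show", "TrilinearFit", function(object) {
  cat("TrilinearFit (non-enhancement / upslope / washout)\n")
  cat(sprintf("  baseline level : %8.3f HU\n", object@baselineLevel))
  cat(sprintf("  slope          : %8.3f HU/s\n", object@upslopeSlope))
  cat(sprintf("  onset          : %8.3f s\n", object@onsetTime))
  cat(sprintf("  peak time      : %8.3f s\n", object@peakTime))
  cat(sprintf("  peak enh.      : %8.3f HU (above baseline)\n",
              object@peakEnhancement))
  cat(sprintf("  washout slope  : %8.3f HU/s\n", object@washoutSlope))
  cat(sprintf("  rss            : %8.3f\n", object@rss))
  cat(sprintf("  upslope window : indices %d..%d\n",
              min(object@windowIndices), max(object@windowIndices)))
  invisible(object)
})

setMethod("show", "PerfusionFeatures", function(object) {
  cat(sprintf(
    "PerfusionFeatures: slope %.3f HU/s, peak %.2f HU, delta %.2f HU\n",
    object@tumorSlope, object@tumorPeak, object@deltaPeak))
  invisible(object)
})

setMethod("show", "PhenotypeModel", function(object) {
  k <- length(object@foldAUC)
  cat(sprintf("PhenotypeModel: %d-fold cross-validated logistic regression\n",
              k))
  cat(sprintf("  per-fold AUC : %s\n",
              paste(sprintf("%.3f", object@foldAUC), collapse = " ")))
  cat(sprintf("  mean AUC     : %.3f\n", object@meanAUC))
  cat(sprintf("  pooled AUC   : %.3f\n", object@pooledAUC))
  invisible(object)
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@volumes)
  cat(sprintf("DynamicSeries: %d x %d x %d voxels, %d timepoints (%.4g..%.4g s)\n",
              d[1], d[2], d[3], d[4],
              min(object@acquisitionTimes), max(object@acquisitionTimes)))
  invisible(object)
})

setMethod("show", "LabelSchema", function(object) {
  cat("LabelSchema:\n")
  for (nm in names(object@codes))
    cat(sprintf("  %2d  %s\n", object@codes[[nm]], nm))
  invisible(object)
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol: %d timepoints, %.4g..%.4g s\n",
              length(object@times), min(object@times), max(object@times)))
  invisible(object)
})
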