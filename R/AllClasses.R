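#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Time-intensity curve of one region of interest
#'
#' The central measurement object of the package: paired acquisition times
#' (seconds) and mean attenuation values (Hounsfield units) for a single
#' region of interest of a dynamic CT perfusion series.
#'
#' @slot times Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @slot values Numeric vector of mean ROI attenuation in HU, same length as
#'   \code{times}, all finite.
#' @slot roiName Single character string naming the region
#'   (\code{"tumor"}, \code{"pancreas"}, or free text).
#' @slot voxelCount Number of voxels averaged at each timepoint
#'   (\code{NA} when the curve was not derived from a volume).
#'
#' @seealso [TimeIntensityCurve()], [fitCurve()], [extractTIC()]
#' @export
setClass("TimeIntensityCurve",
  slots = c(
    times = "numeric",
    values = "numeric",
    roiName = "character",
    voxelCount = "integer"
  ),
  prototype = prototype(roiName = "roi", voxelCount = NA_integer_)
)

setValidity("TimeIntensityCurve", function(object) {
  msg <- character(0)
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 3L)
    msg <- c(msg, "a time-intensity curve needs at least 3 samples")
  if (anyNA(object@times) || any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite (drop gaps before construction)")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@roiName) != 1L)
    msg <- c(msg, "roiName must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeIntensityCurve
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param values Mean attenuation in HU, same length as \code{times}.
#' @param roiName Name of the region of interest.
#' @param voxelCount Optional number of voxels averaged per timepoint.
#' @return A [TimeIntensityCurve-class] object.
#' @examples
#' tic <- TimeIntensityCurve(seq(0, 24, 2), 40 + seq(0, 24, 2), "tumor")
#' tic
#' @export
TimeIntensityCurve <- function(times, values, roiName = "roi",
                               voxelCount = NA_integer_) {
  new("TimeIntensityCurve",
    times = as.numeric(times), values = as.numeric(values),
    roiName = as.character(roiName),
    voxelCount = as.integer(voxelCount)
  )
}

#' Smoothing-spline summary of a time-intensity curve
#'
#' Result of the first fitting step: a cubic smoothing spline through the
#' curve, its analytic first derivative evaluated at the sample times, and
#' the index of the maximum derivative (first index on ties), which
#' localizes the contrast upslope.
#'
#' @slot times Sample times (copied from the input curve), seconds.
#' @slot smoothedValues Spline values at the sample times, HU.
#' @slot derivative Spline first derivative at the sample times, HU/s.
#' @slot argmaxIndex Integer index of the maximum derivative (1-based,
#'   first index on ties).
#' @slot smoothing The residual-sum-of-squares smoothing target actually
#'   used.
#' @seealso [fitSpline()]
#' @export
setClass("SplineSummary",
  slots = c(
    times = "numeric",
    smoothedValues = "numeric",
    derivative = "numeric",
    argmaxIndex = "integer",
    smoothing = "numeric"
  )
)

setValidity("SplineSummary", function(object) {
  msg <- character(0)
  n <- length(object@times)
  if (length(object@smoothedValues) != n || length(object@derivative) != n)
    msg <- c(msg, "smoothedValues and derivative must match times in length")
  if (length(object@argmaxIndex) != 1L || is.na(object@argmaxIndex) ||
      object@argmaxIndex < 1L || object@argmaxIndex > n)
    msg <- c(msg, "argmaxIndex out of range")
  else if (object@argmaxIndex != which.max(object@derivative))
    msg <- c(msg, "argmaxIndex must be the first maximum of the derivative")
  if (length(msg)) msg else TRUE
})

#' Fitted trilinear curve model
#'
#' The three-phase (non-enhancement, upslope, washout) piecewise-linear model
#' of a time-intensity curve. The non-enhancement phase is a constant
#' (static) line, the upslope and washout phases are least-squares lines.
#' The intersection of the static line with the upslope line is the start of
#' enhancement (onset); the intersection of the upslope with the washout
#' line is the peak. Peak enhancement is reported relative to the baseline
#' level, i.e. as HU above the static line.
#'
#' @slot baselineLevel Static line level of the non-enhancement phase, HU.
#' @slot upslopeSlope Enhancement slope, HU/s (the headline biomarker).
#' @slot upslopeIntercept Intercept of the upslope line, HU.
#' @slot washoutSlope Slope of the washout line, HU/s.
#' @slot washoutIntercept Intercept of the washout line, HU.
#' @slot onsetTime Start of enhancement, seconds.
#' @slot peakTime Time of peak enhancement, seconds.
#' @slot peakEnhancement Model value at \code{peakTime} minus
#'   \code{baselineLevel}, HU.
#' @slot rss Total squared residual over the three phases.
#' @slot windowIndices Contiguous sample indices assigned to the upslope
#'   phase.
#' @seealso [fitTrilinear()], [fitCurve()]
#' @export
setClass("TrilinearFit",
  slots = c(
    baselineLevel = "numeric",
    upslopeSlope = "numeric",
    upslopeIntercept = "numeric",
    washoutSlope = "numeric",
    washoutIntercept = "numeric",
    onsetTime = "numeric",
    peakTime = "numeric",
    peakEnhancement = "numeric",
    rss = "numeric",
    windowIndices = "integer"
  )
)

setValidity("TrilinearFit", function(object) {
  msg <- character(0)
  if (!(object@onsetTime < object@peakTime))
    msg <- c(msg, "onsetTime must precede peakTime")
  expected <- object@upslopeSlope * (object@peakTime - object@onsetTime)
  tol <- 1e-9 * max(1, abs(expected))
  if (abs(object@peakEnhancement - expected) > tol)
    msg <- c(msg,
      "peakEnhancement must equal upslopeSlope * (peakTime - onsetTime)")
  w <- object@windowIndices
  if (length(w) < 2L || any(diff(w) != 1L))
    msg <- c(msg, "windowIndices must be contiguous with length >= 2")
  if (length(msg)) msg else TRUE
})

#' Dynamic CT perfusion series
#'
#' A 4D attenuation grid (x, y, z, time) in Hounsfield units together with
#' the acquisition time of each 3D volume and the voxel spacing.
#'
#' @slot volumes 4D numeric array, dimensions X x Y x Z x T, HU.
#' @slot acquisitionTimes Seconds, length T, strictly increasing.
#' @slot voxelSpacing Millimetre triple.
#' @seealso [readDynamicSeries()], [extractTIC()], [generatePhantom()]
#' @export
setClass("DynamicSeries",
  slots = c(
    volumes = "array",
    acquisitionTimes = "numeric",
    voxelSpacing = "numeric"
  )
)

setValidity("DynamicSeries", function(object) {
  msg <- character(0)
  d <- dim(object@volumes)
  if (length(d) != 4L)
    msg <- c(msg, "volumes must be a 4D array (x, y, z, t)")
  else {
    if (d[4] < 8L)
      msg <- c(msg, "a dynamic series needs at least 8 timepoints")
    if (length(object@acquisitionTimes) != d[4])
      msg <- c(msg, "acquisitionTimes must match the 4th array dimension")
  }
  if (any(diff(object@acquisitionTimes) <= 0))
    msg <- c(msg, "acquisitionTimes must be strictly increasing")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be a positive mm triple")
  if (length(msg)) msg else TRUE
})

#' Construct a DynamicSeries
#'
#' @param volumes 4D array (x, y, z, t) of attenuation in HU.
#' @param acquisitionTimes Acquisition time of each volume, seconds.
#' @param voxelSpacing Voxel spacing in mm, length 3.
#' @return A [DynamicSeries-class] object.
#' @export
DynamicSeries <- function(volumes, acquisitionTimes,
                          voxelSpacing = c(1, 1, 1)) {
  new("DynamicSeries",
    volumes = volumes,
    acquisitionTimes = as.numeric(acquisitionTimes),
    voxelSpacing = as.numeric(voxelSpacing)
  )
}

#' Anatomical label schema for segmentation maps
#'
#' Maps integer voxel labels to anatomical structure names. The tumor and
#' pancreas parenchyma labels are mandatory; vessels and stent labels drive
#' the default exclusion set used when averaging the tumor ROI.
#'
#' @slot codes Named integer vector: structure name -> voxel label.
#' @slot vesselNames Names of vascular structures (candidates for
#'   exclusion from the tumor ROI).
#' @slot stentNames Names of stent / endoprosthesis structures.
#' @seealso [defaultLabelSchema()], [extractTIC()]
#' @export
setClass("LabelSchema",
  slots = c(
    codes = "integer",
    vesselNames = "character",
    stentNames = "character"
  )
)

setValidity("LabelSchema", function(object) {
  msg <- character(0)
  if (is.null(names(object@codes)) || any(names(object@codes) == ""))
    msg <- c(msg, "codes must be a fully named integer vector")
  if (anyDuplicated(object@codes))
    msg <- c(msg, "label codes must be unique")
  if (anyDuplicated(names(object@codes)))
    msg <- c(msg, "label names must be unique")
  for (req in c("tumor", "pancreas"))
    if (!req %in% names(object@codes))
      msg <- c(msg, sprintf("mandatory label '%s' missing from schema", req))
  extra <- setdiff(c(object@vesselNames, object@stentNames),
                   names(object@codes))
  if (length(extra))
    msg <- c(msg, paste("unknown structure names:",
                        paste(extra, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-patient perfusion features
#'
#' The three biomarker features used for vascular phenotyping: tumor
#' enhancement slope (HU/s), tumor peak enhancement (HU), and the
#' pancreas-minus-tumor peak-enhancement difference (delta, HU). The sign
#' convention makes delta positive when the pancreas enhances more than the
#' tumor, so hypovascular tumors have large positive values.
#'
#' @slot tumorSlope Tumor enhancement slope, HU/s.
#' @slot tumorPeak Tumor peak enhancement, HU.
#' @slot deltaPeak Pancreas peak enhancement minus tumor peak enhancement,
#'   HU.
#' @seealso [computeFeatures()]
#' @export
setClass("PerfusionFeatures",
  slots = c(
    tumorSlope = "numeric",
    tumorPeak = "numeric",
    deltaPeak = "numeric"
  )
)

setValidity("PerfusionFeatures", function(object) {
  vals <- c(object@tumorSlope, object@tumorPeak, object@deltaPeak)
  if (length(vals) != 3L || any(!is.finite(vals)))
    "tumorSlope, tumorPeak and deltaPeak must be finite scalars"
  else TRUE
})

#' Cross-validated logistic phenotype classifier
#'
#' A ridge-penalized logistic regression over the three perfusion features,
#' evaluated with stratified k-fold cross-validation. Scores are
#' out-of-fold predicted probabilities of the isovascular class; per-fold
#' ROC curves and AUCs, their mean, and the pooled (all out-of-fold scores)
#' AUC are stored.
#'
#' @slot coefficients Full-data model coefficients on the standardized
#'   feature scale (intercept first).
#' @slot center,scale Feature standardization of the full-data model.
#' @slot folds Integer fold assignment per sample.
#' @slot foldAUC AUC per fold.
#' @slot meanAUC Mean of the per-fold AUCs.
#' @slot pooledAUC AUC of all pooled out-of-fold scores.
#' @slot roc List of per-fold ROC data frames (fpr, tpr, threshold).
#' @slot scores Out-of-fold predicted probabilities.
#' @slot labels Integer reference labels (1 = isovascular).
#' @slot threshold Probability threshold used for the predicted phenotype.
#' @slot lambda Ridge penalty used.
#' @slot seed Seed that generated the fold assignment.
#' @seealso [crossvalClassify()]
#' @export
setClass("PhenotypeModel",
  slots = c(
    coefficients = "numeric",
    center = "numeric",
    scale = "numeric",
    folds = "integer",
    foldAUC = "numeric",
    meanAUC = "numeric",
    pooledAUC = "numeric",
    roc = "list",
    scores = "numeric",
    labels = "integer",
    threshold = "numeric",
    lambda = "numeric",
    seed = "integer"
  )
)

setValidity("PhenotypeModel", function(object) {
  msg <- character(0)
  if (object@meanAUC < 0 || object@meanAUC > 1)
    msg <- c(msg, "meanAUC must lie in [0, 1]")
  if (length(object@scores) != length(object@labels) ||
      length(object@scores) != length(object@folds))
    msg <- c(msg, "scores, labels and folds must have equal length")
  if (length(msg)) msg else TRUE
})

#' Acquisition protocol (canonical time grid)
#'
#' The dynamic acquisition time grid of the interleaved perfusion protocol:
#' 13 acquisitions at 2 s intervals from t = 0, one parenchymal-phase volume
#' at 35 s, 9 acquisitions at 3 s intervals from 38 s, one at 70 s, and late
#' acquisitions at 90, 120 and 150 s (27 timepoints). The scan starts 2 s
#' before the measured aortic contrast arrival, recorded as
#' \code{arrivalOffset}.
#'
#' @slot times Acquisition times, seconds, strictly increasing.
#' @slot arrivalOffset Seconds between scan start and aortic contrast
#'   arrival (default 2).
#' @seealso [defaultProtocol()]
#' @export
setClass("AcquisitionProtocol",
  slots = c(times = "numeric", arrivalOffset = "numeric")
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character(0)
  if (length(object@times) < 8L)
    msg <- c(msg, "protocol needs at least 8 timepoints")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "protocol times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' The default 27-point acquisition time grid
#'
#' @param arrivalOffset Seconds between scan start and aortic arrival.
#' @return An [AcquisitionProtocol-class] object.
#' @examples
#' protocolTimes(defaultProtocol())
#' @export
defaultProtocol <- function(arrivalOffset = 2) {
  new("AcquisitionProtocol",
    times = c(seq(0, 24, by = 2), 35, seq(38, 62, by = 3), 70, 90, 120, 150),
    arrivalOffset = arrivalOffset
  )
}

#' Group-level simulation parameters
#'
#' Feature distribution and survival parameters of one vascular phenotype
#' group for the synthetic cohort generator. Defaults for the two phenotypes
#' are provided by [hypovascularDefaults()] and [isovascularDefaults()].
#'
#' @param slopeMean,slopeSd Tumor enhancement slope distribution, HU/s.
#' @param peakMean,peakSd Tumor peak enhancement distribution, HU.
#' @param deltaMean,deltaSd Pancreas-minus-tumor peak difference, HU.
#' @param n Number of patients in the group.
#' @param survivalMedianDays Median overall survival, days.
#' @param label Group label.
#' @return A list of class \code{"GroupParams"}.
#' @export
groupParams <- function(slopeMean, slopeSd, peakMean, peakSd,
                        deltaMean, deltaSd, n, survivalMedianDays,
                        label = "group") {
  stopifnot(slopeSd > 0, peakSd > 0, deltaSd > 0, n > 0,
            survivalMedianDays > 0)
  structure(
    list(slopeMean = slopeMean, slopeSd = slopeSd,
         peakMean = peakMean, peakSd = peakSd,
         deltaMean = deltaMean, deltaSd = deltaSd,
         n = as.integer(n), survivalMedianDays = survivalMedianDays,
         label = label),
    class = "GroupParams"
  )
}

#' @rdname groupParams
#' @export
hypovascularDefaults <- function() {
  groupParams(2.0, 0.6, 46.8, 12.2, 35.3, 19.4, 72L, 320,
              label = "hypovascular")
}

#' @rdname groupParams
#' @export
isovascularDefaults <- function() {
  groupParams(2.9, 1.1, 69.9, 22.1, 12.0, 9.1, 20L, 377,
              label = "isovascular")
}
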