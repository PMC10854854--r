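#' Default anatomical label schema
#'
#' Integer label assignments for the anatomical structures segmented around
#' the pancreas. The names follow the segmentation model's structure list;
#' the integer codes are a package convention and can be edited or loaded
#' from a YAML file with [readLabelSchema()].
#'
#' @return A [LabelSchema-class].
#' @examples
#' defaultLabelSchema()
#' @export
defaultLabelSchema <- function() {
  codes <- c(
    background = 0L,
    pancreas = 1L,
    tumor = 2L,
    portomesenteric_splenic_veins = 3L,
    abdominal_aorta = 4L,
    celiac_trunk = 5L,
    hepatic_artery = 6L,
    splenic_artery = 7L,
    superior_mesenteric_artery = 8L,
    pancreatic_duct = 9L,
    common_bile_duct = 10L,
    stent = 11L
  )
  new("LabelSchema",
      codes = codes,
      vesselNames = c("portomesenteric_splenic_veins", "abdominal_aorta",
                      "celiac_trunk", "hepatic_artery", "splenic_artery",
                      "superior_mesenteric_artery"),
      stentNames = "stent")
}

#' Read a label schema from YAML
#'
#' The file must contain a \code{codes} mapping (structure name ->
#' integer) and may contain \code{vessels} and \code{stents} name lists.
#'
#' @param path Path to a YAML file.
#' @return A [LabelSchema-class].
#' @export
readLabelSchema <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$codes)) stop("schema file must contain a 'codes' mapping")
  codes <- vapply(y$codes, function(x) as.integer(x), integer(1))
  new("LabelSchema", codes = codes,
      vesselNames = as.character(unlist(y$vessels)),
      stentNames = as.character(unlist(y$stents)))
}

#' Default exclusion set for the tumor ROI
#'
#' Vessels, endoprostheses and stents running through the tumor
#' segmentation are excluded before averaging to reduce artifacts in the
#' time-intensity curve.
#'
#' @param schema A [LabelSchema-class].
#' @return Character vector of structure names.
#' @export
defaultTumorExclusions <- function(schema = defaultLabelSchema()) {
  c(schema@vesselNames, schema@stentNames)
}

#' Read a dynamic series from NIfTI
#'
#' Accepts either a single 4D NIfTI file or a vector of 3D NIfTI files
#' (one per timepoint, in acquisition order).
#'
#' @param paths One 4D NIfTI path or a character vector of 3D NIfTI paths.
#' @param acquisitionTimes Acquisition times in seconds, one per volume.
#' @return A [DynamicSeries-class].
#' @export
readDynamicSeries <- function(paths, acquisitionTimes) {
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    arr <- array(as.numeric(img), dim = dim(img))
    if (length(dim(arr)) != 4L)
      stop("single-file input must be a 4D NIfTI volume")
    sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  } else {
    first <- RNifti::readNifti(paths[1])
    d3 <- dim(first)
    if (length(d3) != 3L) stop("per-timepoint inputs must be 3D volumes")
    arr <- array(NA_real_, dim = c(d3, length(paths)))
    arr[, , , 1] <- as.numeric(first)
    for (k in seq_along(paths)[-1]) {
      img <- RNifti::readNifti(paths[k])
      if (!identical(dim(img), d3))
        stop(sprintf("volume %d has a different spatial shape", k))
      arr[, , , k] <- as.numeric(img)
    }
    sp <- tryCatch(RNifti::pixdim(first)[1:3], error = function(e) c(1, 1, 1))
  }
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  DynamicSeries(arr, acquisitionTimes, voxelSpacing = sp)
}

#' Read a 3D label map from NIfTI
#'
#' @param path NIfTI path.
#' @return 3D integer array.
#' @export
readLabelMap <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  if (length(dim(arr)) != 3L) stop("label map must be a 3D volume")
  arr
}

#' Extract a per-ROI time-intensity curve from a dynamic series
#'
#' Overlays the single-timepoint 3D segmentation on every timepoint of the
#' series and averages the attenuation of the ROI voxels. Voxels carrying
#' an excluded structure's label are removed before averaging. For the
#' tumor ROI the default exclusion set is all vessels plus stent labels
#' ([defaultTumorExclusions()]); pass \code{exclude = character(0)} to
#' disable.
#'
#' @param series A [DynamicSeries-class].
#' @param labels 3D integer label map, spatially congruent with the series.
#' @param schema A [LabelSchema-class].
#' @param roi Structure name to extract (e.g. \code{"tumor"}).
#' @param exclude Character vector of structure names to exclude, or
#'   \code{NULL} for the ROI-dependent default.
#' @return A [TimeIntensityCurve-class]; the number of averaged voxels is
#'   recorded in its \code{voxelCount}.
#' @export
extractTIC <- function(series, labels, schema = defaultLabelSchema(),
                       roi = "tumor", exclude = NULL) {
  stopifnot(is(series, "DynamicSeries"), is(schema, "LabelSchema"))
  d <- dim(series@volumes)
  if (!identical(as.integer(dim(labels)), as.integer(d[1:3])))
    stop("label map shape does not match the series' spatial shape")
  if (!roi %in% names(schema@codes))
    stop(sprintf("roi '%s' not present in the label schema", roi))
  if (is.null(exclude))
    exclude <- if (roi == "tumor") defaultTumorExclusions(schema)
               else character(0)
  unknown <- setdiff(exclude, names(schema@codes))
  if (length(unknown))
    stop(paste("unknown exclusion labels:", paste(unknown, collapse = ", ")))

  ## the label map assigns one label per voxel, so exclusion amounts to
  ## removing voxels whose label is in the exclusion set before averaging
  roiCode <- schema@codes[[roi]]
  exCodes <- schema@codes[exclude]
  mask <- labels == roiCode & !(labels %in% exCodes)
  idx <- which(mask)
  if (length(idx) == 0L)
    stop(sprintf("ROI '%s' is empty after exclusion", roi))

  nt <- d[4]
  nvox <- prod(d[1:3])
  vals <- vapply(seq_len(nt), function(k) {
    mean(series@volumes[(k - 1L) * nvox + idx])
  }, numeric(1))
  TimeIntensityCurve(series@acquisitionTimes, vals, roiName = roi,
                     voxelCount = length(idx))
}

#' Structural sanity report for a segmentation
#'
#' Report-only checks of a label map against a schema: per-label voxel
#' counts, flags for empty mandatory labels, and a flag when the tumor's
#' bounding box does not touch the pancreas' bounding region (a tumor
#' disconnected from the gland usually indicates a mislabel).
#'
#' @param labels 3D integer label map.
#' @param schema A [LabelSchema-class].
#' @param margin Voxel margin by which the pancreas bounding box is grown
#'   before the overlap check.
#' @return List with \code{counts} (named integer vector over all schema
#'   labels) and \code{flags} (character vector, empty when nothing is
#'   suspicious).
#' @export
validateSegmentation <- function(labels, schema = defaultLabelSchema(),
                                 margin = 5L) {
  stopifnot(is(schema, "LabelSchema"))
  counts <- vapply(schema@codes, function(code)
    sum(labels == code), integer(1))
  names(counts) <- names(schema@codes)
  flags <- character(0)
  for (req in c("tumor", "pancreas"))
    if (counts[[req]] == 0L)
      flags <- c(flags, sprintf("mandatory label '%s' has no voxels", req))
  if (counts[["tumor"]] > 0L && counts[["pancreas"]] > 0L) {
    bbox <- function(code) {
      w <- which(labels == code, arr.ind = TRUE)
      rbind(apply(w, 2, min), apply(w, 2, max))
    }
    bt <- bbox(schema@codes[["tumor"]])
    bp <- bbox(schema@codes[["pancreas"]])
    overlap <- all(bt[1, ] <= bp[2, ] + margin) &&
      all(bt[2, ] >= bp[1, ] - margin)
    if (!overlap)
      flags <- c(flags,
        "tumor bounding box is disconnected from the pancreas region")
  }
  list(counts = counts, flags = flags)
}
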