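## Truncated-normal draw by rejection; bounds are physical minima so the
## acceptance rate is high and a bounded retry count is safe.
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf,
                        maxTries = 1000L) {
  for (i in seq_len(maxTries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop(sprintf(
    "could not draw from truncated normal(mean=%.3g, sd=%.3g) within bounds (%.3g, %.3g)",
    mean, sd, lower, upper))
}

#' Evaluate the exact trilinear model
#'
#' @param t Times, seconds.
#' @param baseline Baseline attenuation, HU.
#' @param onset Start of enhancement, seconds.
#' @param slope Enhancement slope, HU/s.
#' @param peakEnhancement Peak enhancement above baseline, HU.
#' @param washoutSlope Washout slope, HU/s.
#' @return Model values, HU.
#' @export
trilinearModel <- function(t, baseline, onset, slope, peakEnhancement,
                           washoutSlope) {
  peakT <- onset + peakEnhancement / slope
  ifelse(t <= onset, baseline,
    ifelse(t <= peakT, baseline + slope * (t - onset),
      baseline + peakEnhancement + washoutSlope * (t - peakT)))
}

#' Generate a synthetic time-intensity curve
#'
#' Samples an exact trilinear curve on the acquisition grid and adds
#' i.i.d. Gaussian noise. The generating parameters are returned alongside
#' so fits can be compared with ground truth.
#'
#' @param protocol An [AcquisitionProtocol-class] (default the 27-point
#'   grid).
#' @param baseline Baseline attenuation, HU.
#' @param onset Start of enhancement, seconds; must lie inside the grid.
#' @param slope Enhancement slope, HU/s (> 0).
#' @param peakEnhancement Peak enhancement above baseline, HU (> 0).
#' @param washoutSlope Washout slope, HU/s (must be below \code{slope}).
#' @param noiseSd Gaussian noise standard deviation, HU.
#' @param seed Optional integer seed (local to this call).
#' @param roiName Name stored on the returned curve.
#' @return List with elements \code{curve} (a
#'   [TimeIntensityCurve-class]) and \code{truth} (named list of the
#'   generating parameters, including \code{peakTime}).
#' @examples
#' g <- generateTIC(onset = 6, slope = 2, peakEnhancement = 20, seed = 1)
#' fitCurve(g$curve)
#' @export
generateTIC <- function(protocol = defaultProtocol(), baseline = 40,
                        onset = 12, slope = 2, peakEnhancement = 46.8,
                        washoutSlope = -0.2, noiseSd = 0, seed = NULL,
                        roiName = "tumor") {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (slope <= 0) stop("slope must be positive")
  if (peakEnhancement <= 0) stop("peakEnhancement must be positive")
  if (washoutSlope >= slope)
    stop("washoutSlope must be smaller than the upslope")
  t <- protocol@times
  peakT <- onset + peakEnhancement / slope
  if (onset <= min(t) || onset >= max(t))
    stop("onset lies outside the acquisition grid")
  if (peakT >= max(t))
    stop("peak time lies outside the acquisition grid")
  clean <- trilinearModel(t, baseline, onset, slope, peakEnhancement,
                          washoutSlope)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  noisy <- clean + if (noiseSd > 0) stats::rnorm(length(t), 0, noiseSd) else 0
  list(
    curve = TimeIntensityCurve(t, noisy, roiName = roiName),
    truth = list(baseline = baseline, onset = onset, slope = slope,
                 peakEnhancement = peakEnhancement,
                 washoutSlope = washoutSlope, peakTime = peakT,
                 noiseSd = noiseSd)
  )
}

#' Generate a synthetic two-phenotype cohort
#'
#' Draws per-patient perfusion parameters from truncated-normal group
#' distributions, synthesizes paired tumor and pancreas time-intensity
#' curves on the acquisition grid, and draws exponential survival times
#' with administrative censoring.
#'
#' Per patient the tumor triple (slope, peak enhancement, pancreas-tumor
#' peak difference) is drawn from the group distribution (slope truncated
#' at 0.1 HU/s, peaks at 5 HU). The pancreas shares the tumor's contrast
#' arrival and peak time (both tissues see the same arterial input), so
#' its slope is its own peak enhancement divided by the common rise
#' duration. A draw is rejected and repeated when the implied peak falls
#' too late in the grid to leave two washout samples.
#'
#' @param hypo,iso [groupParams()] lists (defaults: Table values of the
#'   hypovascular and isovascular phenotype groups).
#' @param noiseSd Gaussian noise SD added to every curve, HU (default 3).
#' @param seed Integer seed; all randomness in the cohort derives from it.
#' @param protocol An [AcquisitionProtocol-class].
#' @param onsetMean,onsetSd Per-patient enhancement onset distribution,
#'   seconds (truncated below at 4 s).
#' @param baselineMean,baselineSd Pre-contrast attenuation distribution, HU.
#' @param washoutMean,washoutSd Tumor washout slope distribution, HU/s
#'   (truncated above at -0.02).
#' @param pancreasWashoutMean Pancreas washout slope mean, HU/s.
#' @param censorHorizonDays Administrative censoring horizon, days.
#' @param latestPeakS Latest admissible peak time, seconds.
#' @return List with \code{records} (data frame: patient_id, group,
#'   phenotype_visual, survival_days, event, plus the true generating
#'   parameters) and \code{curves} (per patient: \code{tumor} and
#'   \code{pancreas} [TimeIntensityCurve-class] objects).
#' @examples
#' coh <- generateCohort(seed = 1)
#' nrow(coh$records)
#' @export
generateCohort <- function(hypo = hypovascularDefaults(),
                           iso = isovascularDefaults(),
                           noiseSd = 3, seed = 42,
                           protocol = defaultProtocol(),
                           onsetMean = 12, onsetSd = 1.5,
                           baselineMean = 40, baselineSd = 5,
                           washoutMean = -0.2, washoutSd = 0.08,
                           pancreasWashoutMean = -0.3,
                           censorHorizonDays = 1095,
                           latestPeakS = 85) {
  stopifnot(inherits(hypo, "GroupParams"), inherits(iso, "GroupParams"))
  set.seed(seed)
  groups <- list(hypo, iso)
  records <- list()
  curves <- list()
  pid <- 0L
  for (gp in groups) {
    rate <- log(2) / gp$survivalMedianDays
    for (k in seq_len(gp$n)) {
      pid <- pid + 1L
      draw <- NULL
      for (try in seq_len(1000L)) {
        slope <- rtruncnorm1(gp$slopeMean, gp$slopeSd, lower = 0.1)
        peak <- rtruncnorm1(gp$peakMean, gp$peakSd, lower = 5)
        delta <- stats::rnorm(1L, gp$deltaMean, gp$deltaSd)
        onset <- rtruncnorm1(onsetMean, onsetSd, lower = 4)
        pancPeak <- peak + delta
        peakT <- onset + peak / slope
        if (pancPeak > 5 && peakT <= latestPeakS) {
          draw <- list(slope = slope, peak = peak, delta = delta,
                       onset = onset, pancPeak = pancPeak, peakT = peakT)
          break
        }
      }
      if (is.null(draw))
        stop("could not draw feasible perfusion parameters after 1000 tries")
      baseT <- stats::rnorm(1L, baselineMean, baselineSd)
      baseP <- stats::rnorm(1L, baselineMean, baselineSd)
      woT <- rtruncnorm1(washoutMean, washoutSd, upper = -0.02)
      woP <- rtruncnorm1(pancreasWashoutMean, washoutSd, upper = -0.02)
      dur <- draw$peakT - draw$onset
      pancSlope <- draw$pancPeak / dur
      tumor <- generateTIC(protocol, baseline = baseT, onset = draw$onset,
                           slope = draw$slope,
                           peakEnhancement = draw$peak,
                           washoutSlope = woT, noiseSd = noiseSd,
                           roiName = "tumor")
      panc <- generateTIC(protocol, baseline = baseP, onset = draw$onset,
                          slope = pancSlope,
                          peakEnhancement = draw$pancPeak,
                          washoutSlope = woP, noiseSd = noiseSd,
                          roiName = "pancreas")
      surv <- stats::rexp(1L, rate)
      id <- sprintf("P%03d", pid)
      records[[pid]] <- data.frame(
        patient_id = id,
        group = gp$label,
        phenotype_visual = as.integer(gp$label == "isovascular"),
        survival_days = min(surv, censorHorizonDays),
        event = as.integer(surv <= censorHorizonDays),
        true_slope = draw$slope,
        true_peak = draw$peak,
        true_delta = draw$delta,
        true_onset = draw$onset,
        true_pancreas_peak = draw$pancPeak
      )
      curves[[id]] <- list(tumor = tumor$curve, pancreas = panc$curve,
                           tumorTruth = tumor$truth, pancreasTruth = panc$truth)
    }
  }
  list(records = do.call(rbind, records), curves = curves,
       protocol = protocol, noiseSd = noiseSd, seed = seed)
}

#' Generate a 4D digital perfusion phantom
#'
#' Builds an ellipsoidal pancreas with an embedded ellipsoidal tumor and a
#' cylindrical vessel running through both, assigns each compartment its
#' own trilinear time-intensity curve, and samples the 4D series on the
#' acquisition grid with optional voxel noise and optional per-timepoint
#' rigid (integer-voxel) jitter emulating residual motion after
#' registration.
#'
#' @param protocol An [AcquisitionProtocol-class].
#' @param shape Integer triple of voxel dimensions (each >= 32).
#' @param schema A [LabelSchema-class]; tumor, pancreas and the vessel
#'   label are taken from it.
#' @param pancreasRadii,tumorRadii Ellipsoid semi-axes in voxels.
#' @param vesselRadius Vessel cylinder radius in voxels.
#' @param tumorParams,pancreasParams,vesselParams Named lists of
#'   [generateTIC()] curve parameters per compartment.
#' @param backgroundHU Attenuation of unlabeled voxels.
#' @param noiseSd Voxel-wise Gaussian noise SD, HU.
#' @param jitterVoxels Maximum rigid shift per timepoint, voxels (0 = none).
#' @param seed Integer seed.
#' @return List with \code{series} ([DynamicSeries-class]),
#'   \code{labels} (3D integer array), \code{schema} and \code{truth}
#'   (per-compartment clean curves as [TimeIntensityCurve-class]).
#' @export
generatePhantom <- function(protocol = defaultProtocol(),
                            shape = c(40L, 40L, 32L),
                            schema = defaultLabelSchema(),
                            pancreasRadii = c(14, 10, 8),
                            tumorRadii = c(6, 5, 4),
                            vesselRadius = 2,
                            tumorParams = list(baseline = 40, onset = 8,
                                               slope = 2,
                                               peakEnhancement = 46.8,
                                               washoutSlope = -0.2),
                            pancreasParams = list(baseline = 40, onset = 8,
                                                  slope = 3.5,
                                                  peakEnhancement = 82,
                                                  washoutSlope = -0.3),
                            vesselParams = list(baseline = 40, onset = 4,
                                                slope = 30,
                                                peakEnhancement = 300,
                                                washoutSlope = -3),
                            backgroundHU = -50,
                            noiseSd = 0, jitterVoxels = 0, seed = NULL) {
  stopifnot(is(protocol, "AcquisitionProtocol"), is(schema, "LabelSchema"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom shape must be at least 32 voxels in each dimension")
  if (any(tumorRadii >= pancreasRadii))
    stop("lesion larger than pancreas: tumor radii must be smaller")
  if (!is.null(seed)) set.seed(seed)

  t <- protocol@times
  nt <- length(t)
  ctr <- (shape + 1) / 2
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  X <- array(ax, dim = shape)
  Y <- array(rep(ay, each = shape[1]), dim = shape)
  Z <- array(rep(az, each = shape[1] * shape[2]), dim = shape)

  inEllipsoid <- function(c0, r) {
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
      ((Z - c0[3]) / r[3])^2 <= 1
  }
  panc <- inEllipsoid(ctr, pancreasRadii)
  tumorCtr <- ctr + c(round(pancreasRadii[1] / 3), 0, 0)
  tumor <- inEllipsoid(tumorCtr, tumorRadii)
  ## vessel: cylinder along x through the tumor centre
  vessel <- (Y - tumorCtr[2])^2 + (Z - tumorCtr[3])^2 <= vesselRadius^2

  labels <- array(0L, dim = shape)
  labels[panc] <- schema@codes[["pancreas"]]
  labels[tumor] <- schema@codes[["tumor"]]
  labels[vessel & (panc | tumor)] <- schema@codes[["abdominal_aorta"]]

  curveOf <- function(p) do.call(trilinearModel, c(list(t = t), p))
  compTIC <- list(
    pancreas = curveOf(pancreasParams),
    tumor = curveOf(tumorParams),
    vessel = curveOf(vesselParams)
  )

  vols <- array(backgroundHU, dim = c(shape, nt))
  pancMask <- labels == schema@codes[["pancreas"]]
  tumorMask <- labels == schema@codes[["tumor"]]
  vesselMask <- labels == schema@codes[["abdominal_aorta"]]
  for (k in seq_len(nt)) {
    v <- array(backgroundHU, dim = shape)
    v[pancMask] <- compTIC$pancreas[k]
    v[tumorMask] <- compTIC$tumor[k]
    v[vesselMask] <- compTIC$vessel[k]
    if (jitterVoxels > 0 && k > 1L) {
      sh <- sample(seq(-jitterVoxels, jitterVoxels), 3L, replace = TRUE)
      v <- shiftVolume(v, sh, fill = backgroundHU)
    }
    if (noiseSd > 0)
      v <- v + array(stats::rnorm(prod(shape), 0, noiseSd), dim = shape)
    vols[, , , k] <- v
  }

  list(
    series = DynamicSeries(vols, t, voxelSpacing = c(2, 2, 3)),
    labels = labels,
    schema = schema,
    truth = lapply(compTIC, function(v)
      TimeIntensityCurve(t, v, roiName = "truth"))
  )
}

## integer-voxel rigid shift with constant fill
shiftVolume <- function(v, shift, fill = 0) {
  d <- dim(v)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    s <- shift[i]
    if (abs(s) >= d[i]) return(out)
    if (s >= 0) { dst[[i]] <- (1 + s):d[i]; src[[i]] <- 1:(d[i] - s) }
    else { dst[[i]] <- 1:(d[i] + s); src[[i]] <- (1 - s):d[i] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}
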