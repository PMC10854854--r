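#' Curve-fit configuration
#'
#' Settings for the two-step curve fit ([fitCurve()]).
#'
#' @param smoothing Non-negative residual-sum-of-squares target for the
#'   smoothing spline, or \code{NULL} (default) for the automatic rule
#'   \eqn{s = n \hat\sigma^2} with \eqn{\hat\sigma} estimated from local
#'   pseudo-residuals (see [fitSpline()]).
#' @param windowSize Number of timepoints in the upslope window (default 5:
#'   two before the maximum derivative, the maximum, two after).
#' @param washoutCapS Only washout samples acquired at or before this time
#'   (seconds) enter the washout line fit; default \code{Inf} keeps all
#'   late acquisitions.
#' @return A list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(smoothing = NULL, windowSize = 5L, washoutCapS = Inf) {
  if (!is.null(smoothing) && (!is.numeric(smoothing) || smoothing < 0))
    stop("smoothing must be a non-negative scalar or NULL")
  windowSize <- as.integer(windowSize)
  if (windowSize < 3L) stop("windowSize must be at least 3")
  structure(list(smoothing = smoothing, windowSize = windowSize,
                 washoutCapS = washoutCapS),
            class = "fitConfig")
}

## Local-linear pseudo-residual noise estimate, valid on non-uniform grids.
## For each interior sample the value is compared with the linear
## interpolation of its neighbours; the normalization makes each squared
## pseudo-residual an unbiased estimate of sigma^2 under i.i.d. noise.
## A 20%-trimmed mean (rescaled by the corresponding chi^2_1 truncated
## moment) keeps the few triples spanning the curve's breakpoints out of
## the estimate while staying far more stable than a median on ~25 values.
estimateNoiseSd <- function(times, values) {
  n <- length(values)
  i <- 2:(n - 1)
  h1 <- times[i] - times[i - 1]
  h2 <- times[i + 1] - times[i]
  a <- h1 / (h1 + h2)                      # weight of right neighbour
  r <- values[i] - (a * values[i + 1] + (1 - a) * values[i - 1])
  c2 <- 1 / (1 + a^2 + (1 - a)^2)
  sq <- sort(c2 * r^2)
  k <- max(1L, floor(0.8 * length(sq)))
  ## E[X | X below the 80% quantile] for X ~ chi^2_1
  scale <- stats::pchisq(stats::qchisq(0.8, 1), 3) / 0.8
  sqrt(mean(sq[seq_len(k)]) / scale)
}

## Solve for the smooth.spline spar whose residual sum of squares matches
## the requested target. RSS is monotone non-decreasing in spar.
splineForTarget <- function(times, values, target) {
  rssAt <- function(spar) {
    f <- stats::smooth.spline(times, values, spar = spar, all.knots = TRUE,
                              keep.data = FALSE)
    sum((values - stats::predict(f, times)$y)^2)
  }
  lo <- -1.5; hi <- 1.5   # beyond spar ~1.5 the band solver degrades
  if (rssAt(lo) >= target) spar <- lo
  else if (rssAt(hi) <= target) spar <- hi
  else spar <- stats::uniroot(function(s) rssAt(s) - target,
                              c(lo, hi), tol = 1e-4)$root
  stats::smooth.spline(times, values, spar = spar, all.knots = TRUE,
                       keep.data = FALSE)
}

#' Smoothing-spline fit of a time-intensity curve
#'
#' First step of the two-step curve fit: a cubic smoothing spline is fitted
#' to the whole curve and its analytic first derivative is evaluated at the
#' sample times. The index of the maximum derivative (first index on ties)
#' localizes the contrast upslope for [selectUpslopeWindow()].
#'
#' When \code{smoothing} is \code{NULL} the residual target is
#' \eqn{s = n \max(\hat\sigma, \sigma_{min})^2}, where \eqn{\hat\sigma} is a
#' median-based local pseudo-residual estimate of the noise standard
#' deviation and \eqn{\sigma_{min}} is a small floor (2\% of the value
#' range) that keeps the derivative of noiseless curves smooth enough for
#' stable localization.
#'
#' @param curve A [TimeIntensityCurve-class] with at least 8 samples.
#' @param smoothing Optional non-negative residual-sum-of-squares target.
#' @return A [SplineSummary-class].
#' @examples
#' tic <- TimeIntensityCurve(seq(0, 26, 2), 40 + 2 * seq(0, 26, 2))
#' fitSpline(tic)
#' @export
fitSpline <- function(curve, smoothing = NULL) {
  stopifnot(is(curve, "TimeIntensityCurve"))
  validObject(curve)
  n <- length(curve@times)
  if (n < 8L)
    stop(sprintf("curve has %d samples; at least 8 are required", n))
  times <- curve@times
  values <- curve@values
  if (is.null(smoothing)) {
    sigma <- estimateNoiseSd(times, values)
    floorSd <- 0.02 * max(diff(range(values)), 1e-8)
    smoothing <- n * max(sigma, floorSd)^2
  }
  fit <- splineForTarget(times, values, smoothing)
  sm <- stats::predict(fit, times)$y
  dv <- stats::predict(fit, times, deriv = 1)$y
  new("SplineSummary",
      times = times, smoothedValues = sm, derivative = dv,
      argmaxIndex = which.max(dv), smoothing = smoothing)
}

#' Select the upslope window around the maximum derivative
#'
#' Second-step localization: a contiguous window of \code{windowSize}
#' sample indices centred on the maximum-derivative index (for the default
#' size 5: two before, the maximum, two after). The window is clipped at
#' the curve boundaries, preserving its size when possible and shrinking
#' it (minimum 3) otherwise. All earlier samples form the non-enhancement
#' phase and all later samples the washout phase, each of which must keep
#' at least 2 points.
#'
#' @param spline A [SplineSummary-class] from [fitSpline()].
#' @param curve The corresponding [TimeIntensityCurve-class].
#' @param windowSize Window length in samples (default 5).
#' @return Integer vector of contiguous sample indices.
#' @examples
#' tic <- TimeIntensityCurve(seq(0, 52, 2),
#'   c(rep(40, 4), 40 + 2 * seq(2, 20, 2), 80 - 0.2 * seq(2, 26, 2)))
#' sp <- fitSpline(tic)
#' selectUpslopeWindow(sp, tic)
#' @export
selectUpslopeWindow <- function(spline, curve, windowSize = 5L) {
  stopifnot(is(spline, "SplineSummary"), is(curve, "TimeIntensityCurve"))
  windowSize <- as.integer(windowSize)
  if (windowSize < 3L) stop("windowSize must be at least 3")
  n <- length(curve@times)
  if (length(spline@times) != n)
    stop("spline summary and curve have different lengths")
  a <- spline@argmaxIndex
  before <- (windowSize - 1L) %/% 2L
  lo <- a - before
  hi <- lo + windowSize - 1L
  ## clip at the curve boundaries, preserving the size when possible
  if (lo < 1L) { hi <- min(n, hi + (1L - lo)); lo <- 1L }
  if (hi > n) { lo <- max(1L, lo - (hi - n)); hi <- n }
  if (hi - lo + 1L < 3L)
    stop("curve too short for an upslope window of at least 3 samples")
  if (lo - 1L < 2L || n - hi < 2L)
    stop(sprintf(
      "insufficient phase support: window %d..%d leaves %d pre-window and %d post-window samples (2 required in each phase)",
      lo, hi, lo - 1L, n - hi))
  lo:hi
}

## least-squares line through (x, y); returns c(intercept, slope)
.lsLine <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sl <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(ym - sl * xm, sl)
}

#' Fit the trilinear model given an upslope window
#'
#' Fits the three phases of the model: a least-squares constant over the
#' pre-window samples (non-enhancement phase), a least-squares line over
#' the window samples (upslope phase) and a least-squares line over the
#' post-window samples (washout phase). The start of enhancement is the
#' intersection of the static line with the upslope line; the peak is the
#' intersection of the upslope with the washout line; peak enhancement is
#' the model value at the peak minus the baseline level.
#'
#' @param curve A [TimeIntensityCurve-class].
#' @param window Contiguous integer indices of the upslope phase, with at
#'   least 2 samples before and after.
#' @param washoutCapS Washout samples later than this time (seconds) are
#'   excluded from the washout line fit (and from the reported rss);
#'   default \code{Inf}.
#' @return A [TrilinearFit-class].
#' @examples
#' t <- c(seq(0, 24, 2), 35, seq(38, 62, 3), 70, 90, 120, 150)
#' v <- ifelse(t <= 6, 40, ifelse(t <= 16, 40 + 2 * (t - 6), 60 - 0.2 * (t - 16)))
#' tic <- TimeIntensityCurve(t, v)
#' fitTrilinear(tic, 4:9)
#' @export
fitTrilinear <- function(curve, window, washoutCapS = Inf) {
  stopifnot(is(curve, "TimeIntensityCurve"))
  validObject(curve)
  window <- as.integer(window)
  n <- length(curve@times)
  if (length(window) < 2L || any(diff(window) != 1L))
    stop("window must be a contiguous index range of length >= 2")
  if (min(window) < 1L || max(window) > n)
    stop("window indices out of range")
  if (min(window) - 1L < 2L || n - max(window) < 2L)
    stop(sprintf(
      "insufficient phase support: window %d..%d leaves %d pre-window and %d post-window samples (2 required in each phase)",
      min(window), max(window), min(window) - 1L, n - max(window)))

  t <- curve@times; y <- curve@values
  preIdx <- seq_len(min(window) - 1L)
  postIdx <- (max(window) + 1L):n
  postFitIdx <- postIdx[t[postIdx] <= washoutCapS]
  if (length(postFitIdx) < 2L)
    stop("washout cap leaves fewer than 2 washout samples")

  baseline <- mean(y[preIdx])
  up <- .lsLine(t[window], y[window])
  wo <- .lsLine(t[postFitIdx], y[postFitIdx])

  if (up[2] <= 0)
    stop("non-enhancing curve: fitted upslope is not positive")
  if (up[2] <= wo[2])
    stop("degenerate geometry: upslope does not exceed washout slope")

  onset <- (baseline - up[1]) / up[2]
  peakT <- (wo[1] - up[1]) / (up[2] - wo[2])
  if (!(onset < peakT))
    stop("degenerate geometry: peak does not follow the start of enhancement")
  peakEnh <- up[2] * (peakT - onset)

  rss <- sum((y[preIdx] - baseline)^2) +
    sum((y[window] - (up[1] + up[2] * t[window]))^2) +
    sum((y[postFitIdx] - (wo[1] + wo[2] * t[postFitIdx]))^2)

  new("TrilinearFit",
      baselineLevel = baseline,
      upslopeSlope = up[2], upslopeIntercept = up[1],
      washoutSlope = wo[2], washoutIntercept = wo[1],
      onsetTime = onset, peakTime = peakT, peakEnhancement = peakEnh,
      rss = rss, windowIndices = window)
}

#' Two-step trilinear curve fit
#'
#' Convenience composition of the complete curve fit: smoothing-spline
#' localization of the maximum derivative ([fitSpline()]), selection of the
#' upslope window ([selectUpslopeWindow()]), and the piecewise-linear fit
#' ([fitTrilinear()]). Errors from the component steps are re-signalled
#' with a stage label.
#'
#' @param curve A [TimeIntensityCurve-class].
#' @param config A [fitConfig()] list.
#' @return A [TrilinearFit-class].
#' @examples
#' t <- c(seq(0, 24, 2), 35, seq(38, 62, 3), 70, 90, 120, 150)
#' v <- ifelse(t <= 6, 40, ifelse(t <= 16, 40 + 2 * (t - 6), 60 - 0.2 * (t - 16)))
#' fitCurve(TimeIntensityCurve(t, v))
#' @export
fitCurve <- function(curve, config = fitConfig()) {
  stopifnot(inherits(config, "fitConfig"))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
  }
  sp <- stage("spline", fitSpline(curve, smoothing = config$smoothing))
  scaleHU <- diff(range(curve@values)) / diff(range(curve@times))
  if (max(sp@derivative) <= 1e-8 * max(1, scaleHU))
    stop("[window] non-enhancing curve: smoothed derivative is never positive",
         call. = FALSE)
  win <- stage("window",
               selectUpslopeWindow(sp, curve, windowSize = config$windowSize))
  stage("trilinear",
        fitTrilinear(curve, win, washoutCapS = config$washoutCapS))
}

#' Flatten a TrilinearFit to a one-row data frame
#'
#' @param fit A [TrilinearFit-class].
#' @return A one-row \code{data.frame} with all fitted quantities.
#' @export
trilinearAsRow <- function(fit) {
  stopifnot(is(fit, "TrilinearFit"))
  data.frame(
    baseline_hu = fit@baselineLevel,
    slope_hu_s = fit@upslopeSlope,
    upslope_intercept_hu = fit@upslopeIntercept,
    washout_slope_hu_s = fit@washoutSlope,
    washout_intercept_hu = fit@washoutIntercept,
    onset_s = fit@onsetTime,
    peak_s = fit@peakTime,
    peak_enhancement_hu = fit@peakEnhancement,
    rss = fit@rss,
    window_first = min(fit@windowIndices),
    window_last = max(fit@windowIndices)
  )
}
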