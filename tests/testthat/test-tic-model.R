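test_that("spline derivative of a straight line is its slope, argmax ties break earliest", {
  t <- seq(0, 52, by = 2)
  curve <- TimeIntensityCurve(t, 40 + 2 * t)
  sp <- fitSpline(curve)
  expect_equal(derivativeValues(sp), rep(2, length(t)), tolerance = 1e-3)
  ## exactly tied derivative vector: first index must win
  ties <- new("SplineSummary", times = t, smoothedValues = 40 + 2 * t,
              derivative = rep(2, length(t)), argmaxIndex = 1L,
              smoothing = 0)
  expect_identical(argmaxDerivative(ties), 1L)
})

test_that("maximum derivative of a noiseless trilinear curve falls inside its upslope", {
  v <- trilinearOracle(gridTimes, 40, 6, 2, 20, -0.2)
  sp <- fitSpline(TimeIntensityCurve(gridTimes, v))
  tmax <- gridTimes[argmaxDerivative(sp)]
  expect_gte(tmax, 6)
  expect_lte(tmax, 16)
})

test_that("spline argmax agrees with a finite-difference oracle on random smooth curves", {
  set.seed(3)
  for (i in 1:100) {
    ## random sigmoid enhancement curves: one rise, one derivative maximum
    A <- runif(1, 30, 80); ctr <- runif(1, 10, 40); w <- runif(1, 2, 6)
    v <- 40 + A / (1 + exp(-(gridTimes - ctr) / w)) + rnorm(27, 0, 0.3)
    sp <- fitSpline(TimeIntensityCurve(gridTimes, v))
    sm <- smoothedValues(sp)
    ## central finite differences of the smoothed values
    fd <- (sm[3:27] - sm[1:25]) / (gridTimes[3:27] - gridTimes[1:25])
    expect_lte(abs(argmaxDerivative(sp) - (which.max(fd) + 1L)), 1L)
  }
})

test_that("fitSpline rejects short and non-finite input", {
  expect_error(fitSpline(TimeIntensityCurve(1:5, rnorm(5))), "at least 8")
  expect_error(TimeIntensityCurve(1:10, c(rnorm(9), NA)), "finite")
})

test_that("upslope window is centred, clipped and phase-guarded", {
  mkSpline <- function(argmax, n = 27) {
    d <- rep(0, n); d[argmax] <- 1
    new("SplineSummary", times = gridTimes[1:n], smoothedValues = rep(0, n),
        derivative = d, argmaxIndex = as.integer(argmax), smoothing = 0)
  }
  curve <- TimeIntensityCurve(gridTimes, seq_along(gridTimes))
  expect_identical(selectUpslopeWindow(mkSpline(7), curve), 5:9)
  expect_error(selectUpslopeWindow(mkSpline(2), curve),
               "insufficient phase support")
  expect_error(selectUpslopeWindow(mkSpline(26), curve),
               "insufficient phase support")
  ## any interior argmax yields a contiguous window containing it
  for (a in 5:23) {
    w <- selectUpslopeWindow(mkSpline(a), curve)
    expect_true(a %in% w)
    expect_identical(diff(w), rep(1L, length(w) - 1L))
    expect_length(w, 5L)
  }
  ## window size 7 centres 3 before / 3 after
  expect_identical(selectUpslopeWindow(mkSpline(10), curve, windowSize = 7),
                   7:13)
})

test_that("exact trilinear input is recovered exactly through fitTrilinear", {
  ## baseline 40 up to 6 s, slope 2 to 16 s, washout -0.2 after
  v <- trilinearOracle(gridTimes, 40, 6, 2, 20, -0.2)
  curve <- TimeIntensityCurve(gridTimes, v)
  fit <- fitTrilinear(curve, 5:9)   # samples at 8..16 s
  expect_equal(upslopeSlope(fit), 2, tolerance = 1e-6)
  expect_equal(onsetTime(fit), 6, tolerance = 1e-6)
  expect_equal(peakEnhancement(fit), 20, tolerance = 1e-6)
  expect_lt(fitRSS(fit), 1e-6)
  expect_equal(baselineLevel(fit), 40, tolerance = 1e-6)
})

test_that("fitTrilinear rejects degenerate geometry and non-enhancing curves", {
  v <- 80 - 1.5 * gridTimes          # strictly decreasing
  expect_error(fitTrilinear(TimeIntensityCurve(gridTimes, v), 10:14),
               "non-enhancing")
  ## upslope shallower than washout: no valid intersection
  v2 <- trilinearOracle(gridTimes, 40, 6, 2, 20, -0.2)
  v2[24:27] <- v2[23] + 5 * (gridTimes[24:27] - gridTimes[23])
  expect_error(fitTrilinear(TimeIntensityCurve(gridTimes, v2), 5:9),
               "degenerate geometry")
  expect_error(fitTrilinear(TimeIntensityCurve(gridTimes, v2), 1:4),
               "insufficient phase support")
})

test_that("noisy fits stay near the exhaustive-partition oracle", {
  set.seed(17)
  ok <- 0; tried <- 0
  for (i in 1:40) {
    p <- drawShortRise()
    v <- trilinearOracle(gridTimes, p$baseline, p$onset, p$slope,
                         p$peakEnhancement, p$washoutSlope) +
      rnorm(27, 0, 0.3)
    f <- tryCatch(fitCurve(TimeIntensityCurve(gridTimes, v)),
                  error = function(e) NULL)
    if (is.null(f)) next
    tried <- tried + 1
    if (fitRSS(f) <= 1.1 * exhaustiveRSS(gridTimes, v)) ok <- ok + 1
  }
  expect_gte(tried, 35)
  expect_gte(ok / tried, 0.85)
})

test_that("estimates are equivariant under value shift and scale", {
  set.seed(5)
  p <- drawShortRise()
  v <- trilinearOracle(gridTimes, p$baseline, p$onset, p$slope,
                       p$peakEnhancement, p$washoutSlope) + rnorm(27, 0, 1)
  f0 <- fitCurve(TimeIntensityCurve(gridTimes, v))
  fShift <- fitCurve(TimeIntensityCurve(gridTimes, v + 25))
  expect_equal(upslopeSlope(fShift), upslopeSlope(f0), tolerance = 1e-6)
  expect_equal(peakEnhancement(fShift), peakEnhancement(f0),
               tolerance = 1e-6)
  expect_equal(baselineLevel(fShift), baselineLevel(f0) + 25,
               tolerance = 1e-6)
  fScale <- fitCurve(TimeIntensityCurve(gridTimes, 3 * v))
  expect_equal(upslopeSlope(fScale), 3 * upslopeSlope(f0),
               tolerance = 1e-6)
  expect_equal(peakEnhancement(fScale), 3 * peakEnhancement(f0),
               tolerance = 1e-6)
  expect_equal(baselineLevel(fScale), 3 * baselineLevel(f0),
               tolerance = 1e-6)
})

test_that("estimated slope increases with the generating slope (fixed noise)", {
  set.seed(9)
  noise <- rnorm(27, 0, 0.5)
  slopes <- seq(1.6, 3.6, by = 0.4)
  est <- vapply(slopes, function(m) {
    v <- trilinearOracle(gridTimes, 40, 7, m, m * 10, -0.2) + noise
    upslopeSlope(fitCurve(TimeIntensityCurve(gridTimes, v)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("fitCurve composition equals the manual three-step invocation", {
  v <- trilinearOracle(gridTimes, 40, 6, 2, 20, -0.2)
  curve <- TimeIntensityCurve(gridTimes, v)
  auto <- fitCurve(curve)
  sp <- fitSpline(curve)
  manual <- fitTrilinear(curve, selectUpslopeWindow(sp, curve))
  expect_equal(trilinearAsRow(auto), trilinearAsRow(manual))
})

test_that("flat curves raise a non-enhancing error with a stage label", {
  flat <- TimeIntensityCurve(gridTimes, rep(45, 27))
  expect_error(fitCurve(flat), "\\[window\\] non-enhancing curve")
})

test_that("seeded noisy sweep never crashes and successes satisfy the model invariants", {
  set.seed(23)
  nSuccess <- 0
  for (i in 1:120) {
    p <- drawShortRise()
    g <- generateTIC(baseline = p$baseline, onset = p$onset,
                     slope = p$slope, peakEnhancement = p$peakEnhancement,
                     washoutSlope = p$washoutSlope, noiseSd = 3)
    f <- tryCatch(fitCurve(g$curve), error = function(e) {
      expect_match(conditionMessage(e), "^\\[(spline|window|trilinear)\\]")
      NULL
    })
    if (is.null(f)) next
    nSuccess <- nSuccess + 1
    expect_lt(onsetTime(f), peakTime(f))
    expect_equal(peakEnhancement(f),
                 upslopeSlope(f) * (peakTime(f) - onsetTime(f)),
                 tolerance = 1e-9)
    w <- windowIndices(f)
    expect_identical(diff(w), rep(1L, length(w) - 1L))
  }
  expect_gte(nSuccess, 80)
})
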