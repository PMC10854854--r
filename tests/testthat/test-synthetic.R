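test_that("the default protocol reproduces the documented 27-point grid", {
  p <- defaultProtocol()
  expect_identical(protocolTimes(p), gridTimes)
  expect_true(all(diff(protocolTimes(p)) > 0))
})

test_that("noiseless generated curves are recovered by the fit within 1e-6", {
  g <- generateTIC(onset = 7, slope = 2, peakEnhancement = 20,
                   washoutSlope = -0.2, noiseSd = 0)
  f <- fitCurve(g$curve)
  expect_equal(upslopeSlope(f), g$truth$slope, tolerance = 1e-6)
  expect_equal(onsetTime(f), g$truth$onset, tolerance = 1e-6)
  expect_equal(peakEnhancement(f), g$truth$peakEnhancement,
               tolerance = 1e-6)
  ## generated values equal the oracle evaluation exactly
  expect_equal(ticValues(g$curve),
               trilinearOracle(gridTimes, 40, 7, 2, 20, -0.2))
})

test_that("generateTIC is deterministic given a seed and validates its geometry", {
  g1 <- generateTIC(noiseSd = 3, seed = 99)
  g2 <- generateTIC(noiseSd = 3, seed = 99)
  expect_identical(ticValues(g1$curve), ticValues(g2$curve))
  g3 <- generateTIC(noiseSd = 3, seed = 100)
  expect_false(identical(ticValues(g1$curve), ticValues(g3$curve)))
  expect_error(generateTIC(onset = -3), "onset")
  expect_error(generateTIC(onset = 100, slope = 2, peakEnhancement = 200),
               "outside")
  expect_error(generateTIC(slope = -1), "positive")
})

test_that("estimated slope is close to truth on average over seeded noisy draws", {
  set.seed(300)
  diffs <- c()
  for (i in 1:150) {
    g <- generateTIC(noiseSd = 3)   # generator defaults, cohort noise level
    f <- tryCatch(fitCurve(g$curve), error = function(e) NULL)
    if (!is.null(f)) diffs <- c(diffs, upslopeSlope(f) - g$truth$slope)
  }
  expect_gte(length(diffs), 135)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("the default cohort has the documented size and group structure", {
  coh <- generateCohort(seed = 42)
  expect_identical(nrow(coh$records), 92L)
  expect_identical(sum(coh$records$group == "hypovascular"), 72L)
  expect_identical(sum(coh$records$group == "isovascular"), 20L)
  expect_identical(coh$records$phenotype_visual,
                   as.integer(coh$records$group == "isovascular"))
  expect_true(all(coh$records$survival_days >= 0))
  expect_true(all(coh$records$event %in% 0:1))
  expect_length(coh$curves, 92L)
  expect_identical(roiName(coh$curves[["P001"]]$tumor), "tumor")
})

test_that("degenerate group distributions reproduce the default feature means", {
  tiny <- 1e-9
  hypo <- groupParams(2.0, tiny, 46.8, tiny, 35.3, tiny, 5L, 320)
  iso <- groupParams(2.9, tiny, 69.9, tiny, 12.0, tiny, 3L, 377)
  coh <- generateCohort(hypo, iso, noiseSd = 0, seed = 1)
  h <- coh$records[coh$records$group == "group", ]
  expect_equal(coh$records$true_slope[1:5], rep(2.0, 5), tolerance = 1e-6)
  expect_equal(coh$records$true_peak[1:5], rep(46.8, 5), tolerance = 1e-6)
  expect_equal(coh$records$true_delta[1:5], rep(35.3, 5), tolerance = 1e-6)
  expect_equal(coh$records$true_peak[6:8], rep(69.9, 3), tolerance = 1e-6)
  expect_equal(coh$records$true_pancreas_peak,
               coh$records$true_peak + coh$records$true_delta,
               tolerance = 1e-6)
})

test_that("cohort regeneration with the same seed is byte-identical on disk", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  for (d in c(d1, d2)) {
    coh <- generateCohort(seed = 7)
    writeCohortCSV(coh$records, file.path(d, "cohort.csv"))
    writeTICCSV(coh$curves[["P005"]]$tumor, file.path(d, "P005_tumor.csv"))
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.csv"))),
                   unname(tools::md5sum(file.path(d2, "cohort.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "P005_tumor.csv"))),
                   unname(tools::md5sum(file.path(d2, "P005_tumor.csv"))))
})

test_that("cohort feature means converge to the group parameters at large n", {
  hypo <- groupParams(2.0, 0.6, 46.8, 12.2, 35.3, 19.4, 1000L, 320,
                      label = "hypovascular")
  iso <- groupParams(2.9, 1.1, 69.9, 22.1, 12.0, 9.1, 500L, 377,
                     label = "isovascular")
  coh <- generateCohort(hypo, iso, noiseSd = 0, seed = 5)
  h <- coh$records[coh$records$group == "hypovascular", ]
  i <- coh$records[coh$records$group == "isovascular", ]
  expect_lt(abs(mean(h$true_slope) - 2.0) / 2.0, 0.02)
  expect_lt(abs(mean(h$true_peak) - 46.8) / 46.8, 0.02)
  expect_lt(abs(mean(i$true_peak) - 69.9) / 69.9, 0.02)
  expect_lt(abs(mean(i$true_delta) - 12.0) / 12.0, 0.1)
})

test_that("zero-noise zero-jitter phantom reproduces compartment curves exactly", {
  ph <- generatePhantom(noiseSd = 0, jitterVoxels = 0)
  tumor <- extractTIC(ph$series, ph$labels, ph$schema, "tumor")
  panc <- extractTIC(ph$series, ph$labels, ph$schema, "pancreas",
                     exclude = character(0))
  expect_equal(ticValues(tumor), ticValues(ph$truth$tumor))
  expect_equal(ticValues(panc), ticValues(ph$truth$pancreas))
  ## compartments are non-trivial
  expect_gt(voxelCount(tumor), 50L)
  expect_gt(diff(range(ticValues(tumor))), 40)
})

test_that("vessel exclusion leaves the tumor curve invariant to vessel enhancement", {
  vp10 <- list(baseline = 40, onset = 4, slope = 60,
               peakEnhancement = 600, washoutSlope = -4)
  phNo <- generatePhantom(noiseSd = 0, vesselRadius = 0)
  phHot <- generatePhantom(noiseSd = 0, vesselParams = vp10)
  ticNo <- extractTIC(phNo$series, phNo$labels, phNo$schema, "tumor")
  ticHot <- extractTIC(phHot$series, phHot$labels, phHot$schema, "tumor")
  expect_equal(ticValues(ticHot), ticValues(ticNo))
  ## sanity: vessel voxels exist and are hot in the second phantom
  expect_gt(sum(phHot$labels == 4L), 0L)
})

test_that("one-voxel rigid jitter perturbs the extracted curve by a bounded amount", {
  devs <- vapply(1:3, function(s) {
    ph <- generatePhantom(noiseSd = 0, jitterVoxels = 1, seed = s)
    tic <- extractTIC(ph$series, ph$labels, ph$schema, "tumor")
    max(abs(ticValues(tic) - ticValues(ph$truth$tumor)))
  }, numeric(1))
  expect_true(all(devs > 0))      # motion does perturb the measurement
  expect_true(all(devs < 60))     # bounded by the compartment-contrast scale
})

test_that("phantom validates its geometric preconditions", {
  expect_error(generatePhantom(shape = c(16, 40, 40)), "at least 32")
  expect_error(generatePhantom(tumorRadii = c(20, 20, 20)),
               "larger than pancreas")
})
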