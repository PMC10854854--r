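## small helper: series of given spatial shape with per-voxel values
## supplied by a function f(t-index, voxel-array)
makeSeries <- function(shape, nt, fill) {
  vols <- array(NA_real_, dim = c(shape, nt))
  for (k in seq_len(nt)) vols[, , , k] <- fill(k)
  DynamicSeries(vols, seq(0, by = 2, length.out = nt))
}

test_that("uniform phantom yields a constant curve with the right voxel count", {
  schema <- defaultLabelSchema()
  shape <- c(6L, 6L, 4L)
  labels <- array(schema@codes[["tumor"]], dim = shape)
  series <- makeSeries(shape, 10L, function(k) array(50, dim = shape))
  tic <- extractTIC(series, labels, schema, "tumor")
  expect_equal(ticValues(tic), rep(50, 10))
  expect_identical(voxelCount(tic), as.integer(prod(shape)))
  expect_identical(ticTimes(tic), acquisitionTimes(series))
})

test_that("excluded vessel voxels are removed before averaging", {
  schema <- defaultLabelSchema()
  shape <- c(10L, 1L, 1L)
  labels <- array(schema@codes[["tumor"]], dim = shape)
  labels[1:3] <- schema@codes[["abdominal_aorta"]]
  vals <- array(40, dim = shape); vals[1:3] <- 300
  series <- makeSeries(shape, 8L, function(k) vals)
  tic <- extractTIC(series, labels, schema, "tumor",
                    exclude = "abdominal_aorta")
  expect_equal(ticValues(tic), rep(40, 8))
  expect_identical(voxelCount(tic), 7L)
  ## the tumor default exclusion set covers vessels automatically
  ticDefault <- extractTIC(series, labels, schema, "tumor")
  expect_equal(ticValues(ticDefault), rep(40, 8))
})

test_that("extractTIC equals a brute-force voxel enumeration on a random phantom", {
  set.seed(4)
  schema <- defaultLabelSchema()
  shape <- c(7L, 5L, 3L)
  labels <- array(sample(c(0L, 1L, 2L, 4L), prod(shape), replace = TRUE),
                  dim = shape)
  nt <- 9L
  vols <- array(rnorm(prod(shape) * nt, 60, 25), dim = c(shape, nt))
  series <- DynamicSeries(vols, seq(0, 16, 2))
  for (roi in c("tumor", "pancreas")) {
    tic <- extractTIC(series, labels, schema, roi, exclude = character(0))
    expected <- numeric(nt)
    cnt <- 0L
    for (k in seq_len(nt)) {
      acc <- c()
      for (x in 1:shape[1]) for (y in 1:shape[2]) for (z in 1:shape[3])
        if (labels[x, y, z] == schema@codes[[roi]])
          acc <- c(acc, vols[x, y, z, k])
      expected[k] <- mean(acc)
      cnt <- length(acc)
    }
    expect_equal(ticValues(tic), expected)
    expect_identical(voxelCount(tic), cnt)
  }
})

test_that("adding excluded-label voxels of arbitrary value never changes the curve", {
  set.seed(8)
  schema <- defaultLabelSchema()
  shape <- c(6L, 6L, 3L)
  labels <- array(0L, dim = shape)
  labels[2:4, 2:4, 1:2] <- schema@codes[["tumor"]]
  vols <- array(rnorm(prod(shape) * 8, 50, 10), dim = c(shape, 8L))
  series <- DynamicSeries(vols, seq(0, 14, 2))
  base <- extractTIC(series, labels, schema, "tumor")
  ## turn some background voxels into a stent with wild values
  labels2 <- labels
  labels2[6, 6, ] <- schema@codes[["stent"]]
  vols2 <- vols
  vols2[6, 6, , ] <- 3000
  series2 <- DynamicSeries(vols2, seq(0, 14, 2))
  withVessel <- extractTIC(series2, labels2, schema, "tumor")
  expect_equal(ticValues(withVessel), ticValues(base))
})

test_that("empty ROI and shape mismatch raise errors", {
  schema <- defaultLabelSchema()
  shape <- c(6L, 6L, 3L)
  labels <- array(0L, dim = shape)
  series <- makeSeries(shape, 8L, function(k) array(0, dim = shape))
  expect_error(extractTIC(series, labels, schema, "tumor"), "empty")
  badLabels <- array(0L, dim = c(5L, 6L, 3L))
  expect_error(extractTIC(series, badLabels, schema, "tumor"),
               "shape")
  expect_error(extractTIC(series, labels, schema, "duodenum"),
               "not present")
})

test_that("segmentation report counts match a histogram oracle and flags problems", {
  set.seed(6)
  schema <- defaultLabelSchema()
  labels <- array(sample(0:11, 500, replace = TRUE), dim = c(10L, 10L, 5L))
  rep1 <- validateSegmentation(labels, schema)
  for (nm in names(schema@codes))
    expect_identical(rep1$counts[[nm]],
                     sum(labels == schema@codes[[nm]]))
  expect_length(rep1$flags, 0L)
  ## remove the tumor entirely: mandatory-label flag
  labels2 <- labels
  labels2[labels2 == schema@codes[["tumor"]]] <- 0L
  rep2 <- validateSegmentation(labels2, schema)
  expect_match(rep2$flags, "tumor", all = FALSE)
  ## tumor far away from the pancreas: disconnection flag
  labels3 <- array(0L, dim = c(40L, 10L, 5L))
  labels3[1:3, 1:3, 1:2] <- schema@codes[["pancreas"]]
  labels3[38:40, 8:10, 4:5] <- schema@codes[["tumor"]]
  rep3 <- validateSegmentation(labels3, schema)
  expect_match(rep3$flags, "disconnected", all = FALSE)
})

test_that("NIfTI round trip preserves volumes for 4D and per-timepoint layouts", {
  set.seed(2)
  shape <- c(8L, 7L, 5L)
  nt <- 8L
  vols <- array(rnorm(prod(shape) * nt, 40, 20), dim = c(shape, nt))
  series <- DynamicSeries(vols, seq(0, 14, 2))
  ## single 4D file
  p4 <- tempfile(fileext = ".nii.gz")
  writeNiftiVolume(series, p4)
  rt <- readDynamicSeries(p4, seq(0, 14, 2))
  expect_equal(rt@volumes, vols, tolerance = 1e-6, ignore_attr = TRUE)
  ## one 3D file per timepoint
  p3 <- vapply(seq_len(nt), function(k) {
    p <- tempfile(fileext = ".nii.gz")
    writeNiftiVolume(vols[, , , k], p)
    p
  }, character(1))
  rt3 <- readDynamicSeries(p3, seq(0, 14, 2))
  expect_equal(rt3@volumes, vols, tolerance = 1e-6, ignore_attr = TRUE)
  ## label map round trip
  lab <- array(sample(0:11, prod(shape), replace = TRUE), dim = shape)
  pl <- tempfile(fileext = ".nii.gz")
  writeNiftiVolume(lab, pl)
  expect_identical(readLabelMap(pl), lab)
})

test_that("label schema YAML round trip and validity checks", {
  schema <- defaultLabelSchema()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    codes = as.list(labelCodes(schema)),
    vessels = as.list(schema@vesselNames),
    stents = as.list(schema@stentNames)), path)
  rt <- readLabelSchema(path)
  expect_identical(labelCodes(rt), labelCodes(schema))
  expect_error(new("LabelSchema", codes = c(pancreas = 1L), vesselNames = character(0),
                   stentNames = character(0)), "tumor")
})
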