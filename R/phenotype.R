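#' Compute the three perfusion features of one patient
#'
#' @param tumorFit [TrilinearFit-class] of the tumor curve.
#' @param pancreasFit [TrilinearFit-class] of the pancreas parenchyma curve.
#' @return A [PerfusionFeatures-class]: tumor slope, tumor peak enhancement,
#'   and pancreas-minus-tumor peak-enhancement difference.
#' @examples
#' t <- c(seq(0, 24, 2), 35, seq(38, 62, 3), 70, 90, 120, 150)
#' v <- ifelse(t <= 6, 40, ifelse(t <= 16, 40 + 2 * (t - 6), 60 - 0.2 * (t - 16)))
#' f <- fitCurve(TimeIntensityCurve(t, v))
#' computeFeatures(f, f)   # identical fits: delta = 0
#' @export
computeFeatures <- function(tumorFit, pancreasFit) {
  stopifnot(is(tumorFit, "TrilinearFit"), is(pancreasFit, "TrilinearFit"))
  new("PerfusionFeatures",
      tumorSlope = tumorFit@upslopeSlope,
      tumorPeak = tumorFit@peakEnhancement,
      deltaPeak = pancreasFit@peakEnhancement - tumorFit@peakEnhancement)
}

#' Area under the ROC curve by the rank formula
#'
#' Midranks handle ties, so the value equals the pairwise concordance
#' probability (ties counted 1/2).
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels (1 = positive class).
#' @return AUC in \[0, 1\].
#' @export
scoreAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC curve points from scores: one threshold per distinct score
rocPoints <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- as.integer(labels)[o]
  tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
  keep <- c(diff(s) != 0, TRUE)   # last point per distinct threshold
  data.frame(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp[keep] / sum(l == 1L)),
    fpr = c(0, fp[keep] / sum(l == 0L))
  )
}

## stratified fold assignment: within each class, shuffle and deal
stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop(sprintf(
        "class %s has %d samples; cannot stratify into %d folds",
        cl, length(idx), folds))
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated logistic phenotype classifier
#'
#' Fits a ridge-penalized logistic regression of the visual vascular
#' phenotype on the three perfusion features, with stratified k-fold
#' cross-validation. Features are standardized inside each training fold;
#' the held-out samples of each fold are scored with the fold's model, an
#' ROC curve and AUC are computed per fold, and the mean per-fold AUC and
#' the pooled AUC over all out-of-fold scores are reported. A full-data
#' model provides the reported coefficients.
#'
#' @param features Data frame or matrix with columns \code{tumor_slope},
#'   \code{tumor_peak}, \code{delta_peak} (any numeric 3-column input is
#'   accepted in that order).
#' @param labels Binary vector, 1 = isovascular (the positive class),
#'   0 = hypovascular; at least 2 samples per class.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the stratified fold assignment.
#' @param lambda Fixed small ridge penalty (default 1e-3).
#' @param threshold Probability threshold for the predicted phenotype.
#' @return A [PhenotypeModel-class].
#' @examples
#' set.seed(1)
#' x <- data.frame(tumor_slope = rnorm(40), tumor_peak = rnorm(40),
#'                 delta_peak = c(rnorm(20, 3), rnorm(20, -3)))
#' y <- rep(c(0, 1), each = 20)
#' crossvalClassify(x, y, seed = 1)
#' @export
crossvalClassify <- function(features, labels, folds = 5L, seed = 1L,
                             lambda = 1e-3, threshold = 0.5) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (nrow(x) != length(labels))
    stop("features and labels differ in length")
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  folds <- as.integer(folds)

  assign <- stratifiedFolds(labels, folds, seed)
  scores <- numeric(length(labels))
  foldAUC <- numeric(folds)
  rocs <- vector("list", folds)

  fitRidge <- function(xtr, ytr) {
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(xtr, ctr, scl)
    ## glmnet warns about small classes on every fold of a small cohort;
    ## that is expected in cross-validation, so muffle just that warning
    fit <- withCallingHandlers(
      glmnet::glmnet(xs, ytr, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(fit = fit, center = ctr, scale = scl)
  }

  for (k in seq_len(folds)) {
    tr <- assign != k; te <- !tr
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L)
      stop("fold without both classes; cannot stratify")
    m <- fitRidge(x[tr, , drop = FALSE], labels[tr])
    xte <- scale(x[te, , drop = FALSE], m$center, m$scale)
    p <- as.numeric(stats::predict(m$fit, xte, type = "response"))
    scores[te] <- p
    foldAUC[k] <- scoreAUC(p, labels[te])
    rocs[[k]] <- rocPoints(p, labels[te])
  }

  full <- fitRidge(x, labels)
  cf <- as.numeric(stats::coef(full$fit))
  names(cf) <- c("(Intercept)", colnames(x))

  new("PhenotypeModel",
      coefficients = cf, center = full$center, scale = full$scale,
      folds = assign, foldAUC = foldAUC, meanAUC = mean(foldAUC),
      pooledAUC = scoreAUC(scores, labels), roc = rocs,
      scores = scores, labels = labels,
      threshold = threshold, lambda = lambda, seed = as.integer(seed))
}

#' Predicted phenotype labels of a cross-validated model
#'
#' Out-of-fold predicted probabilities thresholded at the model's decision
#' threshold (1 = predicted isovascular).
#'
#' @param model A [PhenotypeModel-class].
#' @return Integer vector of 0/1 predictions.
#' @export
predictedPhenotype <- function(model) {
  stopifnot(is(model, "PhenotypeModel"))
  as.integer(model@scores >= model@threshold)
}

#' Mann-Whitney U test between two groups
#'
#' U counts the pairs where the first group's value exceeds the second's
#' (ties count 1/2), so U = 0 means every value of the first group lies
#' below the second. Small samples without ties use the exact null
#' distribution; small tied samples are handled by full enumeration of all
#' group assignments; otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Numeric samples of the two groups (non-empty).
#' @param exactMax Per-group size up to which the exact distribution is
#'   used (default 20).
#' @param enumMax Maximum number of label assignments enumerated in the
#'   tied exact case.
#' @return List with \code{U} (first-group convention), \code{p}
#'   (two-sided) and \code{method}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, exactMax = 20L, enumMax = 200000L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(pooled) > 0L
  small <- n1 <= exactMax && n2 <= exactMax

  if (small && !ties) {
    p <- if (U > mu) {
      2 * (1 - stats::pwilcox(U - 1, n1, n2))
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  if (small && choose(n1 + n2, n1) <= enumMax) {
    ## exact permutation null by enumeration of all group assignments
    idx <- utils::combn(n1 + n2, n1)
    Uall <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  ## normal approximation with tie correction and continuity correction
  n <- n1 + n2
  tj <- table(pooled)
  tieTerm <- sum(tj^3 - tj) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Group comparison of one perfusion feature
#'
#' Mann-Whitney U test of one feature between the two phenotype groups,
#' with group means and standard deviations.
#'
#' @param features Data frame containing the feature column.
#' @param labels Binary group labels (1 = isovascular).
#' @param feature Column name to test.
#' @return List with group summaries (\code{mean0}, \code{sd0},
#'   \code{mean1}, \code{sd1}; group 0 first), \code{U} (group-0
#'   convention), \code{p} and \code{method}.
#' @export
featureGroupTest <- function(features, labels, feature) {
  if (!feature %in% colnames(features))
    stop(sprintf("feature '%s' not found", feature))
  labels <- as.integer(labels)
  v0 <- features[[feature]][labels == 0L]
  v1 <- features[[feature]][labels == 1L]
  if (length(v0) == 0L || length(v1) == 0L)
    stop("both phenotype groups must be non-empty")
  tst <- mannWhitneyU(v0, v1)
  c(list(feature = feature,
         mean0 = mean(v0), sd0 = stats::sd(v0), n0 = length(v0),
         mean1 = mean(v1), sd1 = stats::sd(v1), n1 = length(v1)),
    tst)
}
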