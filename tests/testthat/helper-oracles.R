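## Independent oracles and shared fixtures. Everything here is written
## deliberately naively (explicit loops, lm.fit enumeration) so it shares
## no code path with the package implementation it checks.

## The default acquisition grid, written out literally.
gridTimes <- c(0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24,
               35, 38, 41, 44, 47, 50, 53, 56, 59, 62, 70, 90, 120, 150)

## Exact trilinear evaluation, independent of the package's generator.
trilinearOracle <- function(t, baseline, onset, slope, peakEnh, washout) {
  peakT <- onset + peakEnh / slope
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    out[i] <- if (t[i] <= onset) baseline
    else if (t[i] <= peakT) baseline + slope * (t[i] - onset)
    else baseline + peakEnh + washout * (t[i] - peakT)
  }
  out
}

## Exhaustive-partition least-squares oracle: minimum total rss over all
## (pre | window | post) partitions with >= 2 points per segment.
exhaustiveRSS <- function(t, y) {
  n <- length(t)
  best <- Inf
  for (i in 3:(n - 4)) {
    for (j in (i + 1):(n - 2)) {
      pre <- 1:(i - 1); win <- i:j; post <- (j + 1):n
      rss <- sum((y[pre] - mean(y[pre]))^2) +
        sum(stats::lm.fit(cbind(1, t[win]), y[win])$residuals^2) +
        sum(stats::lm.fit(cbind(1, t[post]), y[post])$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

## Benchmark curve family: rises spanning exactly five dense-grid samples
## (upslope identifiable and fully covered by the five-point window).
drawShortRise <- function() {
  a <- sample(3:5, 1)
  onset <- 2 * a + stats::runif(1, 0.5, 1.5)
  dur <- stats::runif(1, 9.6, 10.4)
  slope <- stats::runif(1, 1.5, 3.5)
  list(baseline = stats::runif(1, 35, 45), onset = onset, slope = slope,
       peakEnhancement = slope * dur,
       washoutSlope = stats::runif(1, -0.4, -0.1))
}

## Pairwise-concordance AUC oracle (ties count one half).
concordanceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Fit the default cohort (seed as given) through the full two-step
## pipeline and return per-patient measured + true features.
fitDefaultCohort <- function(seed, noiseSd = 3) {
  coh <- generateCohort(noiseSd = noiseSd, seed = seed)
  rec <- coh$records
  meas <- matrix(NA_real_, nrow(rec), 3,
                 dimnames = list(NULL, c("slope", "peak", "delta")))
  for (i in seq_len(nrow(rec))) {
    id <- rec$patient_id[i]
    ok <- tryCatch({
      ft <- fitCurve(coh$curves[[id]]$tumor)
      fp <- fitCurve(coh$curves[[id]]$pancreas)
      meas[i, ] <- c(upslopeSlope(ft), peakEnhancement(ft),
                     peakEnhancement(fp) - peakEnhancement(ft))
      TRUE
    }, error = function(e) FALSE)
  }
  cbind(rec, as.data.frame(meas))
}
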