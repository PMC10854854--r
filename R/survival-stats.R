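#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function under right censoring.
#' The median is the smallest observed time at which the estimated
#' survival drops to 0.5 or below; when the curve never reaches 0.5 the
#' median is undefined and flagged.
#'
#' @param times Follow-up times (days), non-negative.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return List of class \code{"kmEstimate"}: \code{table} (one row per
#'   distinct event/censoring time: time, nRisk, nEvent, nCensor, surv),
#'   \code{median}, \code{medianReached}, \code{n}.
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$table$surv     # 0.75 0.50 0.25 0.00
#' km$median         # 2
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("need at least one record")
  if (any(times < 0)) stop("negative survival times are not allowed")
  events <- as.integer(events)
  if (any(!events %in% c(0L, 1L))) stop("events must be 0/1")
  if (length(events) != length(times))
    stop("times and events differ in length")

  ut <- sort(unique(times))
  nRisk <- nEvent <- nCensor <- integer(length(ut))
  for (i in seq_along(ut)) {
    nRisk[i] <- sum(times >= ut[i])
    nEvent[i] <- sum(times == ut[i] & events == 1L)
    nCensor[i] <- sum(times == ut[i] & events == 0L)
  }
  surv <- cumprod(1 - nEvent / nRisk)
  tab <- data.frame(time = ut, nRisk = nRisk, nEvent = nEvent,
                    nCensor = nCensor, surv = surv)
  reached <- any(surv <= 0.5)
  med <- if (reached) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(list(table = tab, median = med, medianReached = reached,
                 n = length(times)),
            class = "kmEstimate")
}

#' @export
print.kmEstimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d events\n",
              x$n, sum(x$table$nEvent)))
  if (x$medianReached)
    cat(sprintf("  median survival: %g\n", x$median))
  else
    cat("  median survival: not reached\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times, with the hypergeometric variance (tie-corrected), referred
#' to a 1-df chi-square distribution.
#'
#' @param timesA,eventsA Follow-up times and event indicators of group A.
#' @param timesB,eventsB Same for group B.
#' @return List with \code{chisq}, \code{p}, \code{observed} and
#'   \code{expected} (group A), and \code{nEvents}.
#' @examples
#' logrankTest(c(2, 4, 6), c(1, 1, 0), c(1, 3, 5), c(1, 1, 1))
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0L || length(timesB) == 0L)
    stop("both groups must be non-empty")
  if (any(c(timesA, timesB) < 0)) stop("negative survival times")
  eventsA <- as.integer(eventsA); eventsB <- as.integer(eventsB)
  dTot <- sum(eventsA) + sum(eventsB)
  if (dTot == 0L) stop("log-rank test needs at least one event")

  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  group <- rep(c(1L, 2L), c(length(timesA), length(timesB)))
  evTimes <- sort(unique(times[events == 1L]))

  O <- E <- V <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == 1L)
    d <- sum(times == t & events == 1L)
    d1 <- sum(times == t & events == 1L & group == 1L)
    O <- O + d1
    E <- E + n1 * d / n
    if (n > 1)
      V <- V + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E, nEvents = dTot)
}
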