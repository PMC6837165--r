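#' Build an event table from right-censored follow-up
#'
#' Collapses per-subject follow-up into the ordered distinct death
#' times, the deaths at each, and the number of subjects known to be at
#' risk entering each time. A subject censored at time t is still at
#' risk at t (deaths are counted before censorings at tied times, the
#' standard convention), but never contributes a death.
#'
#' @param durations numeric vector of follow-up times in days (>= 0).
#' @param events logical/0-1 vector; TRUE/1 = death observed at
#'   \code{durations}, FALSE/0 = right-censored there.
#' @return An \linkS4class{EventTable}. All-censored input yields an
#'   empty table.
#' @examples
#' buildEventTable(c(2, 4, 4, 6), c(1, 1, 0, 1))
#' @export
buildEventTable <- function(durations, events) {
  durations <- as.numeric(durations)
  events <- as.logical(events)
  if (length(durations) != length(events))
    stop("durations and events must have equal length")
  if (anyNA(durations) || anyNA(events)) stop("missing values not allowed")
  if (any(durations < 0)) stop("durations must be >= 0")
  dt <- sort(unique(durations[events]))
  if (!length(dt))
    return(methods::new("EventTable", times = numeric(0),
                        deaths = integer(0), atRisk = integer(0)))
  deaths <- vapply(dt, function(t) sum(events & durations == t), integer(1))
  atRisk <- vapply(dt, function(t) sum(durations >= t), integer(1))
  methods::new("EventTable", times = dt, deaths = deaths, atRisk = atRisk)
}

#' @rdname EventTable-accessors
#' @export
setMethod("eventTimes", "EventTable", function(x) x@times)

#' Accessors for EventTable
#'
#' @param x an \linkS4class{EventTable}.
#' @return numeric/integer vectors over the distinct death times.
#' @name EventTable-accessors
#' @aliases eventTimes nDeaths nAtRisk
NULL

#' @rdname EventTable-accessors
#' @export
setMethod("nDeaths", "EventTable", function(x) x@deaths)

#' @rdname EventTable-accessors
#' @export
setMethod("nAtRisk", "EventTable", function(x) x@atRisk)

setMethod("show", "EventTable", function(object) {
  cat("EventTable with", length(object@times), "distinct death times\n")
  if (length(object@times))
    print(data.frame(time = object@times, deaths = object@deaths,
                     at_risk = object@atRisk), row.names = FALSE)
})

#' Kaplan-Meier survival estimate
#'
#' The product-limit estimator: S(t) is the running product of
#' (1 - deaths_k / atRisk_k) over death times t_k <= t. The curve is 1
#' before the first death and constant between death times.
#'
#' @param table an \linkS4class{EventTable}.
#' @return A \linkS4class{SurvivalCurve}.
#' @examples
#' kmEstimate(buildEventTable(c(2, 4, 4, 6), c(1, 1, 0, 1)))
#' @export
kmEstimate <- function(table) {
  stopifnot(methods::is(table, "EventTable"))
  methods::new("SurvivalCurve", times = table@times,
               estimate = cumprod(1 - table@deaths / table@atRisk),
               atRisk = table@atRisk, deaths = table@deaths)
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' The running sum of deaths_k / atRisk_k over death times t_k <= t; 0
#' before the first death. Always bounded above by -log of the
#' Kaplan-Meier estimate at the same times.
#'
#' @param table an \linkS4class{EventTable}.
#' @return A \linkS4class{HazardCurve}.
#' @export
naEstimate <- function(table) {
  stopifnot(methods::is(table, "EventTable"))
  methods::new("HazardCurve", times = table@times,
               estimate = cumsum(table@deaths / table@atRisk),
               atRisk = table@atRisk, deaths = table@deaths)
}

#' Evaluate a step curve at arbitrary times
#'
#' @param x a \linkS4class{SurvivalCurve} or \linkS4class{HazardCurve}.
#' @param t numeric times.
#' @return The estimate at each \code{t} (right-continuous step
#'   function; 1 for survival / 0 for hazard before the first death).
#' @name curve-evaluation
#' @aliases curveAt
NULL

.curveAt <- function(x, t, before) {
  idx <- findInterval(t, x@times)
  out <- c(before, x@estimate)[idx + 1L]
  out
}

#' @rdname curve-evaluation
#' @export
setMethod("curveAt", "SurvivalCurve", function(x, t) .curveAt(x, t, 1))

#' @rdname curve-evaluation
#' @export
setMethod("curveAt", "HazardCurve", function(x, t) .curveAt(x, t, 0))

setMethod("show", "SurvivalCurve", function(object) {
  cat("Kaplan-Meier curve over", length(object@times), "death times;",
      "final S =", if (length(object@estimate))
        round(object@estimate[length(object@estimate)], 4) else 1, "\n")
})

setMethod("show", "HazardCurve", function(object) {
  cat("Nelson-Aalen curve over", length(object@times), "death times;",
      "final cumulative hazard =", if (length(object@estimate))
        round(object@estimate[length(object@estimate)], 4) else 0, "\n")
})

#' Export a curve as a plain table
#'
#' @param curve a \linkS4class{SurvivalCurve} or \linkS4class{HazardCurve}.
#' @param file optional path; when given, written as TSV.
#' @return data.frame with columns time, estimate, at_risk, deaths.
#' @export
curveTable <- function(curve, file = NULL) {
  df <- data.frame(time = curve@times, estimate = curve@estimate,
                   at_risk = curve@atRisk, deaths = curve@deaths)
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

## Per-event-time observed/expected bookkeeping shared by the log-rank
## test and the O/E hazard ratio.
.logrankTerms <- function(durA, evA, durB, evB) {
  evA <- as.logical(evA); evB <- as.logical(evB)
  dt <- sort(unique(c(durA[evA], durB[evB])))
  if (!length(dt))
    return(list(OA = 0, OB = sum(evB), EA = 0, EB = 0, V = 0, nTimes = 0))
  sdA <- sort(durA); sdB <- sort(durB)
  ## at risk entering t = N - #{durations < t}
  nA <- length(durA) - findInterval(dt, sdA, left.open = TRUE)
  nB <- length(durB) - findInterval(dt, sdB, left.open = TRUE)
  dA <- tabulate(match(durA[evA], dt), nbins = length(dt))
  dB <- tabulate(match(durB[evB], dt), nbins = length(dt))
  n <- nA + nB
  d <- dA + dB
  eA <- d * nA / n
  eB <- d * nB / n
  v <- ifelse(n > 1, d * (nA / n) * (nB / n) * (n - d) / (n - 1), 0)
  list(OA = sum(dA), OB = sum(dB), EA = sum(eA), EB = sum(eB),
       V = sum(v), nTimes = length(dt))
}

#' Two-sample log-rank test
#'
#' At each pooled death time the expected deaths in a group are the
#' total deaths times that group's at-risk fraction; the variance term
#' is hypergeometric. Z = (O_A - E_A) / sqrt(sum Var); the two-sided
#' p-value comes from chi-square with 1 df on Z^2. Swapping the groups
#' negates Z and leaves p unchanged.
#'
#' @param durationsA,eventsA follow-up and death indicators, group A.
#' @param durationsB,eventsB follow-up and death indicators, group B.
#' @return A \linkS4class{LogRankResult}. With no events (or zero
#'   variance) the result is flagged degenerate with Z = 0, p = 1.
#' @examples
#' logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrankTest <- function(durationsA, eventsA, durationsB, eventsB) {
  tm <- .logrankTerms(durationsA, eventsA, durationsB, eventsB)
  if (tm$nTimes == 0 || tm$V <= 0)
    return(methods::new("LogRankResult", z = 0, p.value = 1,
                        observed = c(A = tm$OA, B = tm$OB),
                        expected = c(A = tm$EA, B = tm$EB),
                        variance = tm$V, degenerate = TRUE))
  z <- (tm$OA - tm$EA) / sqrt(tm$V)
  methods::new("LogRankResult", z = z,
               p.value = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
               observed = c(A = tm$OA, B = tm$OB),
               expected = c(A = tm$EA, B = tm$EB),
               variance = tm$V, degenerate = FALSE)
}

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank test: Z = %.4f, p = %.4g%s\n", object@z,
              object@p.value,
              if (object@degenerate) " (degenerate)" else ""))
  cat(sprintf("  observed A/B: %g/%g, expected A/B: %.3f/%.3f\n",
              object@observed[1], object@observed[2],
              object@expected[1], object@expected[2]))
})

#' Observed/expected (Pike) hazard ratio
#'
#' HR = (O_A / E_A) / (O_B / E_B) with observed and expected death
#' counts accumulated exactly as in the log-rank test; equals 1 when the
#' groups have identical event experience. With the analysis convention
#' used here, group A is the high-expression group, so HR > 1 means
#' high expression carries the higher death rate.
#'
#' @inheritParams logrankTest
#' @return A single number, or NA (with a warning) when either group has
#'   zero expected events.
#' @examples
#' hazardRatio(c(1, 2), c(1, 1), c(3, 4), c(1, 1))  # 3.8
#' @export
hazardRatio <- function(durationsA, eventsA, durationsB, eventsB) {
  if (!length(durationsA) || !length(durationsB))
    stop("both groups must contain at least one subject")
  tm <- .logrankTerms(durationsA, eventsA, durationsB, eventsB)
  if (tm$EA <= 0 || tm$EB <= 0 || tm$OB == 0) {
    warning("hazard ratio undefined (a group has zero expected or observed events)")
    return(NA_real_)
  }
  (tm$OA / tm$EA) / (tm$OB / tm$EB)
}

#' Median dichotomization of a marker
#'
#' Samples at or below the median go to the low group, samples strictly
#' above it to the high group. When every value is identical the split
#' is degenerate (empty high group) and flagged.
#'
#' @param values numeric vector of per-sample expression (>= 2 values).
#' @param ids optional sample identifiers (defaults to names or index).
#' @return A list with \code{low}, \code{high} (ids), \code{median} and
#'   \code{degenerate}.
#' @examples
#' medianSplit(c(s1 = 1, s2 = 2, s3 = 3))
#' @export
medianSplit <- function(values, ids = NULL) {
  if (length(values) < 2) stop("need at least 2 samples to split")
  if (is.null(ids))
    ids <- if (!is.null(names(values))) names(values) else seq_along(values)
  med <- stats::median(values)
  high <- ids[values > med]
  list(low = ids[values <= med], high = high, median = med,
       degenerate = length(high) == 0)
}

#' Expression prevalence filter
#'
#' Keeps miRNAs whose fraction of non-zero expression values, computed
#' over the samples entering the analysis, is at least
#' \code{minNonzeroFraction} (boundary inclusive).
#'
#' @param cohort a \linkS4class{MirnaCohort} or a plain matrix
#'   (miRNAs x samples).
#' @param minNonzeroFraction threshold in (0, 1], default 0.6.
#' @return The input with filtered rows (same class as given).
#' @export
filterMirnas <- function(cohort, minNonzeroFraction = 0.6) {
  if (minNonzeroFraction <= 0 || minNonzeroFraction > 1)
    stop("minNonzeroFraction must be in (0, 1]")
  m <- if (methods::is(cohort, "MirnaCohort")) rpm(cohort) else as.matrix(cohort)
  keep <- rowMeans(m != 0) >= minNonzeroFraction
  cohort[keep, , drop = FALSE]
}

#' Extract per-subject follow-up from clinical annotation
#'
#' Encodes the censoring convention: an alive patient is censored at the
#' last follow-up day, a dead patient contributes an event at the day of
#' death.
#'
#' @param clinical data.frame with \code{days} and \code{status}.
#' @return list(durations, events).
#' @keywords internal
followUp <- function(clinical) {
  list(durations = as.numeric(clinical$days),
       events = clinical$status == "dead")
}
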