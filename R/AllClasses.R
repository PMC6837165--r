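#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MirnaCohort: expression plus clinical follow-up in one container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' miRNA expression matrix (features in rows, samples in columns; reads
#' per million) together with per-sample clinical annotation in
#' \code{colData}: \code{subtype} (one of LA, LB, HER2E, BL, Control),
#' \code{status} ("alive"/"dead"), \code{days} (days to death or last
#' follow-up), \code{age}, and optionally \code{stage} (AJCC stage,
#' possibly with sub-stage letters).
#'
#' @slot ... inherited from SummarizedExperiment.
#' @seealso [MirnaCohort()], [generateCohort()]
#' @exportClass MirnaCohort
setClass("MirnaCohort", contains = "SummarizedExperiment")

setValidity("MirnaCohort", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subtype", "status", "days", "age")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (!"rpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rpm' is required")
  else if (any(SummarizedExperiment::assay(object, "rpm") < 0, na.rm = TRUE))
    msg <- c(msg, "expression (rpm) must be non-negative")
  if ("days" %in% colnames(cd) && any(cd$days < 0, na.rm = TRUE))
    msg <- c(msg, "days must be >= 0")
  if ("status" %in% colnames(cd) &&
      !all(cd$status %in% c("alive", "dead")))
    msg <- c(msg, "status must be 'alive' or 'dead'")
  if (length(msg)) msg else TRUE
})

#' Event table: the substrate of the nonparametric survival estimators
#'
#' Ordered distinct event (death) times with the number of deaths and
#' the number of subjects known to be at risk entering each time.
#' Censored subjects contribute to the at-risk counts up to and
#' including their censoring time but never to the death counts.
#'
#' @slot times numeric, strictly increasing distinct death times (days).
#' @slot deaths integer, deaths at each time (>= 1).
#' @slot atRisk integer, subjects at risk entering each time
#'   (non-increasing; \code{deaths <= atRisk}).
#' @seealso [buildEventTable()], [kmEstimate()], [naEstimate()]
#' @exportClass EventTable
setClass("EventTable",
  representation(times = "numeric", deaths = "integer", atRisk = "integer"))

setValidity("EventTable", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@deaths) != n || length(object@atRisk) != n)
    msg <- c(msg, "times, deaths and atRisk must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (n > 0) {
    if (any(object@deaths < 1)) msg <- c(msg, "deaths must be >= 1 at event times")
    if (any(object@deaths > object@atRisk))
      msg <- c(msg, "deaths cannot exceed the at-risk count")
    if (n > 1 && any(diff(object@atRisk) > 0))
      msg <- c(msg, "atRisk must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Step-function survival / cumulative-hazard curves
#'
#' \code{SurvivalCurve} holds the Kaplan-Meier estimate: 1 before the
#' first death time, non-increasing, constant between death times.
#' \code{HazardCurve} holds the Nelson-Aalen cumulative hazard: 0 before
#' the first death time, non-decreasing.
#'
#' @slot times numeric, death times at which the step function jumps.
#' @slot estimate numeric, the estimate immediately after each time.
#' @slot atRisk,deaths integer, carried over from the event table so the
#'   curve can be exported for external plotting.
#' @rdname survival-curves
#' @exportClass SurvivalCurve
setClass("SurvivalCurve",
  representation(times = "numeric", estimate = "numeric",
                 atRisk = "integer", deaths = "integer"))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (any(object@estimate < -1e-12 | object@estimate > 1 + 1e-12))
    msg <- c(msg, "survival estimates must lie in [0, 1]")
  if (length(object@estimate) > 1 && any(diff(object@estimate) > 1e-12))
    msg <- c(msg, "survival estimate must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname survival-curves
#' @exportClass HazardCurve
setClass("HazardCurve",
  representation(times = "numeric", estimate = "numeric",
                 atRisk = "integer", deaths = "integer"))

setValidity("HazardCurve", function(object) {
  msg <- character()
  if (any(object@estimate < -1e-12))
    msg <- c(msg, "cumulative hazard must be >= 0")
  if (length(object@estimate) > 1 && any(diff(object@estimate) < -1e-12))
    msg <- c(msg, "cumulative hazard must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Two-sample log-rank test result
#'
#' Observed and expected death counts per group accumulated over the
#' pooled event times, the hypergeometric variance sum, the signed
#' normal statistic Z (positive when group A experiences more deaths
#' than expected) and the two-sided p-value from chi-square(1) on Z^2.
#'
#' @slot z signed test statistic.
#' @slot p.value two-sided p-value in [0, 1].
#' @slot observed,expected length-2 numeric, per-group totals (A, B).
#' @slot variance the summed variance term.
#' @slot degenerate TRUE when no events or zero variance (Z = 0, p = 1).
#' @seealso [logrankTest()], [hazardRatio()]
#' @exportClass LogRankResult
setClass("LogRankResult",
  representation(z = "numeric", p.value = "numeric",
                 observed = "numeric", expected = "numeric",
                 variance = "numeric", degenerate = "logical"))

setValidity("LogRankResult", function(object) {
  if (object@p.value < 0 || object@p.value > 1) "p.value must be in [0, 1]" else TRUE
})

#' Star sets from top-k list intersection
#'
#' Four-star miRNAs appear in the top-k survival ranking of every
#' subtype; one-star miRNAs appear in exactly one subtype's list.
#' Two-/three-star counts are retained for reporting.
#'
#' @slot fourStar character vector.
#' @slot oneStar named list (one character vector per subtype).
#' @slot multiStar named integer vector of list-membership multiplicities
#'   (counts of miRNAs present in exactly 1..S lists).
#' @slot k the top-k used.
#' @seealso [starClassify()]
#' @exportClass StarSets
setClass("StarSets",
  representation(fourStar = "character", oneStar = "list",
                 multiStar = "integer", k = "integer"))

setValidity("StarSets", function(object) {
  msg <- character()
  for (s in names(object@oneStar))
    if (length(intersect(object@fourStar, object@oneStar[[s]])))
      msg <- c(msg, sprintf("four-star and one-star[%s] sets overlap", s))
  if (length(msg)) msg else TRUE
})

#' Directed regulatory relation tables
#'
#' Three deduplicated edge tables over a shared uppercase symbol
#' namespace: miRNA -> target gene, TF -> target miRNA, TF -> target
#' gene. The same symbol may act as gene and TF, which is what makes
#' regulatory circuits detectable.
#'
#' @slot mirnaTargets data.frame with columns mirna, gene.
#' @slot tfMirna data.frame with columns tf, mirna.
#' @slot tfGene data.frame with columns tf, gene.
#' @seealso [loadInteractionDB()], [generateInteractionDB()], [refineNetwork()]
#' @exportClass InteractionDB
setClass("InteractionDB",
  representation(mirnaTargets = "data.frame", tfMirna = "data.frame",
                 tfGene = "data.frame"))

setValidity("InteractionDB", function(object) {
  msg <- character()
  if (!identical(colnames(object@mirnaTargets), c("mirna", "gene")))
    msg <- c(msg, "mirnaTargets must have columns mirna, gene")
  if (!identical(colnames(object@tfMirna), c("tf", "mirna")))
    msg <- c(msg, "tfMirna must have columns tf, mirna")
  if (!identical(colnames(object@tfGene), c("tf", "gene")))
    msg <- c(msg, "tfGene must have columns tf, gene")
  for (nm in c("mirnaTargets", "tfMirna", "tfGene")) {
    tb <- slot(object, nm)
    if (anyDuplicated(tb)) msg <- c(msg, paste(nm, "contains duplicate edges"))
  }
  if (length(msg)) msg else TRUE
})

#' Snapshots of the 11-step miRNA/gene/TF refinement
#'
#' @slot steps named list step1..step11 of character vectors (gene, TF or
#'   miRNA symbols depending on the step).
#' @slot mirnas,genes,tfs the final refined sets (steps 11, 9 and 10).
#' @slot corrReport data.frame of the per-pair expression correlations
#'   examined at the anti-correlation step (mirna, gene, r, kept).
#' @seealso [refineNetwork()], [detectCircuits()]
#' @exportClass RefinedSets
setClass("RefinedSets",
  representation(steps = "list", mirnas = "character", genes = "character",
                 tfs = "character", corrReport = "data.frame"))

#' Ground-truth manifest of a synthetic cohort
#'
#' Records what was planted so that recovery can be scored: the
#' four-star and per-subtype one-star effect miRNAs, the
#' miRNA-gene pairs generated with anti-correlated mRNA, the planted
#' miRNA/TF regulatory circuits, and the miRNAs given a stage-II
#' expression shift.
#'
#' @slot fourStar character.
#' @slot oneStar named list per subtype.
#' @slot anticorrelatedPairs data.frame (mirna, gene, r).
#' @slot plantedCircuits data.frame (mirna, symbol).
#' @slot stageShiftIds character.
#' @seealso [generateCohort()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(fourStar = "character", oneStar = "list",
                 anticorrelatedPairs = "data.frame",
                 plantedCircuits = "data.frame",
                 stageShiftIds = "character"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  for (s in names(object@oneStar))
    if (length(intersect(object@fourStar, object@oneStar[[s]])))
      msg <- c(msg, "fourStar must be disjoint from every oneStar list")
  if (length(msg)) msg else TRUE
})
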