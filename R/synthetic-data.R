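## Symbol pools for planted regulatory circuits: transcription factors
## whose genes are themselves miRNA targets, plus companion target genes.
.circuitTfPool <- c("TP53", "ESR1", "BRCA1", "MYC", "HIF1A", "NFKB1",
                    "E2F1", "E2F3", "STAT3", "SP1")
.circuitGenePool <- c("CCND1", "CDKN1A", "BCL2", "VEGFA", "EGFR",
                      "PTEN", "CDH1", "NOTCH1", "RB1", "AKT1")

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the structure of a subtyped breast-cancer miRNA-seq
#' survival cohort: four tumor subtypes (86/39/24/41) plus 41 controls,
#' 587 miRNAs of which 44 carry a survival effect in every subtype
#' (four-star) and 12 per subtype carry a subtype-restricted effect
#' (one-star). Expression is log-normal RPM; planted miRNAs take a mean
#' shift tied to a per-patient latent risk indicator, and survival times
#' are exponential with hazard \code{baselineHazard * effectHr^risk},
#' administratively censored at \code{censorHorizon} days with
#' additional uniform dropout.
#'
#' @param subtypeSizes named integer vector of cohort sizes; must
#'   include a \code{Control} entry.
#' @param nMirnas total number of miRNAs.
#' @param nFourStar number of planted pan-subtype effect miRNAs.
#' @param nOneStarPerSubtype planted subtype-specific effect miRNAs per
#'   tumor subtype.
#' @param effectHr target hazard ratio (> 0) between the high- and
#'   low-expression halves of the pooled subtype+control cohort for
#'   planted miRNAs; 1 plants no survival effect. For subtypes smaller
#'   than half the pooled cohort the latent per-patient multiplier is
#'   raised to compensate for the controls that unavoidably enter the
#'   high-expression arm.
#' @param baselineHazard baseline death hazard per day.
#' @param censorHorizon administrative censoring horizon in days.
#' @param dropoutProb probability that a patient instead drops out
#'   uniformly within the follow-up window.
#' @param zeroFractionNull probability that a null miRNA's expression
#'   value is exactly zero (sequencing dropout).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @param riskDelta log2-scale expression shift (in units of
#'   \code{sdLog}) separating high- from low-risk patients for planted
#'   miRNAs.
#' @param tumorOffset log2-scale shift of four-star miRNAs in all tumors
#'   relative to controls.
#' @param subtypeOffset log2-scale shift of one-star miRNAs in their own
#'   subtype relative to everything else.
#' @param baseLogMean,sdLog log2-scale mean and standard deviation of
#'   null expression.
#' @param nCircuits number of planted miRNA-gene-TF regulatory circuits
#'   (drawn from the four-star miRNAs; at most 10).
#' @param nStageShift number of planted stage-II-shifted miRNAs (drawn
#'   from the four-star set).
#' @return A validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(subtypeSizes = c(LA = 86, LB = 39, HER2E = 24,
                                          BL = 41, Control = 41),
                         nMirnas = 587, nFourStar = 44,
                         nOneStarPerSubtype = 12, effectHr = 3,
                         baselineHazard = 2e-4, censorHorizon = 3000,
                         zeroFractionNull = 0.2, seed = 1,
                         dropoutProb = 0.3,
                         riskDelta = 3, tumorOffset = 1.5,
                         subtypeOffset = 1.5, baseLogMean = 5, sdLog = 1,
                         nCircuits = 5, nStageShift = 8) {
  cfg <- list(subtypeSizes = subtypeSizes, nMirnas = as.integer(nMirnas),
              nFourStar = as.integer(nFourStar),
              nOneStarPerSubtype = as.integer(nOneStarPerSubtype),
              effectHr = effectHr, baselineHazard = baselineHazard,
              censorHorizon = censorHorizon,
              zeroFractionNull = zeroFractionNull, seed = as.integer(seed),
              dropoutProb = dropoutProb, riskDelta = riskDelta, tumorOffset = tumorOffset,
              subtypeOffset = subtypeOffset, baseLogMean = baseLogMean,
              sdLog = sdLog, nCircuits = as.integer(nCircuits),
              nStageShift = as.integer(nStageShift))
  if (!"Control" %in% names(cfg$subtypeSizes))
    stop("subtypeSizes must contain a 'Control' entry")
  if (any(cfg$subtypeSizes < 0) || cfg$nMirnas <= 0)
    stop("configuration error: sizes must be positive")
  if (cfg$effectHr <= 0 || cfg$baselineHazard <= 0 || cfg$censorHorizon <= 0)
    stop("configuration error: hazards and horizon must be > 0")
  if (cfg$zeroFractionNull < 0 || cfg$zeroFractionNull > 1)
    stop("configuration error: zeroFractionNull must be in [0, 1]")
  nTumorSub <- sum(names(cfg$subtypeSizes) != "Control")
  if (cfg$nFourStar + nTumorSub * cfg$nOneStarPerSubtype > cfg$nMirnas)
    stop("configuration error: more planted miRNAs than miRNAs")
  if (cfg$nCircuits > min(cfg$nFourStar, length(.circuitTfPool)) &&
      cfg$nCircuits > 0)
    stop("configuration error: nCircuits exceeds available four-star miRNAs/symbols")
  class(cfg) <- "CohortConfig"
  cfg
}

#' Generate a synthetic subtyped survival cohort with known ground truth
#'
#' Draws a latent binary risk indicator for every tumor sample (the
#' high-risk stratum sized to span half of the subtype's pooled
#' tumor-plus-control analysis cohort), exponential survival whose
#' hazard is \code{baselineHazard} times a risk multiplier calibrated so
#' the median-split arms of a planted miRNA contrast at \code{effectHr}
#' (controls at baseline),
#' administrative censoring at the horizon plus uniform dropout, and a
#' log-normal RPM expression matrix where only the planted miRNAs are
#' tied to risk (four-star: in every subtype, plus a tumor-vs-control
#' offset; one-star: in one subtype only).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{cohort} (a \linkS4class{MirnaCohort}) and
#'   \code{truth} (a \linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generateCohort(cohortConfig(nMirnas = 50, nFourStar = 4,
#'                                    nOneStarPerSubtype = 2, seed = 7))
#' sim$cohort
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  sizes <- config$subtypeSizes
  subtypeNames <- names(sizes)
  tumorSubtypes <- setdiff(subtypeNames, "Control")

  subtype <- rep(subtypeNames, sizes)
  n <- length(subtype)
  sampleIds <- unlist(lapply(subtypeNames, function(s)
    sprintf("%s_%03d", s, seq_len(sizes[[s]]))), use.names = FALSE)

  ## Latent risk indicator per tumor sample. The high-risk stratum in
  ## each subtype is sized to span half of that subtype's pooled
  ## analysis cohort (subtype tumors + controls), so that a median
  ## split on a planted miRNA recovers the risk strata rather than
  ## diluting them with controls; for small subtypes this saturates at
  ## every tumor being high-risk.
  nControls <- sizes[["Control"]]
  risk <- integer(n)
  hazardMult <- rep(1, n)
  for (s in tumorSubtypes) {
    idx <- which(subtype == s)
    nHighArm <- floor((length(idx) + nControls) / 2)
    nh <- min(length(idx), nHighArm)
    if (nh == 0) next
    hr <- sample(idx, nh)
    risk[hr] <- 1L
    ## effectHr targets the hazard ratio of the high- vs low-expression
    ## *halves* of the pooled subtype+control cohort. When the subtype
    ## is smaller than half that cohort, baseline-hazard controls spill
    ## into the high arm; the latent multiplier is raised so the
    ## arm-level contrast still hits the target.
    nExtra <- max(0L, nHighArm - nh)
    hazardMult[hr] <- max(config$effectHr,
                          (config$effectHr * (nh + nExtra) - nExtra) / nh)
  }

  hazard <- config$baselineHazard * hazardMult
  tDeath <- stats::rexp(n, rate = hazard)
  ## administrative censoring at the horizon; a fraction of patients
  ## additionally drop out uniformly over the follow-up window
  dropsOut <- stats::runif(n) < config$dropoutProb
  dropTime <- stats::runif(n, 0, config$censorHorizon)
  cens <- ifelse(dropsOut, dropTime, config$censorHorizon)
  days <- floor(pmin(tDeath, cens))
  status <- ifelse(tDeath <= cens, "dead", "alive")
  age <- pmin(90, pmax(26, round(stats::rnorm(n, mean = 56, sd = 12))))

  mirnaIds <- sprintf("syn-miR-%04d", seq_len(config$nMirnas))
  nPlanted <- config$nFourStar +
    length(tumorSubtypes) * config$nOneStarPerSubtype
  plantedPos <- sample(config$nMirnas, nPlanted)
  fourStarIds <- sort(mirnaIds[plantedPos[seq_len(config$nFourStar)]])
  oneStarIds <- list()
  off <- config$nFourStar
  for (s in tumorSubtypes) {
    oneStarIds[[s]] <- sort(mirnaIds[
      plantedPos[off + seq_len(config$nOneStarPerSubtype)]])
    off <- off + config$nOneStarPerSubtype
  }

  x <- matrix(stats::rnorm(config$nMirnas * n, config$baseLogMean,
                           config$sdLog),
              nrow = config$nMirnas, ncol = n,
              dimnames = list(mirnaIds, sampleIds))
  isTumor <- subtype != "Control"
  if (length(fourStarIds))
    x[fourStarIds, ] <- x[fourStarIds, , drop = FALSE] +
      rep(config$sdLog * (config$tumorOffset * isTumor +
                          config$riskDelta * risk),
          each = length(fourStarIds))
  for (s in tumorSubtypes) {
    ids <- oneStarIds[[s]]
    if (!length(ids)) next
    inS <- subtype == s
    x[ids, ] <- x[ids, , drop = FALSE] +
      rep(config$sdLog * (config$subtypeOffset * inS +
                          config$riskDelta * risk * inS),
          each = length(ids))
  }

  expr <- 2^x
  nullIds <- setdiff(mirnaIds, c(fourStarIds, unlist(oneStarIds)))
  if (length(nullIds) && config$zeroFractionNull > 0) {
    zeroMask <- matrix(stats::runif(length(nullIds) * n) <
                         config$zeroFractionNull,
                       nrow = length(nullIds))
    expr[nullIds, ][zeroMask] <- 0
  }

  ## planted circuits and anti-correlated mRNA targets
  nc <- config$nCircuits
  circuits <- data.frame(mirna = character(0), symbol = character(0),
                         stringsAsFactors = FALSE)
  pairs <- data.frame(mirna = character(0), gene = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  if (nc > 0 && length(fourStarIds)) {
    cm <- fourStarIds[seq_len(nc)]
    circuits <- data.frame(mirna = cm, symbol = .circuitTfPool[seq_len(nc)],
                           stringsAsFactors = FALSE)
    pairs <- data.frame(
      mirna = rep(cm, 2),
      gene = c(.circuitTfPool[seq_len(nc)], .circuitGenePool[seq_len(nc)]),
      r = -0.5, stringsAsFactors = FALSE)
  }
  stageShift <- sort(fourStarIds[seq_len(min(config$nStageShift,
                                             length(fourStarIds)))])

  clinical <- data.frame(sample_id = sampleIds, subtype = subtype,
                         status = status, days = days, age = age,
                         stage = NA_character_,
                         stringsAsFactors = FALSE)
  truth <- methods::new("SyntheticTruth", fourStar = fourStarIds,
                        oneStar = oneStarIds,
                        anticorrelatedPairs = pairs,
                        plantedCircuits = circuits,
                        stageShiftIds = stageShift)
  list(cohort = MirnaCohort(expr, clinical), truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@fourStar), "four-star miRNAs;",
      "one-star per subtype:",
      paste(names(object@oneStar), lengths(object@oneStar),
            sep = "=", collapse = ", "), "\n")
  cat("  planted circuits:", nrow(object@plantedCircuits),
      "| anti-correlated pairs:", nrow(object@anticorrelatedPairs),
      "| stage-shift miRNAs:", length(object@stageShiftIds), "\n")
})

#' Generate mRNA expression anti-correlated with planted miRNAs
#'
#' For every planted (miRNA, gene) pair the gene's log-scale mRNA column
#' is built so its Pearson correlation with the miRNA's log2(rpm + 1)
#' expression is approximately the recorded target (default -0.5); a
#' target of magnitude 1 yields an exact affine transform. All other
#' genes are independent noise.
#'
#' @param truth a \linkS4class{SyntheticTruth} whose
#'   \code{anticorrelatedPairs} reference miRNAs present in the cohort.
#' @param cohort the \linkS4class{MirnaCohort} the miRNA expression is
#'   read from.
#' @param seed integer seed.
#' @param extraGenes additional independent-noise gene symbols to
#'   include (beyond the planted ones).
#' @return matrix, genes x samples, log2-scale mRNA expression.
#' @export
generateMrna <- function(truth, cohort, seed = 1,
                         extraGenes = sprintf("NOISE%02d", 1:20)) {
  stopifnot(methods::is(truth, "SyntheticTruth"),
            methods::is(cohort, "MirnaCohort"))
  pairs <- truth@anticorrelatedPairs
  bad <- setdiff(pairs$mirna, rownames(rpm(cohort)))
  if (length(bad))
    stop("unknown miRNA identifier(s) in anticorrelatedPairs: ",
         paste(bad, collapse = ", "))
  set.seed(seed)
  le <- logExpr(cohort)
  genes <- unique(c(pairs$gene, extraGenes))
  ns <- ncol(le)
  out <- matrix(stats::rnorm(length(genes) * ns, mean = 6, sd = 1),
                nrow = length(genes),
                dimnames = list(genes, colnames(le)))
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    zm <- as.numeric(scale(le[pairs$mirna[i], ]))
    r <- pairs$r[i]
    g <- if (abs(r) >= 1) r * zm
         else r * zm + sqrt(1 - r^2) * stats::rnorm(ns)
    out[pairs$gene[i], ] <- 6 + g
  }
  out
}

#' Generate interaction tables containing the planted circuits
#'
#' Every planted circuit (m, X) contributes edges m -> X (miRNA
#' targets), X -> m (TF -> miRNA) and X -> G (TF -> gene) where G is
#' m's companion anti-correlated target gene, which m also targets.
#' Decoy genes and TFs are attached with random edges drawn from
#' disjoint symbol pools so that no unplanted miRNA/TF reciprocal pair
#' (i.e. no spurious circuit) can arise.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nDecoyGenes,nDecoyTfs decoy counts (>= 0).
#' @param seed integer seed.
#' @return An \linkS4class{InteractionDB}.
#' @export
generateInteractionDB <- function(truth, nDecoyGenes = 50, nDecoyTfs = 10,
                                  seed = 1) {
  stopifnot(methods::is(truth, "SyntheticTruth"),
            nDecoyGenes >= 0, nDecoyTfs >= 0)
  set.seed(seed)
  circuits <- truth@plantedCircuits
  pairs <- truth@anticorrelatedPairs
  mt <- data.frame(mirna = character(0), gene = character(0))
  tm <- data.frame(tf = character(0), mirna = character(0))
  tg <- data.frame(tf = character(0), gene = character(0))
  if (nrow(circuits)) {
    companion <- vapply(seq_len(nrow(circuits)), function(i) {
      g <- setdiff(pairs$gene[pairs$mirna == circuits$mirna[i]],
                   circuits$symbol[i])
      if (length(g)) g[1] else paste0(circuits$symbol[i], "T")
    }, character(1))
    mt <- data.frame(mirna = rep(circuits$mirna, 2),
                     gene = c(circuits$symbol, companion))
    tm <- data.frame(tf = circuits$symbol, mirna = circuits$mirna)
    tg <- data.frame(tf = circuits$symbol, gene = companion)
  }
  plantedMirnas <- unique(c(truth@fourStar, unlist(truth@oneStar)))
  if (nDecoyGenes > 0 && length(plantedMirnas)) {
    dg <- sprintf("DECG%03d", seq_len(nDecoyGenes))
    mt <- rbind(mt, data.frame(
      mirna = sample(plantedMirnas, nDecoyGenes, replace = TRUE),
      gene = dg))
  }
  if (nDecoyTfs > 0) {
    dtf <- sprintf("DECTF%02d", seq_len(nDecoyTfs))
    dgenes <- if (nDecoyGenes > 0) sprintf("DECG%03d", seq_len(nDecoyGenes))
              else paste0(dtf, "G")
    tg <- rbind(tg, data.frame(tf = dtf,
                               gene = sample(dgenes, nDecoyTfs,
                                             replace = TRUE)))
    if (length(plantedMirnas)) {
      ## decoy TFs may target miRNAs; they are never miRNA targets
      ## themselves, so no unplanted loop can form
      half <- dtf[seq_len(ceiling(nDecoyTfs / 2))]
      tm <- rbind(tm, data.frame(
        tf = half, mirna = sample(plantedMirnas, length(half),
                                  replace = TRUE)))
    }
  }
  interactionDB(mt, tm, tg)
}

#' Assign tumor stages and plant a stage-II expression shift
#'
#' Tumor samples are assigned AJCC sub-stages IA/IB/IIA/IIB uniformly at
#' random (controls stay unstaged). For the truth manifest's
#' stage-shift miRNAs, the expression of stage-II samples is then
#' multiplied by \code{2^shift}, so that on the log2 scale the stage-II
#' mean exceeds the stage-I mean by \code{shift}.
#'
#' @param cohort a \linkS4class{MirnaCohort}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param shift non-negative log2-scale expression shift.
#' @param seed integer seed.
#' @return The updated \linkS4class{MirnaCohort} (stage column filled,
#'   expression shifted).
#' @export
generateStageLabels <- function(cohort, truth, shift = 1, seed = 1) {
  stopifnot(methods::is(cohort, "MirnaCohort"), shift >= 0)
  set.seed(seed)
  cl <- clinicalData(cohort)
  tumors <- which(cl$subtype != "Control")
  cl$stage <- NA_character_
  if (length(tumors)) {
    cl$stage[tumors] <- sample(c("IA", "IB", "IIA", "IIB"),
                               length(tumors), replace = TRUE)
    expr <- rpm(cohort)
    ids <- intersect(truth@stageShiftIds, rownames(expr))
    stageII <- which(cl$stage %in% c("IIA", "IIB"))
    if (length(ids) && length(stageII) && shift > 0)
      expr[ids, stageII] <- expr[ids, stageII, drop = FALSE] * 2^shift
    return(MirnaCohort(expr, cl))
  }
  MirnaCohort(rpm(cohort), cl)
}

#' Write a truth manifest as JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeTruth <- function(truth, file) {
  jsonlite::write_json(
    list(four_star = truth@fourStar, one_star = truth@oneStar,
         anticorrelated_pairs = truth@anticorrelatedPairs,
         planted_circuits = truth@plantedCircuits,
         stage_shift_ids = truth@stageShiftIds),
    file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}
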