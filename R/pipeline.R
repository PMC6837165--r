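#' Assemble a pipeline configuration
#'
#' Exactly one of \code{synthetic} (a \code{\link{cohortConfig}}) or
#' \code{inputs} (a named list of file paths: \code{expression},
#' \code{clinical}, optionally \code{mrna}, \code{mirnaTargets},
#' \code{tfMirna}, \code{tfGene}, \code{gmt}) must be provided.
#'
#' @param synthetic a \code{\link{cohortConfig}}, or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param filterFraction minimum non-zero fraction for the prevalence
#'   filter (default 0.6).
#' @param k top-k list length per subtype (default 100).
#' @param corrThreshold anti-correlation threshold (default -0.3).
#' @param folds,cvSeed cross-validation settings.
#' @param alpha stage-ANOVA significance level.
#' @param stageShift synthetic stage-II expression shift (log2 scale).
#' @param seed global pipeline seed; per-stage seeds are derived from it
#'   as \code{(seed * 97 + stageIndex) mod (2^31 - 1)}.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(synthetic = cohortConfig(), inputs = NULL,
                           filterFraction = 0.6, k = 100,
                           corrThreshold = -0.3, folds = 5, cvSeed = 0,
                           alpha = 0.05, stageShift = 1, seed = 0) {
  if (is.null(synthetic) == is.null(inputs))
    stop("provide exactly one of 'synthetic' or 'inputs'")
  if (filterFraction <= 0 || filterFraction > 1)
    stop("filterFraction must be in (0, 1]")
  if (k < 1) stop("k must be >= 1")
  if (corrThreshold >= 0) stop("corrThreshold must be negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  cfg <- list(synthetic = synthetic, inputs = inputs,
              filterFraction = filterFraction, k = as.integer(k),
              corrThreshold = corrThreshold, folds = as.integer(folds),
              cvSeed = as.integer(cvSeed), alpha = alpha,
              stageShift = stageShift, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Sections mirror \code{\link{pipelineConfig}} arguments; a
#' \code{synthetic:} block holds \code{\link{cohortConfig}} fields, an
#' \code{inputs:} block holds file paths.
#'
#' @param file YAML path.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  y <- yaml::read_yaml(file)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    args <- y$synthetic
    if (!is.null(args$subtypeSizes))
      args$subtypeSizes <- unlist(args$subtypeSizes)
    syn <- do.call(cohortConfig, args)
  }
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipelineConfig, c(list(synthetic = syn), args))
}

.seedFor <- function(seed, i) (abs(seed) * 97L + i) %% 2147483647L

.stageRun <- function(state, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  state$runtimes[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

#' Run the full selection / validation / network pipeline
#'
#' Executes the prevalence filter, per-subtype survival scoring, top-k
#' selection, star-set intersection, the objective tables,
#' cross-validated classification, the stage ANOVA report, network
#' refinement with circuit detection, and (when gene sets are supplied)
#' over-representation analysis, writing every artifact plus a JSON run
#' manifest into \code{outdir}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory.
#' @return the run manifest (named list), invisibly the same content as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env()
  state$runtimes <- list()
  seeds <- list(synthetic = .seedFor(config$seed, 1L),
                stage = .seedFor(config$seed, 2L),
                mrna = .seedFor(config$seed, 3L),
                interactions = .seedFor(config$seed, 4L),
                cv = config$cvSeed)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- .stageRun(state, "simulate", function() {
      cfg <- config$synthetic
      cfg$seed <- seeds$synthetic
      out <- generateCohort(cfg)
      cohort <- generateStageLabels(out$cohort, out$truth,
                                    shift = config$stageShift,
                                    seed = seeds$stage)
      mrna <- generateMrna(out$truth, cohort, seed = seeds$mrna)
      db <- generateInteractionDB(out$truth, seed = seeds$interactions)
      writeCohort(cohort, outdir)
      writeTruth(out$truth, file.path(outdir, "truth.json"))
      writeInteractionDB(db, outdir)
      list(cohort = cohort, truth = out$truth, mrna = mrna, db = db)
    })
    cohort <- sim$cohort; mrna <- sim$mrna; db <- sim$db
    truth <- sim$truth
    gmt <- NULL
  } else {
    loaded <- .stageRun(state, "load", function() {
      inp <- config$inputs
      for (f in c(inp$expression, inp$clinical))
        if (is.null(f) || !file.exists(f))
          stop("required input file missing: ",
               if (is.null(f)) "(unset path)" else f)
      cohort <- readCohort(inp$expression, inp$clinical)
      mrna <- if (!is.null(inp$mrna)) {
        ex <- utils::read.delim(inp$mrna, check.names = FALSE)
        m <- t(as.matrix(ex[, -1, drop = FALSE])); colnames(m) <- ex[[1]]
        m
      } else NULL
      db <- if (!is.null(inp$mirnaTargets))
        loadInteractionDB(inp$mirnaTargets, inp$tfMirna, inp$tfGene)
      else NULL
      list(cohort = cohort, mrna = mrna, db = db, gmt = inp$gmt)
    })
    cohort <- loaded$cohort; mrna <- loaded$mrna; db <- loaded$db
    gmt <- loaded$gmt
  }

  nBefore <- nrow(cohort)
  cohort <- .stageRun(state, "filter", function()
    filterMirnas(cohort, config$filterFraction))

  tumorSubtypes <- sort(setdiff(unique(subtypes(cohort)), "Control"))
  records <- .stageRun(state, "score", function()
    do.call(rbind, lapply(tumorSubtypes, function(s)
      scoreSubtype(cohort, s))))

  topLists <- .stageRun(state, "topk", function() {
    out <- lapply(tumorSubtypes, function(s)
      rankTopK(records[records$subtype == s, ], k = config$k))
    names(out) <- tumorSubtypes
    out
  })
  stars <- .stageRun(state, "stars", function()
    starClassify(topLists, k = config$k))

  fourTab <- .stageRun(state, "psi", function()
    psiTable(records, fourStar(stars)))
  oneTabs <- lapply(tumorSubtypes, function(s) {
    rec <- records[records$subtype == s &
                   records$mirna %in% oneStar(stars)[[s]], , drop = FALSE]
    rec <- rec[order(-rec$score, rec$mirna),
               c("mirna", "hr", "p", "score")]
    rownames(rec) <- NULL
    rec
  })
  names(oneTabs) <- tumorSubtypes

  cv <- .stageRun(state, "classify", function() {
    rows <- list()
    if (length(fourStar(stars))) {
      task <- buildTask(fourStar(stars), cohort, "tumor-vs-control")
      rows[["four-star"]] <- cbind(
        data.frame(task = "four-star tumor-vs-control",
                   n_features = length(task$features)),
        crossValidate(task, folds = config$folds, seed = seeds$cv))
    }
    for (s in tumorSubtypes) {
      feats <- oneStar(stars)[[s]]
      if (!length(feats)) next
      task <- buildTask(feats, cohort, "subtype-vs-rest", subtype = s)
      rows[[s]] <- cbind(
        data.frame(task = paste0("one-star ", s, " vs rest"),
                   n_features = length(task$features)),
        crossValidate(task, folds = config$folds, seed = seeds$cv))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  stageTab <- .stageRun(state, "stages", function() {
    cl <- clinicalData(cohort)
    if (!"stage" %in% colnames(cl) || !any(!is.na(cl$stage)))
      return(NULL)
    stageReport(stars, cohort, alpha = config$alpha)
  })

  network <- .stageRun(state, "network", function() {
    if (is.null(db)) return(NULL)
    starUnion <- unique(c(fourStar(stars), unlist(oneStar(stars))))
    refined <- refineNetwork(starUnion, db, logExpr(cohort), mrna,
                             corrThreshold = config$corrThreshold)
    circuits <- detectCircuits(refined, db)
    graphs <- buildNetwork(refined, db, dir = outdir)
    list(refined = refined, circuits = circuits,
         files = graphs$files,
         nodes = list(full = igraph::vcount(graphs$full),
                      loops = igraph::vcount(graphs$loops)),
         edges = list(full = igraph::ecount(graphs$full),
                      loops = igraph::ecount(graphs$loops)))
  })

  ora <- .stageRun(state, "ora", function() {
    if (is.null(network) || is.null(gmt) || !length(network$refined@genes))
      return(NULL)
    universe <- unique(c(db@mirnaTargets$gene, db@tfGene$gene))
    oraEnrichment(network$refined@genes, universe, gmt)
  })

  results <- list(config = config, records = records, topLists = topLists,
                  stars = stars, fourTab = fourTab, oneTabs = oneTabs,
                  cv = cv, stageTab = stageTab, network = network,
                  ora = ora, truth = truth)
  saveRDS(results, file.path(outdir, "results.rds"))
  files <- renderReport(outdir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirStar")),
    seed = config$seed, derived_seeds = seeds,
    parameters = list(filter_fraction = config$filterFraction,
                      k = config$k,
                      corr_threshold = config$corrThreshold,
                      folds = config$folds, alpha = config$alpha),
    counts = list(
      samples = ncol(cohort),
      tumors = sum(subtypes(cohort) != "Control"),
      controls = sum(subtypes(cohort) == "Control"),
      mirnas_input = nBefore, mirnas_kept = nrow(cohort),
      four_star = length(fourStar(stars)),
      one_star = as.list(lengths(oneStar(stars))),
      circuits = if (is.null(network)) NA else nrow(network$circuits),
      refined_mirnas = if (is.null(network)) NA
                       else length(network$refined@mirnas)),
    files = basename(c(files, file.path(outdir, "results.rds"))),
    runtimes_s = state$runtimes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render the report tables from a completed run
#'
#' Re-creates, byte-identically, the TSV tables from the stored run
#' results: the four-star objective table, the per-subtype one-star
#' tables, the classification accuracy table and the stage report, plus
#' an index file linking every artifact.
#'
#' @param outdir the run directory (must contain results.rds).
#' @return character vector of written file paths.
#' @export
renderReport <- function(outdir) {
  rds <- file.path(outdir, "results.rds")
  if (!file.exists(rds)) stop("no completed run in ", outdir)
  res <- readRDS(rds)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  wt(res$fourTab, "fourstar_psi.tsv")
  for (s in names(res$oneTabs))
    wt(res$oneTabs[[s]], sprintf("onestar_%s.tsv", s))
  if (!is.null(res$cv)) wt(res$cv, "classification_accuracy.tsv")
  if (!is.null(res$stageTab)) wt(res$stageTab, "stage_report.tsv")
  if (!is.null(res$network)) {
    wt(res$network$circuits, "circuits.tsv")
    wt(res$network$refined@corrReport, "step9_correlations.tsv")
  }
  if (!is.null(res$ora)) wt(res$ora, "ora_enrichment.tsv")
  writeStarSets(res$stars, file.path(outdir, "star_sets.json"))
  files <- c(files, file.path(outdir, "star_sets.json"))
  idx <- file.path(outdir, "INDEX.txt")
  writeLines(c("Run artifacts:", basename(files)), idx)
  c(files, idx)
}
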