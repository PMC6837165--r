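#' Construct a MirnaCohort
#'
#' @param rpm numeric matrix of reads-per-million expression, miRNAs in
#'   rows and samples in columns. Dimnames are required.
#' @param clinical data.frame with one row per sample (matched by
#'   \code{sample_id} or row order) and columns \code{subtype},
#'   \code{status}, \code{days}, \code{age}, optionally \code{stage}.
#'
#' @return A \linkS4class{MirnaCohort}.
#' @examples
#' m <- matrix(rexp(12), nrow = 3,
#'             dimnames = list(paste0("mir", 1:3), paste0("s", 1:4)))
#' cl <- data.frame(sample_id = paste0("s", 1:4),
#'                  subtype = c("LA", "LA", "Control", "Control"),
#'                  status = c("dead", "alive", "alive", "alive"),
#'                  days = c(100, 900, 800, 700), age = c(60, 55, 50, 65))
#' MirnaCohort(m, cl)
#' @export
MirnaCohort <- function(rpm, clinical) {
  rpm <- as.matrix(rpm)
  if (is.null(rownames(rpm)) || is.null(colnames(rpm)))
    stop("rpm must carry miRNA rownames and sample colnames")
  clinical <- as.data.frame(clinical)
  if ("sample_id" %in% colnames(clinical)) {
    rownames(clinical) <- clinical$sample_id
    if (!all(colnames(rpm) %in% rownames(clinical)))
      stop("clinical table lacks rows for some samples")
    clinical <- clinical[colnames(rpm), , drop = FALSE]
  } else if (nrow(clinical) != ncol(rpm)) {
    stop("clinical table must have one row per sample")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpm = rpm),
    colData = S4Vectors::DataFrame(clinical, row.names = colnames(rpm)))
  methods::new("MirnaCohort", se)
}

#' Accessors for MirnaCohort
#'
#' \code{rpm} returns the raw expression matrix; \code{logExpr} the
#' log2(rpm + 1) matrix used throughout the analysis; \code{clinicalData}
#' the clinical annotation as a data.frame; \code{subtypes} the
#' per-sample subtype factor.
#'
#' @param x a \linkS4class{MirnaCohort}.
#' @return A matrix, data.frame or character vector as described.
#' @name MirnaCohort-accessors
#' @aliases rpm logExpr clinicalData subtypes
NULL

#' @rdname MirnaCohort-accessors
#' @export
setMethod("rpm", "MirnaCohort", function(x)
  SummarizedExperiment::assay(x, "rpm"))

#' @rdname MirnaCohort-accessors
#' @export
setMethod("logExpr", "MirnaCohort", function(x)
  log2(SummarizedExperiment::assay(x, "rpm") + 1))

#' @rdname MirnaCohort-accessors
#' @export
setMethod("clinicalData", "MirnaCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname MirnaCohort-accessors
#' @export
setMethod("subtypes", "MirnaCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$subtype))

setMethod("show", "MirnaCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MirnaCohort:", nrow(object), "miRNAs x", ncol(object), "samples\n")
  tab <- table(cd$subtype)
  cat("  subtypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  deaths:", sum(cd$status == "dead"), "| censored:",
      sum(cd$status == "alive"), "\n")
  if ("stage" %in% colnames(cd) && any(!is.na(cd$stage)))
    cat("  staged samples:", sum(!is.na(cd$stage)), "\n")
})

#' Read / write a cohort as TSV
#'
#' The on-disk layout is the field-standard exchange form: the
#' expression file has samples in rows and a header row of miRNA
#' identifiers (first column \code{sample_id}); the clinical file has
#' columns sample_id, subtype, status, days, age and optionally stage.
#'
#' @param expressionFile,clinicalFile paths to TSV files.
#' @return A \linkS4class{MirnaCohort}.
#' @export
readCohort <- function(expressionFile, clinicalFile) {
  for (f in c(expressionFile, clinicalFile))
    if (!file.exists(f)) stop("input file not found: ", f)
  ex <- utils::read.delim(expressionFile, check.names = FALSE)
  cl <- utils::read.delim(clinicalFile, check.names = FALSE)
  m <- t(as.matrix(ex[, -1, drop = FALSE]))
  colnames(m) <- ex[[1]]
  MirnaCohort(m, cl)
}

#' @param cohort a \linkS4class{MirnaCohort}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return \code{writeCohort} returns the two file paths, invisibly.
#' @rdname readCohort
#' @export
writeCohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, paste0(prefix, "_expression.tsv"))
  cf <- file.path(dir, paste0(prefix, "_clinical.tsv"))
  ex <- data.frame(sample_id = colnames(rpm(cohort)), t(rpm(cohort)),
                   check.names = FALSE)
  utils::write.table(ex, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- clinicalData(cohort)
  if (!"sample_id" %in% colnames(cl))
    cl <- cbind(sample_id = rownames(cl), cl)
  utils::write.table(cl, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = ef, clinical = cf))
}
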