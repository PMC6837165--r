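#' Score every miRNA for one subtype by median-split survival analysis
#'
#' Pools the tumors of one subtype with the controls, splits the pooled
#' cohort at the median expression of each miRNA, and records the
#' observed/expected hazard ratio of the high- versus low-expression
#' group together with the log-rank p-value. The ranking score is
#' HR - p. A degenerate split (all values tied) leaves the record
#' flagged with a missing score.
#'
#' @param cohort a \linkS4class{MirnaCohort} (already prevalence
#'   filtered, see \code{\link{filterMirnas}}).
#' @param subtype the tumor subtype to score (e.g. "LA").
#' @param control label of the control samples pooled into every
#'   subtype's cohort.
#' @return data.frame with columns mirna, subtype, hr, p, score,
#'   degenerate.
#' @export
scoreSubtype <- function(cohort, subtype, control = "Control") {
  stopifnot(methods::is(cohort, "MirnaCohort"))
  st <- subtypes(cohort)
  if (!subtype %in% st) stop("subtype not present in cohort: ", subtype)
  if (!control %in% st) stop("no control samples labelled ", control)
  keep <- st %in% c(subtype, control)
  if (sum(keep) < 4) stop("cohort too small (< 4 samples)")
  cl <- clinicalData(cohort)[keep, , drop = FALSE]
  fu <- followUp(cl)
  le <- logExpr(cohort)[, keep, drop = FALSE]
  res <- lapply(rownames(le), function(m) {
    sp <- medianSplit(le[m, ])
    if (sp$degenerate)
      return(data.frame(mirna = m, subtype = subtype, hr = NA_real_,
                        p = NA_real_, score = NA_real_, degenerate = TRUE))
    hi <- colnames(le) %in% sp$high
    tm <- .logrankTerms(fu$durations[hi], fu$events[hi],
                        fu$durations[!hi], fu$events[!hi])
    hr <- if (tm$EA <= 0 || tm$EB <= 0 || tm$OB == 0) NA_real_
          else (tm$OA / tm$EA) / (tm$OB / tm$EB)
    p <- if (tm$nTimes == 0 || tm$V <= 0) 1
         else stats::pchisq((tm$OA - tm$EA)^2 / tm$V, df = 1,
                            lower.tail = FALSE)
    data.frame(mirna = m, subtype = subtype, hr = hr, p = p,
               score = if (is.na(hr)) NA_real_ else hr - p,
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Select the top-k miRNAs from a score table
#'
#' Orders records by descending score, breaking ties lexicographically
#' by miRNA identifier; records with missing scores are excluded.
#'
#' @param records data.frame from \code{\link{scoreSubtype}} (columns
#'   mirna, score).
#' @param k list length (returns \code{min(k, available)} ids).
#' @return character vector of miRNA ids, best first.
#' @export
rankTopK <- function(records, k = 100) {
  records <- records[!is.na(records$score), , drop = FALSE]
  ord <- order(-records$score, records$mirna)
  utils::head(records$mirna[ord], k)
}

#' Intersect per-subtype top-k lists into star sets
#'
#' Four-star miRNAs appear in every subtype's list; one-star miRNAs in
#' exactly one. Intermediate multiplicities (two-/three-star counts) are
#' retained for reporting.
#'
#' @param topLists named list of top-k id vectors, one per subtype.
#' @param k the k used to build the lists (recorded).
#' @return A \linkS4class{StarSets}.
#' @examples
#' starClassify(list(A = c("m1", "m2"), B = c("m1", "m3"),
#'                   C = c("m1", "m4"), D = c("m1", "m5")))
#' @export
starClassify <- function(topLists, k = max(lengths(topLists), 1L)) {
  stopifnot(is.list(topLists), length(topLists) >= 1)
  all <- unique(unlist(topLists))
  mult <- vapply(all, function(m)
    sum(vapply(topLists, function(l) m %in% l, logical(1))), integer(1))
  fourStar <- sort(all[mult == length(topLists)])
  oneStar <- lapply(topLists, function(l)
    sort(intersect(l, all[mult == 1L])))
  counts <- vapply(seq_along(topLists), function(i) sum(mult == i),
                   integer(1))
  names(counts) <- paste0("star", seq_along(topLists))
  methods::new("StarSets", fourStar = fourStar, oneStar = oneStar,
               multiStar = counts, k = as.integer(k))
}

#' @rdname StarSets-accessors
#' @export
setMethod("fourStar", "StarSets", function(x) x@fourStar)

#' Accessors for StarSets
#'
#' @param x a \linkS4class{StarSets}.
#' @return \code{fourStar}: character vector; \code{oneStar}: named list.
#' @name StarSets-accessors
#' @aliases fourStar oneStar
NULL

#' @rdname StarSets-accessors
#' @export
setMethod("oneStar", "StarSets", function(x) x@oneStar)

setMethod("show", "StarSets", function(object) {
  cat("StarSets (top-k =", object@k, "):", length(object@fourStar),
      "four-star;", "one-star:",
      paste(names(object@oneStar), lengths(object@oneStar),
            sep = "=", collapse = ", "), "\n")
})

#' Write star sets as JSON
#'
#' @param starSets a \linkS4class{StarSets}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeStarSets <- function(starSets, file) {
  jsonlite::write_json(
    list(k = starSets@k, four_star = starSets@fourStar,
         one_star = starSets@oneStar,
         multiplicity = as.list(starSets@multiStar)),
    file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' The combined relevance objective over subtypes
#'
#' For one miRNA, sums (HR_i - p_i) over the S subtypes. With S = 4 this
#' is the score used to rank four-star miRNAs; with S = 1 it reduces to
#' the single-subtype score used for the one-star tables.
#'
#' @param hr numeric vector of per-subtype hazard ratios (length S).
#' @param p numeric vector of matching log-rank p-values.
#' @param S expected number of subtypes (defaults to 4).
#' @return The scalar objective value.
#' @examples
#' psiScore(c(2.318, 2.910, 3.003, 4.037), c(0.019, 0.017, 0.020, 0.002))
#' @export
psiScore <- function(hr, p, S = 4) {
  if (length(hr) != S || length(p) != S)
    stop("expected exactly ", S, " (hr, p) pairs")
  if (anyNA(hr) || anyNA(p)) stop("missing subtype entry")
  sum(hr - p)
}

#' Build the per-miRNA objective table for the four-star set
#'
#' Mirrors the published layout: one row per four-star miRNA with
#' per-subtype (HR, p) columns and the summed objective, sorted
#' strictly descending by the objective.
#'
#' @param records combined score records from
#'   \code{\link{scoreSubtype}} over all subtypes.
#' @param mirnas the miRNAs to tabulate (typically
#'   \code{fourStar(starSets)}).
#' @return data.frame, one row per miRNA, columns
#'   \code{hr_<subtype>}, \code{p_<subtype>}, \code{psi}.
#' @export
psiTable <- function(records, mirnas) {
  subs <- sort(unique(records$subtype))
  if (!length(mirnas)) {
    out <- data.frame(mirna = character(0))
    for (s in subs) {
      out[[paste0("hr_", s)]] <- numeric(0)
      out[[paste0("p_", s)]] <- numeric(0)
    }
    out$psi <- numeric(0)
    return(out)
  }
  rows <- lapply(mirnas, function(m) {
    rec <- records[records$mirna == m, , drop = FALSE]
    rec <- rec[match(subs, rec$subtype), , drop = FALSE]
    out <- data.frame(mirna = m)
    for (i in seq_along(subs)) {
      out[[paste0("hr_", subs[i])]] <- rec$hr[i]
      out[[paste0("p_", subs[i])]] <- rec$p[i]
    }
    out$psi <- if (anyNA(rec$hr)) NA_real_
               else psiScore(rec$hr, rec$p, S = length(subs))
    out
  })
  tab <- do.call(rbind, rows)
  if (nrow(tab)) tab <- tab[order(-tab$psi, tab$mirna), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Published per-subtype survival statistics for the star miRNAs
#'
#' Plain-text copies of the reported per-subtype hazard ratios,
#' log-rank p-values and objective values for the 44 four-star miRNAs
#' (\code{fourStarTable}) and the 50 one-star miRNAs across the four
#' subtypes (\code{oneStarTable}), as printed to three decimals. They
#' serve as reference inputs for reproducing the objective computation.
#'
#' @return data.frame.
#' @export
fourStarTable <- function() {
  utils::read.delim(system.file("extdata", "fourstar_survival_stats.tsv",
                                package = "mirStar"))
}

#' @rdname fourStarTable
#' @export
oneStarTable <- function() {
  utils::read.delim(system.file("extdata", "onestar_survival_stats.tsv",
                                package = "mirStar"))
}
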