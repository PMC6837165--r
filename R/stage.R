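#' Assign tumor samples to collapsed AJCC stage groups I / II
#'
#' Sub-stages (IA/IB, IIA/IIB, with or without a "Stage " prefix) are
#' collapsed to I and II; samples in stages III/IV, unstaged samples and
#' controls are excluded. With scope "subtype" only tumors of the given
#' subtype are retained; with scope "all" every staged tumor is.
#'
#' @param clinical clinical data.frame (columns subtype, stage).
#' @param scope "all" (four-star analyses) or "subtype" (one-star).
#' @param subtype required when \code{scope = "subtype"}.
#' @return named character vector, sample id -> "I" or "II".
#' @export
assignStageGroups <- function(clinical, scope = c("all", "subtype"),
                              subtype = NULL) {
  scope <- match.arg(scope)
  if (!"stage" %in% colnames(clinical))
    stop("no stage annotations present")
  keep <- clinical$subtype != "Control"
  if (scope == "subtype") {
    if (is.null(subtype)) stop("subtype required for scope = 'subtype'")
    keep <- clinical$subtype == subtype
  }
  st <- toupper(trimws(sub("(?i)^stage\\s*", "", clinical$stage,
                           perl = TRUE)))
  collapsed <- rep(NA_character_, length(st))
  collapsed[st %in% c("I", "IA", "IB")] <- "I"
  collapsed[st %in% c("II", "IIA", "IIB")] <- "II"
  sel <- keep & !is.na(collapsed)
  if (!any(sel)) stop("no staged samples in scope")
  ids <- if (!is.null(rownames(clinical))) rownames(clinical)
         else as.character(seq_len(nrow(clinical)))
  stats::setNames(collapsed[sel], ids[sel])
}

#' One-way ANOVA of expression across stages for one miRNA
#'
#' Classical one-way ANOVA with stage as the independent variable and
#' the expression value as the dependent variable, plus the direction
#' of change ("increase" when the stage-II mean exceeds the stage-I
#' mean).
#'
#' @param values named numeric vector of per-sample expression.
#' @param stageMap named vector from \code{\link{assignStageGroups}};
#'   only samples present in both are used.
#' @return list with groupMeans, F, p, direction, n (per-stage counts).
#'   F and p are NA when within-group variance vanishes with equal
#'   means.
#' @examples
#' stageAnova(c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6),
#'            c(a = "I", b = "I", c = "I", d = "II", e = "II", f = "II"))
#' @export
stageAnova <- function(values, stageMap) {
  common <- intersect(names(values), names(stageMap))
  if (length(common) < 4) stop("need >= 2 samples per stage")
  y <- values[common]
  g <- factor(stageMap[common], levels = c("I", "II"))
  if (any(table(g) < 2)) stop("need >= 2 samples per stage")
  means <- tapply(y, g, mean)
  direction <- if (isTRUE(all.equal(means[["II"]], means[["I"]]))) "none"
               else if (means[["II"]] > means[["I"]]) "increase"
               else "decrease"
  if (all(y == y[1]))  # no variance at all: F is 0/0
    return(list(groupMeans = means, F = NA_real_, p = NA_real_,
                direction = "none", n = table(g)))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  if (!is.finite(Fv)) { Fv <- NA_real_; pv <- NA_real_; direction <- "none" }
  list(groupMeans = means, F = Fv, p = pv, direction = direction,
       n = table(g))
}

#' Stage-change report over the star miRNAs
#'
#' One row per miRNA in the union of the star sets: four-star miRNAs
#' are tested over all staged tumors, each one-star miRNA over the
#' staged tumors of its own subtype. Expression is analyzed on the
#' log2(rpm + 1) scale by default. No multiplicity correction is
#' applied by default; set \code{correct = TRUE} for
#' Benjamini-Hochberg.
#'
#' @param starSets a \linkS4class{StarSets}.
#' @param cohort a staged \linkS4class{MirnaCohort}.
#' @param alpha significance level for the flag (default 0.05).
#' @param scale "log" (default) or "raw" expression scale.
#' @param correct apply BH correction across the reported miRNAs.
#' @return data.frame: mirna, set, n_I, n_II, mean_I, mean_II, F, p,
#'   direction, significant.
#' @export
stageReport <- function(starSets, cohort, alpha = 0.05,
                        scale = c("log", "raw"), correct = FALSE) {
  scale <- match.arg(scale)
  stopifnot(methods::is(starSets, "StarSets"),
            methods::is(cohort, "MirnaCohort"))
  expr <- if (scale == "log") logExpr(cohort) else rpm(cohort)
  cl <- clinicalData(cohort)
  jobs <- list()
  for (m in fourStar(starSets))
    jobs[[length(jobs) + 1L]] <- list(mirna = m, set = "four-star",
                                      scope = "all", subtype = NULL)
  for (s in names(oneStar(starSets)))
    for (m in oneStar(starSets)[[s]])
      jobs[[length(jobs) + 1L]] <- list(mirna = m,
                                        set = paste0("one-star ", s),
                                        scope = "subtype", subtype = s)
  if (!length(jobs))
    return(data.frame(mirna = character(0), set = character(0),
                      n_I = integer(0), n_II = integer(0),
                      mean_I = numeric(0), mean_II = numeric(0),
                      F = numeric(0), p = numeric(0),
                      direction = character(0), significant = logical(0)))
  rows <- lapply(jobs, function(j) {
    out <- data.frame(mirna = j$mirna, set = j$set, n_I = NA_integer_,
                      n_II = NA_integer_, mean_I = NA_real_,
                      mean_II = NA_real_, F = NA_real_, p = NA_real_,
                      direction = NA_character_, significant = NA)
    if (!j$mirna %in% rownames(expr)) return(out)
    res <- tryCatch({
      sm <- assignStageGroups(cl, scope = j$scope, subtype = j$subtype)
      stageAnova(expr[j$mirna, ], sm)
    }, error = function(e) NULL)
    if (is.null(res)) return(out)
    out$n_I <- res$n[["I"]]; out$n_II <- res$n[["II"]]
    out$mean_I <- res$groupMeans[["I"]]
    out$mean_II <- res$groupMeans[["II"]]
    out$F <- res$F; out$p <- res$p; out$direction <- res$direction
    out
  })
  rep <- do.call(rbind, rows)
  pAdj <- if (correct) stats::p.adjust(rep$p, method = "BH") else rep$p
  rep$significant <- !is.na(pAdj) & pAdj < alpha
  rep
}
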