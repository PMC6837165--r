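#' Construct an InteractionDB from three edge tables
#'
#' Gene and TF symbols are uppercased (one shared namespace); edges are
#' deduplicated; whitespace is trimmed. miRNA identifiers are kept
#' verbatim apart from trimming, since miRNA nomenclature is
#' case-sensitive by convention.
#'
#' @param mirnaTargets data.frame/2-column table, miRNA -> target gene.
#' @param tfMirna data.frame, TF -> target miRNA.
#' @param tfGene data.frame, TF -> target gene.
#' @return An \linkS4class{InteractionDB}.
#' @export
interactionDB <- function(mirnaTargets, tfMirna, tfGene) {
  norm <- function(x) trimws(as.character(x))
  mt <- data.frame(mirna = norm(mirnaTargets[[1]]),
                   gene = toupper(norm(mirnaTargets[[2]])))
  tm <- data.frame(tf = toupper(norm(tfMirna[[1]])),
                   mirna = norm(tfMirna[[2]]))
  tg <- data.frame(tf = toupper(norm(tfGene[[1]])),
                   gene = toupper(norm(tfGene[[2]])))
  mt <- unique(mt); tm <- unique(tm); tg <- unique(tg)
  rownames(mt) <- rownames(tm) <- rownames(tg) <- NULL
  methods::new("InteractionDB", mirnaTargets = mt, tfMirna = tm,
               tfGene = tg)
}

setMethod("show", "InteractionDB", function(object) {
  cat("InteractionDB:",
      nrow(object@mirnaTargets), "miRNA->gene,",
      nrow(object@tfMirna), "TF->miRNA,",
      nrow(object@tfGene), "TF->gene edges\n")
})

.readEdgeFile <- function(path, what) {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  ok <- lengths(parts) >= 2 &
    vapply(parts, function(p) all(nzchar(trimws(p[1:2]))), logical(1))
  if (any(!ok))
    warning(sprintf("%s: rejected %d malformed row(s) at line(s) %s",
                    what, sum(!ok),
                    paste(which(!ok), collapse = ", ")))
  data.frame(from = vapply(parts[ok], `[`, character(1), 1),
             to = vapply(parts[ok], `[`, character(1), 2))
}

#' Load an InteractionDB from TSV edge lists
#'
#' Each file is a headerless 2-column TSV (source, target). Malformed
#' rows are rejected with their line numbers; duplicate edges are
#' stored once.
#'
#' @param mirnaTargetsFile miRNA -> gene edges.
#' @param tfMirnaFile TF -> miRNA edges.
#' @param tfGeneFile TF -> gene edges.
#' @return An \linkS4class{InteractionDB}.
#' @export
loadInteractionDB <- function(mirnaTargetsFile, tfMirnaFile, tfGeneFile) {
  mt <- .readEdgeFile(mirnaTargetsFile, "miRNA targets")
  tm <- .readEdgeFile(tfMirnaFile, "TF->miRNA")
  tg <- .readEdgeFile(tfGeneFile, "TF->gene")
  interactionDB(mt, tm, tg)
}

#' Write an InteractionDB as three TSV edge lists
#'
#' @param db an \linkS4class{InteractionDB}.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeInteractionDB <- function(db, dir, prefix = "interactions") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna_targets = file.path(dir, paste0(prefix, "_mirna_gene.tsv")),
    tf_mirna = file.path(dir, paste0(prefix, "_tf_mirna.tsv")),
    tf_gene = file.path(dir, paste0(prefix, "_tf_gene.tsv")))
  utils::write.table(db@mirnaTargets, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(db@tfMirna, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(db@tfGene, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Eleven-step refinement of miRNA, gene and TF sets
#'
#' Starting from a miRNA set, alternately restricts genes, TFs and
#' miRNAs through the interaction tables: (1) genes targeted by the
#' input miRNAs; (2) TFs targeting the input miRNAs; (3) input miRNAs
#' targeted by a step-2 TF; (4) genes targeted by step-3 miRNAs; (5)
#' TFs targeting step-4 genes; (6) intersection of step-2 and step-5
#' TFs; (7) genes targeted by step-6 TFs; (8) step-7 genes also
#' targeted by the input miRNAs; (9) step-8 genes whose mRNA is
#' anti-correlated (Pearson r strictly below \code{corrThreshold})
#' with at least one step-3 miRNA; (10) TFs targeting step-9 genes;
#' (11) step-3 miRNAs targeted by a step-10 TF. The procedure is
#' contractive: new miRNAs never enter at step 3.
#'
#' @param mirnaSet character vector of starting miRNA ids.
#' @param db an \linkS4class{InteractionDB}.
#' @param mirnaExpr matrix (miRNAs x samples), log-scale expression
#'   used for the anti-correlation step.
#' @param mrnaExpr matrix (genes x samples), log-scale mRNA expression
#'   over the same samples. Step-8 genes without an mRNA profile are
#'   dropped at step 9 with a warning.
#' @param corrThreshold strict upper bound on the Pearson correlation
#'   (default -0.3).
#' @return A \linkS4class{RefinedSets}.
#' @export
refineNetwork <- function(mirnaSet, db, mirnaExpr = NULL, mrnaExpr = NULL,
                          corrThreshold = -0.3) {
  stopifnot(methods::is(db, "InteractionDB"))
  mt <- db@mirnaTargets; tm <- db@tfMirna; tg <- db@tfGene
  s1 <- sort(unique(mt$gene[mt$mirna %in% mirnaSet]))
  s2 <- sort(unique(tm$tf[tm$mirna %in% mirnaSet]))
  s3 <- sort(unique(intersect(mirnaSet, tm$mirna[tm$tf %in% s2])))
  s4 <- sort(unique(mt$gene[mt$mirna %in% s3]))
  s5 <- sort(unique(tg$tf[tg$gene %in% s4]))
  s6 <- intersect(s2, s5)
  s7 <- sort(unique(tg$gene[tg$tf %in% s6]))
  s8 <- intersect(s7, s1)

  corrReport <- data.frame(mirna = character(0), gene = character(0),
                           r = numeric(0), kept = logical(0))
  if (length(s8)) {
    if (is.null(mirnaExpr) || is.null(mrnaExpr)) {
      warning("no expression supplied; all step-8 genes dropped at step 9")
      s9 <- character(0)
    } else {
      if (!identical(colnames(mirnaExpr), colnames(mrnaExpr)))
        stop("miRNA and mRNA expression must share the same samples")
      missing <- setdiff(s8, rownames(mrnaExpr))
      if (length(missing))
        warning("no mRNA expression for gene(s), dropped at step 9: ",
                paste(missing, collapse = ", "))
      present <- intersect(s8, rownames(mrnaExpr))
      ms <- intersect(s3, rownames(mirnaExpr))
      rows <- list()
      for (g in present) for (m in ms) {
        r <- suppressWarnings(
          stats::cor(mirnaExpr[m, ], mrnaExpr[g, ]))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, gene = g, r = r,
          kept = !is.na(r) && r < corrThreshold)
      }
      if (length(rows)) corrReport <- do.call(rbind, rows)
      s9 <- sort(unique(corrReport$gene[corrReport$kept]))
    }
  } else s9 <- character(0)

  s10 <- sort(unique(tg$tf[tg$gene %in% s9]))
  s11 <- sort(unique(intersect(s3, tm$mirna[tm$tf %in% s10])))

  methods::new("RefinedSets",
               steps = list(step1 = s1, step2 = s2, step3 = s3, step4 = s4,
                            step5 = s5, step6 = s6, step7 = s7, step8 = s8,
                            step9 = s9, step10 = s10, step11 = s11),
               mirnas = s11, genes = s9, tfs = s10,
               corrReport = corrReport)
}

setMethod("show", "RefinedSets", function(object) {
  cat("RefinedSets:", length(object@mirnas), "miRNAs,",
      length(object@genes), "genes,", length(object@tfs), "TFs after refinement\n")
  cat("  step sizes:",
      paste(names(object@steps), lengths(object@steps), sep = "=",
            collapse = ", "), "\n")
})

#' Detect miRNA/TF regulatory circuits
#'
#' A circuit is a pair (m, X) where the miRNA m targets the gene X and
#' the transcription factor encoded by X targets m, restricted to the
#' refined miRNA (step 11) and TF (step 10) sets. Returned in
#' deterministic (mirna, symbol) order.
#'
#' @param refined a \linkS4class{RefinedSets}.
#' @param db the \linkS4class{InteractionDB} used for refinement.
#' @return data.frame with columns mirna, symbol.
#' @export
detectCircuits <- function(refined, db) {
  stopifnot(methods::is(refined, "RefinedSets"),
            methods::is(db, "InteractionDB"))
  mt <- db@mirnaTargets; tm <- db@tfMirna
  cand <- mt[mt$mirna %in% refined@mirnas & mt$gene %in% refined@tfs, ,
             drop = FALSE]
  if (!nrow(cand))
    return(data.frame(mirna = character(0), symbol = character(0)))
  back <- paste(tm$tf, tm$mirna)
  keep <- paste(cand$gene, cand$mirna) %in% back
  out <- data.frame(mirna = cand$mirna[keep], symbol = cand$gene[keep])
  out <- unique(out[order(out$mirna, out$symbol), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite regulatory network
#'
#' Builds a typed igraph over the refined miRNA/gene/TF sets (node
#' attribute \code{type} in miRNA/gene/TF; a symbol acting as both gene
#' and TF is typed TF), in a full variant and a loops-only variant
#' restricted to the detected circuits. Optionally exports both as
#' GraphML and SIF.
#'
#' @param refined a \linkS4class{RefinedSets}.
#' @param db an \linkS4class{InteractionDB}.
#' @param dir optional output directory for GraphML/SIF export.
#' @param prefix filename prefix for exports.
#' @return list with igraph objects \code{full} and \code{loops}, and
#'   \code{files} (exported paths, if any).
#' @export
buildNetwork <- function(refined, db, dir = NULL, prefix = "network") {
  stopifnot(methods::is(refined, "RefinedSets"))
  mirnas <- refined@mirnas; genes <- refined@genes; tfs <- refined@tfs
  mt <- db@mirnaTargets; tm <- db@tfMirna; tg <- db@tfGene
  e1 <- mt[mt$mirna %in% mirnas & mt$gene %in% union(genes, tfs), ,
           drop = FALSE]
  e2 <- tm[tm$tf %in% tfs & tm$mirna %in% mirnas, , drop = FALSE]
  e3 <- tg[tg$tf %in% tfs & tg$gene %in% genes, , drop = FALSE]
  edges <- rbind(
    data.frame(from = e1$mirna, to = e1$gene,
               relation = rep("targets", nrow(e1))),
    data.frame(from = e2$tf, to = e2$mirna,
               relation = rep("regulates_mirna", nrow(e2))),
    data.frame(from = e3$tf, to = e3$gene,
               relation = rep("regulates_gene", nrow(e3))))
  nodes <- unique(c(mirnas, genes, tfs, edges$from, edges$to))
  type <- ifelse(nodes %in% mirnas, "miRNA",
                 ifelse(nodes %in% tfs, "TF", "gene"))
  full <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes, type = type))

  circuits <- detectCircuits(refined, db)
  loopNodes <- unique(c(circuits$mirna, circuits$symbol))
  loopEdges <- rbind(
    data.frame(from = circuits$mirna, to = circuits$symbol,
               relation = rep("targets", nrow(circuits))),
    data.frame(from = circuits$symbol, to = circuits$mirna,
               relation = rep("regulates_mirna", nrow(circuits))))
  loops <- igraph::graph_from_data_frame(
    loopEdges, directed = TRUE,
    vertices = data.frame(
      name = loopNodes,
      type = ifelse(loopNodes %in% circuits$mirna, "miRNA", "TF")))

  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gmlFull <- file.path(dir, paste0(prefix, "_full.graphml"))
    gmlLoop <- file.path(dir, paste0(prefix, "_loops.graphml"))
    igraph::write_graph(full, gmlFull, format = "graphml")
    igraph::write_graph(loops, gmlLoop, format = "graphml")
    sifFull <- file.path(dir, paste0(prefix, "_full.sif"))
    sifLoop <- file.path(dir, paste0(prefix, "_loops.sif"))
    writeLines(paste(edges$from, edges$relation, edges$to, sep = "\t"),
               sifFull)
    writeLines(paste(loopEdges$from, loopEdges$relation, loopEdges$to,
                     sep = "\t"), sifLoop)
    files <- c(gmlFull, gmlLoop, sifFull, sifLoop)
  }
  list(full = full, loops = loops, files = files)
}

#' Node degrees and hubs of a PPI network
#'
#' Treats the edge list as an undirected simple graph (self-loops are
#' dropped with a warning, duplicate edges collapsed) and returns each
#' node's degree in descending order, flagging hubs above a degree
#' quantile.
#'
#' @param edges 2-column data.frame or matrix of undirected edges.
#' @param hubQuantile nodes with degree strictly above this quantile of
#'   the degree distribution are flagged as hubs (default 0.9).
#' @return data.frame with columns node, degree, hub.
#' @export
ppiDegrees <- function(edges, hubQuantile = 0.9) {
  edges <- as.data.frame(edges)[, 1:2]
  colnames(edges) <- c("a", "b")
  self <- edges$a == edges$b
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop(s)")
    edges <- edges[!self, , drop = FALSE]
  }
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b),
                paste(edges$b, edges$a))
  edges <- edges[!duplicated(key), , drop = FALSE]
  deg <- sort(table(c(edges$a, edges$b)), decreasing = TRUE)
  df <- data.frame(node = names(deg), degree = as.integer(deg))
  df$hub <- df$degree > stats::quantile(df$degree, hubQuantile)
  rownames(df) <- NULL
  df
}

#' Read gene sets from a GMT file
#'
#' @param file path to a GMT file (term, description, members...).
#' @return named list of character vectors.
#' @export
readGeneSets <- function(file) fgsea::gmtPathways(file)

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether its overlap with the query is
#' larger than expected from drawing \code{length(query)} genes from
#' the universe without replacement (upper-tail hypergeometric), with
#' Benjamini-Hochberg correction across terms.
#'
#' @param query character vector of genes of interest (must be a subset
#'   of the universe, non-empty).
#' @param universe background gene universe.
#' @param geneSets named list of character vectors, or a GMT file path.
#' @param qCutoff significance threshold on the BH-adjusted p-value.
#' @return data.frame with columns term, overlap, term_size, query_size,
#'   p, q, significant, sorted by p.
#' @export
oraEnrichment <- function(query, universe, geneSets, qCutoff = 0.05) {
  if (!length(query)) stop("empty query gene set")
  query <- unique(query); universe <- unique(universe)
  if (length(setdiff(query, universe)))
    stop("query must be a subset of the universe")
  if (is.character(geneSets) && length(geneSets) == 1 &&
      file.exists(geneSets))
    geneSets <- readGeneSets(geneSets)
  if (!length(geneSets)) stop("no gene sets supplied")
  rows <- lapply(names(geneSets), function(term) {
    members <- intersect(unique(geneSets[[term]]), universe)
    ov <- length(intersect(members, query))
    p <- stats::phyper(ov - 1, length(members),
                       length(universe) - length(members),
                       length(query), lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = length(members),
               query_size = length(query), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < qCutoff
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
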