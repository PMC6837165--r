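test_that("interaction tables are normalized and deduplicated", {
  db <- interactionDB(
    data.frame(m = c("miR-1", "miR-1", "miR-2"),
               g = c("Tp53", "TP53", "myc")),
    data.frame(tf = "tp53", m = "miR-1"),
    data.frame(tf = "TP53", g = c("Myc", "MYC")))
  expect_equal(nrow(db@mirnaTargets), 2)  # Tp53/TP53 unified then deduped
  expect_equal(sort(db@mirnaTargets$gene), c("MYC", "TP53"))
  expect_equal(db@tfMirna$tf, "TP53")
  expect_equal(nrow(db@tfGene), 1)
})

test_that("edge files load with malformed rows rejected by line number", {
  dir <- withr::local_tempdir()
  writeLines(c("miR-1\tTP53", "bad-row-no-tab", "miR-2\tMYC",
               "miR-1\tTP53"), file.path(dir, "mt.tsv"))
  writeLines("TP53\tmiR-1", file.path(dir, "tm.tsv"))
  writeLines("TP53\tMYC", file.path(dir, "tg.tsv"))
  expect_warning(
    db <- loadInteractionDB(file.path(dir, "mt.tsv"),
                            file.path(dir, "tm.tsv"),
                            file.path(dir, "tg.tsv")),
    "line\\(s\\) 2")
  expect_equal(nrow(db@mirnaTargets), 2)  # duplicate stored once
  expect_error(loadInteractionDB(file.path(dir, "nope.tsv"),
                                 file.path(dir, "tm.tsv"),
                                 file.path(dir, "tg.tsv")),
               "not found")
})

test_that("generated edge counts reconcile with the truth manifest", {
  sim <- generateCohort(cohortConfig(seed = 4, nCircuits = 5))
  db <- generateInteractionDB(sim$truth, nDecoyGenes = 30, nDecoyTfs = 8,
                              seed = 2)
  nc <- nrow(sim$truth@plantedCircuits)
  expect_equal(nrow(db@mirnaTargets), 2 * nc + 30)
  expect_equal(nrow(db@tfMirna), nc + 4)      # half the decoy TFs
  expect_equal(nrow(db@tfGene), nc + 8)
})

test_that("refinement recovers planted circuits and is contractive", {
  sim <- generateCohort(cohortConfig(seed = 6))
  co <- sim$cohort
  mrna <- generateMrna(sim$truth, co, seed = 3)
  db <- generateInteractionDB(sim$truth, 50, 10, seed = 4)
  starUnion <- c(sim$truth@fourStar, unlist(sim$truth@oneStar))

  ref <- refineNetwork(starUnion, db, logExpr(co), mrna)
  circuitMirnas <- unique(sim$truth@plantedCircuits$mirna)
  expect_true(all(circuitMirnas %in% ref@mirnas))

  # monotone restrictions between steps
  s <- ref@steps
  expect_true(all(s$step6 %in% intersect(s$step2, s$step5)))
  expect_true(all(s$step8 %in% intersect(s$step7, s$step1)))
  expect_true(all(s$step11 %in% s$step3))
  expect_true(all(s$step3 %in% starUnion))
  expect_true(all(s$step9 %in% s$step8))
  expect_true(all(ref@corrReport$r[ref@corrReport$kept] < -0.3))

  # idempotence on its own output
  ref2 <- refineNetwork(ref@mirnas, db, logExpr(co), mrna)
  expect_setequal(ref2@mirnas, ref@mirnas)
  expect_setequal(ref2@genes, ref@genes)
  expect_setequal(ref2@tfs, ref@tfs)

  # a more negative threshold can only shrink the step-9 gene set
  refTight <- refineNetwork(starUnion, db, logExpr(co), mrna,
                            corrThreshold = -0.45)
  expect_true(all(refTight@genes %in% ref@genes))

  # circuits match the brute-force enumeration and the manifest
  circ <- detectCircuits(ref, db)
  expect_equal(circ, bruteForceCircuits(db))

  # empty db: everything empty
  emptyDb <- interactionDB(db@mirnaTargets[0, ], db@tfMirna[0, ],
                           db@tfGene[0, ])
  ref0 <- refineNetwork(starUnion, emptyDb, logExpr(co), mrna)
  expect_true(all(lengths(ref0@steps) == 0))
})

test_that("a positively correlated target gene is removed at the correlation step", {
  sim <- generateCohort(cohortConfig(seed = 7, nCircuits = 2))
  truth <- sim$truth
  # flip one companion gene's target correlation to +0.5
  flip <- which(!truth@anticorrelatedPairs$gene %in%
                truth@plantedCircuits$symbol)[1]
  flippedGene <- truth@anticorrelatedPairs$gene[flip]
  truth@anticorrelatedPairs$r[flip] <- +0.5
  mrna <- generateMrna(truth, sim$cohort, seed = 5)
  db <- generateInteractionDB(truth, 20, 5, seed = 6)
  ref <- refineNetwork(c(truth@fourStar, unlist(truth@oneStar)), db,
                       logExpr(sim$cohort), mrna)
  expect_true(flippedGene %in% ref@steps$step8)
  expect_false(flippedGene %in% ref@steps$step9)
})

test_that("circuit detection equals exhaustive enumeration on random databases", {
  set.seed(41)
  mirPool <- paste0("miR-", 1:12)
  symPool <- paste0("SYM", 1:15)
  for (rep in 1:20) {
    nE <- sample(10:60, 1)  # three tables, well under 200 edges total
    db <- interactionDB(
      data.frame(m = sample(mirPool, nE, TRUE), g = sample(symPool, nE, TRUE)),
      data.frame(tf = sample(symPool, nE, TRUE), m = sample(mirPool, nE, TRUE)),
      data.frame(tf = sample(symPool, nE, TRUE), g = sample(symPool, nE, TRUE)))
    # refinement-free detection: treat every symbol/miRNA as refined
    ref <- methods::new("RefinedSets",
                        steps = list(), mirnas = mirPool,
                        genes = symPool, tfs = symPool,
                        corrReport = data.frame())
    expect_equal(detectCircuits(ref, db), bruteForceCircuits(db))
  }
})

test_that("network assembly counts reconcile with the refined sets", {
  sim <- generateCohort(cohortConfig(seed = 8))
  mrna <- generateMrna(sim$truth, sim$cohort, seed = 1)
  db <- generateInteractionDB(sim$truth, 40, 10, seed = 2)
  ref <- refineNetwork(c(sim$truth@fourStar, unlist(sim$truth@oneStar)),
                       db, logExpr(sim$cohort), mrna)
  dir <- withr::local_tempdir()
  net <- buildNetwork(ref, db, dir = dir)
  expect_true(all(file.exists(net$files)))
  expect_gte(igraph::vcount(net$full), igraph::vcount(net$loops))
  circ <- detectCircuits(ref, db)
  expect_equal(igraph::vcount(net$loops),
               length(unique(c(circ$mirna, circ$symbol))))
  expect_equal(igraph::ecount(net$loops), 2 * nrow(circ))
  types <- igraph::V(net$full)$type
  expect_setequal(unique(types), c("miRNA", "gene", "TF"))

  # one-circuit graph: 2 nodes, 2 edges
  db1 <- interactionDB(data.frame(m = "hsa-miR-100-5p", g = "TP53"),
                       data.frame(tf = "TP53", m = "hsa-miR-100-5p"),
                       data.frame(tf = "TP53", g = "CCND1"))
  ref1 <- methods::new("RefinedSets", steps = list(),
                       mirnas = "hsa-miR-100-5p", genes = "CCND1",
                       tfs = "TP53", corrReport = data.frame())
  net1 <- buildNetwork(ref1, db1)
  expect_equal(igraph::vcount(net1$loops), 2)
  expect_equal(igraph::ecount(net1$loops), 2)
  circ1 <- detectCircuits(ref1, db1)
  expect_equal(circ1,
               data.frame(mirna = "hsa-miR-100-5p", symbol = "TP53"))
})

test_that("PPI degrees follow the handshake identity and flag hubs", {
  tri <- ppiDegrees(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  expect_true(all(tri$degree == 2))

  star <- ppiDegrees(data.frame(a = "HUB", b = paste0("L", 1:5)))
  expect_equal(star$degree[star$node == "HUB"], 5)
  expect_true(star$hub[star$node == "HUB"])
  expect_true(all(star$degree[star$node != "HUB"] == 1))

  set.seed(3)
  e <- unique(data.frame(a = sample(LETTERS[1:10], 40, TRUE),
                         b = sample(LETTERS[1:10], 40, TRUE)))
  e <- e[e$a != e$b, ]
  key <- ifelse(e$a < e$b, paste(e$a, e$b), paste(e$b, e$a))
  e <- e[!duplicated(key), ]
  deg <- ppiDegrees(e)
  expect_equal(sum(deg$degree), 2 * nrow(e))

  expect_warning(d2 <- ppiDegrees(data.frame(a = c("A", "A"),
                                             b = c("A", "B"))),
                 "self-loop")
  expect_equal(d2$degree, c(1L, 1L))
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- paste0("g", 1:20)
  term <- universe[1:5]
  query <- c(universe[1:4], universe[10])
  res <- oraEnrichment(query, universe, list(TERM = term), qCutoff = 0.05)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)

  # independent enumeration over all 5-subsets of the universe
  allSub <- utils::combn(20, 5)
  hits <- sum(colSums(allSub <= 5) >= 4)
  expect_equal(res$p, hits / ncol(allSub), tolerance = 1e-12)

  # zero overlap with a small term is never significant
  res0 <- oraEnrichment(universe[10:12], universe, list(T = universe[1:3]))
  expect_equal(res0$overlap, 0)
  expect_false(res0$significant)
  expect_gt(res0$p, 0.4)

  # query = universe: maximal overlap is certain, p = 1
  resAll <- oraEnrichment(universe, universe, list(T = term))
  expect_equal(resAll$p, 1)

  expect_error(oraEnrichment(character(0), universe, list(T = term)),
               "empty query")
  expect_error(oraEnrichment("not-there", universe, list(T = term)),
               "subset")

  # BH q-values are monotone in raw p
  set.seed(19)
  sets <- lapply(1:8, function(i) sample(universe, sample(3:8, 1)))
  names(sets) <- paste0("T", 1:8)
  resM <- oraEnrichment(sample(universe, 6), universe, sets)
  expect_true(all(diff(resM$q[order(resM$p)]) >= -1e-12))
})

test_that("GMT gene sets round-trip through the reader", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("pathA\tdesc\tTP53\tMYC\tBRCA1",
               "pathB\tdesc\tESR1\tMYC"), gmt)
  sets <- readGeneSets(gmt)
  expect_equal(sets$pathA, c("TP53", "MYC", "BRCA1"))
  expect_equal(sets$pathB, c("ESR1", "MYC"))
})
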