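test_that("cohort generation is reproducible and matches configured sizes", {
  cfg <- smallConfig(seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(rpm(a$cohort), rpm(b$cohort))
  expect_identical(clinicalData(a$cohort), clinicalData(b$cohort))
  expect_identical(a$truth@fourStar, b$truth@fourStar)

  tab <- table(subtypes(a$cohort))
  expect_equal(as.integer(tab[names(cfg$subtypeSizes)]),
               unname(cfg$subtypeSizes))
  expect_equal(nrow(rpm(a$cohort)), cfg$nMirnas)
})

test_that("default configuration reproduces the reference cohort structure", {
  sim <- generateCohort(cohortConfig(seed = 1))
  st <- subtypes(sim$cohort)
  expect_equal(ncol(rpm(sim$cohort)), 231)
  expect_equal(sum(st != "Control"), 190)
  expect_equal(sum(st == "Control"), 41)
  expect_equal(length(sim$truth@fourStar), 44)
  expect_equal(lengths(sim$truth@oneStar),
               c(LA = 12L, LB = 12L, HER2E = 12L, BL = 12L))
})

test_that("clinical and expression values respect their domains", {
  sim <- generateCohort(smallConfig(3))
  cl <- clinicalData(sim$cohort)
  expect_true(all(cl$days >= 0))
  expect_true(all(cl$status %in% c("alive", "dead")))
  expect_true(all(rpm(sim$cohort) >= 0))
  # null miRNAs carry zeros at roughly the configured rate
  nulls <- setdiff(rownames(rpm(sim$cohort)),
                   c(sim$truth@fourStar, unlist(sim$truth@oneStar)))
  zf <- mean(rpm(sim$cohort)[nulls, ] == 0)
  expect_lt(abs(zf - 0.2), 0.05)
})

test_that("zero-effect configuration plants nothing", {
  cfg <- cohortConfig(subtypeSizes = c(LA = 10, Control = 8),
                      nMirnas = 20, nFourStar = 0,
                      nOneStarPerSubtype = 0, nCircuits = 0,
                      nStageShift = 0, seed = 2)
  sim <- generateCohort(cfg)
  expect_length(sim$truth@fourStar, 0)
  expect_true(all(lengths(sim$truth@oneStar) == 0))
  expect_equal(nrow(sim$truth@plantedCircuits), 0)
})

test_that("configuration errors are rejected", {
  expect_error(cohortConfig(baselineHazard = 0), "configuration error")
  expect_error(cohortConfig(effectHr = -1), "configuration error")
  expect_error(cohortConfig(nMirnas = 10, nFourStar = 20),
               "configuration error")
  expect_error(cohortConfig(subtypeSizes = c(LA = 5)), "Control")
})

test_that("with no planted effect the ranking cannot tell planted from null", {
  cfg <- cohortConfig(subtypeSizes = c(LA = 40, Control = 30),
                      nMirnas = 100, nFourStar = 5,
                      nOneStarPerSubtype = 0, nCircuits = 0,
                      nStageShift = 0, effectHr = 1)
  k <- 20
  hits <- 0; total <- 0
  for (sd in 1:30) {
    cfg$seed <- sd
    sim <- generateCohort(cfg)
    top <- rankTopK(scoreSubtype(sim$cohort, "LA"), k)
    hits <- hits + sum(sim$truth@fourStar %in% top)
    total <- total + length(sim$truth@fourStar)
  }
  chance <- k / cfg$nMirnas
  se <- sqrt(chance * (1 - chance) / total)
  expect_lt(abs(hits / total - chance), 4 * se)
})

test_that("mRNA generation hits the target anti-correlation", {
  sim <- generateCohort(cohortConfig(seed = 5))
  mrna <- generateMrna(sim$truth, sim$cohort, seed = 7)
  pairs <- sim$truth@anticorrelatedPairs
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    r <- cor(logExpr(sim$cohort)[pairs$mirna[i], ], mrna[pairs$gene[i], ])
    expect_gt(r, -0.65); expect_lt(r, -0.35)
  }
  # non-planted genes are independent noise
  r0 <- cor(logExpr(sim$cohort)[pairs$mirna[1], ], mrna["NOISE01", ])
  expect_lt(abs(r0), 0.25)
})

test_that("mRNA generation handles degenerate and invalid inputs", {
  sim <- generateCohort(smallConfig(4))
  truth0 <- methods::new("SyntheticTruth", fourStar = character(0),
                         oneStar = list(),
                         anticorrelatedPairs = data.frame(
                           mirna = character(0), gene = character(0),
                           r = numeric(0)),
                         plantedCircuits = data.frame(
                           mirna = character(0), symbol = character(0)),
                         stageShiftIds = character(0))
  m0 <- generateMrna(truth0, sim$cohort, seed = 1)
  expect_equal(nrow(m0), 20)  # only the default noise genes

  # target correlation -1 is an exact affine decreasing transform
  m <- sim$truth@fourStar[1]
  truth1 <- truth0
  truth1@anticorrelatedPairs <- data.frame(mirna = m, gene = "G1", r = -1)
  m1 <- generateMrna(truth1, sim$cohort, seed = 1)
  expect_lte(cor(logExpr(sim$cohort)[m, ], m1["G1", ]), -0.99)

  truthBad <- truth0
  truthBad@anticorrelatedPairs <- data.frame(mirna = "no-such-mir",
                                             gene = "G1", r = -0.5)
  expect_error(generateMrna(truthBad, sim$cohort), "unknown miRNA")
})

test_that("interaction tables contain exactly the planted circuits", {
  sim <- generateCohort(cohortConfig(seed = 2, nCircuits = 5))
  db <- generateInteractionDB(sim$truth, nDecoyGenes = 50,
                              nDecoyTfs = 10, seed = 3)
  found <- bruteForceCircuits(db)
  planted <- sim$truth@plantedCircuits
  planted <- planted[order(planted$mirna, planted$symbol), ]
  rownames(planted) <- NULL
  expect_equal(found, planted)
  expect_equal(nrow(found), 5)

  # zero circuits, zero decoys: three empty tables
  truth0 <- sim$truth
  truth0@plantedCircuits <- planted[0, ]
  truth0@fourStar <- character(0); truth0@oneStar <- list()
  db0 <- generateInteractionDB(truth0, 0, 0, seed = 1)
  expect_equal(nrow(db0@mirnaTargets), 0)
  expect_equal(nrow(db0@tfMirna), 0)
  expect_equal(nrow(db0@tfGene), 0)
})

test_that("stage labels stage tumors only and plant the stage-II shift", {
  sim <- generateCohort(smallConfig(6))
  staged <- generateStageLabels(sim$cohort, sim$truth, shift = 2, seed = 9)
  cl <- clinicalData(staged)
  expect_true(all(is.na(cl$stage[cl$subtype == "Control"])))
  tumorStages <- cl$stage[cl$subtype != "Control"]
  expect_true(all(tumorStages %in% c("IA", "IB", "IIA", "IIB")))

  le <- logExpr(staged)
  sI <- rownames(cl)[!is.na(cl$stage) & cl$stage %in% c("IA", "IB")]
  sII <- rownames(cl)[!is.na(cl$stage) & cl$stage %in% c("IIA", "IIB")]
  for (m in sim$truth@stageShiftIds) {
    gap <- mean(le[m, sII]) - mean(le[m, sI])
    expect_gt(gap, 1)  # planted gap of 2 minus sampling noise
  }

  # cohort with no tumors: nothing staged
  cfg <- cohortConfig(subtypeSizes = c(LA = 0, Control = 10), nMirnas = 5,
                      nFourStar = 0, nOneStarPerSubtype = 0,
                      nCircuits = 0, nStageShift = 0, seed = 1)
  simC <- generateCohort(cfg)
  stagedC <- generateStageLabels(simC$cohort, simC$truth, shift = 1)
  expect_true(all(is.na(clinicalData(stagedC)$stage)))
})

test_that("truth manifests and cohort files round-trip through disk", {
  sim <- generateCohort(smallConfig(8))
  dir <- withr::local_tempdir()
  writeTruth(sim$truth, file.path(dir, "truth.json"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$four_star, sim$truth@fourStar)

  writeCohort(sim$cohort, dir)
  back <- readCohort(file.path(dir, "cohort_expression.tsv"),
                     file.path(dir, "cohort_clinical.tsv"))
  expect_equal(dim(rpm(back)), dim(rpm(sim$cohort)))
  expect_equal(rpm(back), rpm(sim$cohort), tolerance = 1e-8)
  expect_equal(subtypes(back), subtypes(sim$cohort))
})
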