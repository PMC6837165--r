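# Shared fixture builders: everything is generated in code at test time.

# Right-censored exponential arm: returns durations/events.
simArm <- function(n, rate, censorMax = 3000) {
  t <- stats::rexp(n, rate)
  c <- stats::runif(n, 0, censorMax)
  list(durations = pmin(t, c), events = t <= c)
}

# A small hand-built cohort with fully controlled expression rows.
tinyCohort <- function(nPerGroup = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerGroup
  expr <- rbind(
    flat = rep(3, n),                      # degenerate: all values tied
    noisy = 2^rnorm(n, 5, 1),              # null expression
    marker = 2^c(rnorm(nPerGroup, 8, 0.3), # high in tumors
                 rnorm(nPerGroup, 4, 0.3)))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  cl <- data.frame(
    sample_id = colnames(expr),
    subtype = rep(c("LA", "Control"), each = nPerGroup),
    status = rep(c("dead", "alive"), n / 2),
    days = 100 + seq_len(n) * 10,
    age = 55, stage = NA_character_)
  MirnaCohort(expr, cl)
}

# Reference scoring of one subtype's top-k, used to cross-check the
# ranking path end to end.
smallConfig <- function(seed = 1) {
  cohortConfig(subtypeSizes = c(LA = 30, LB = 20, HER2E = 16, BL = 20,
                                Control = 20),
               nMirnas = 60, nFourStar = 6, nOneStarPerSubtype = 2,
               nCircuits = 3, nStageShift = 3, seed = seed)
}

# Brute-force circuit enumeration: scan every miRNA->gene edge and look
# for the reciprocal TF->miRNA edge; independent of detectCircuits().
bruteForceCircuits <- function(db) {
  mt <- db@mirnaTargets; tm <- db@tfMirna
  hits <- list()
  for (i in seq_len(nrow(mt))) {
    for (j in seq_len(nrow(tm))) {
      if (mt$gene[i] == tm$tf[j] && mt$mirna[i] == tm$mirna[j])
        hits[[length(hits) + 1L]] <- data.frame(mirna = mt$mirna[i],
                                                symbol = mt$gene[i])
    }
  }
  if (!length(hits))
    return(data.frame(mirna = character(0), symbol = character(0)))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$mirna, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
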