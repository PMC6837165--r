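#' The default registry of seven classifier families
#'
#' Each entry is a list with \code{fit(x, y)} and
#' \code{predict(model, x)} closures plus the recorded hyperparameters.
#' The families are logistic regression (LR), decision tree (DT),
#' single-hidden-layer neural network (ANN), linear-kernel support
#' vector machine (SVM), k-nearest neighbours (K-NN), random forest
#' (RF) and Gaussian naive Bayes (NB), each at its library defaults
#' (recorded in \code{params}); entries can be replaced or dropped to
#' inject exact settings.
#'
#' @param hidden hidden-layer size for the neural network.
#' @param k neighbours for K-NN.
#' @param ntree trees for the random forest.
#' @return named list of classifier entries.
#' @export
classifierRegistry <- function(hidden = 5, k = 5, ntree = 200) {
  list(
    LR = list(params = list(),
      fit = function(x, y) suppressWarnings(
        stats::glm(y ~ ., data = data.frame(x, y = y),
                   family = stats::binomial())),
      predict = function(m, x) factor(
        ifelse(suppressWarnings(
          stats::predict(m, data.frame(x), type = "response")) > 0.5,
          levels(m$model$y)[2], levels(m$model$y)[1]),
        levels = levels(m$model$y))),
    DT = list(params = list(),
      fit = function(x, y) rpart::rpart(y ~ ., data.frame(x, y = y),
                                        method = "class"),
      predict = function(m, x) stats::predict(m, data.frame(x),
                                              type = "class")),
    ANN = list(params = list(size = hidden, decay = 0.01, maxit = 200),
      fit = function(x, y) nnet::nnet(y ~ ., data.frame(x, y = y),
                                      size = hidden, decay = 0.01,
                                      maxit = 200, trace = FALSE),
      predict = function(m, x) factor(
        stats::predict(m, data.frame(x), type = "class"),
        levels = m$lev)),
    SVM = list(params = list(kernel = "linear"),
      fit = function(x, y) e1071::svm(x, y, kernel = "linear"),
      predict = function(m, x) stats::predict(m, x)),
    `K-NN` = list(params = list(k = k),
      fit = function(x, y) list(x = x, y = y, k = k),
      predict = function(m, x) class::knn(m$x, x, m$y, k = m$k)),
    RF = list(params = list(ntree = ntree),
      fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree),
      predict = function(m, x) stats::predict(m, x)),
    NB = list(params = list(),
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict = function(m, x) stats::predict(m, x)))
}

#' Build a labeled classification task from star sets
#'
#' For \code{kind = "tumor-vs-control"} (the four-star task) every
#' tumor is positive and every control negative; for
#' \code{kind = "subtype-vs-rest"} (one-star tasks) the given subtype's
#' tumors are positive and all other samples — other subtypes and
#' controls — negative. Features are the panel miRNAs' log2(rpm + 1)
#' expression.
#'
#' @param features character vector of panel miRNA ids.
#' @param cohort a \linkS4class{MirnaCohort}.
#' @param kind the task type.
#' @param subtype positive-class subtype for "subtype-vs-rest".
#' @return list with \code{x} (samples x features matrix), \code{y}
#'   (factor neg/pos), \code{kind}, \code{subtype}, \code{features}.
#' @export
buildTask <- function(features, cohort,
                      kind = c("tumor-vs-control", "subtype-vs-rest"),
                      subtype = NULL) {
  kind <- match.arg(kind)
  stopifnot(methods::is(cohort, "MirnaCohort"))
  features <- intersect(features, rownames(rpm(cohort)))
  if (!length(features)) stop("empty feature list")
  st <- subtypes(cohort)
  y <- if (kind == "tumor-vs-control") st != "Control" else {
    if (is.null(subtype)) stop("subtype required for subtype-vs-rest")
    st == subtype
  }
  if (!any(y) || all(y)) stop("a class has 0 samples")
  list(x = t(logExpr(cohort)[features, , drop = FALSE]),
       y = factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")),
       kind = kind, subtype = subtype, features = features)
}

## Stratified fold assignment: within each class, samples are shuffled
## and dealt round-robin into folds.
.stratifiedFolds <- function(y, folds, seed) {
  if (folds < 2) stop("folds must be >= 2")
  if (any(table(y) < folds))
    stop("a class has fewer samples than folds; cannot stratify")
  set.seed(seed)
  assign <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated accuracy per classifier
#'
#' Folds are stratified by class and fixed by the seed; accuracy is the
#' overall fraction of correct test predictions pooled over the k
#' folds. The table carries one column per classifier plus their
#' arithmetic mean.
#'
#' @param task from \code{\link{buildTask}}.
#' @param registry classifier registry
#'   (default \code{\link{classifierRegistry}()}).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed (default 0).
#' @return one-row data.frame: per-classifier accuracies and
#'   \code{Average}.
#' @export
crossValidate <- function(task, registry = classifierRegistry(),
                          folds = 5, seed = 0) {
  fold <- .stratifiedFolds(task$y, folds, seed)
  acc <- vapply(names(registry), function(nm) {
    entry <- registry[[nm]]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      set.seed(seed * 1000L + f)  # for stochastic learners
      model <- entry$fit(task$x[tr, , drop = FALSE], task$y[tr])
      pred <- entry$predict(model, task$x[te, , drop = FALSE])
      correct <- correct + sum(as.character(pred) ==
                               as.character(task$y[te]))
    }
    correct / length(task$y)
  }, numeric(1))
  out <- as.data.frame(as.list(acc), check.names = FALSE)
  out$Average <- mean(acc)
  out
}

#' Compare miRNA panels on one classification task
#'
#' Runs the same cross-validation for each named panel (after
#' intersecting with available features) and returns one accuracy row
#' per panel, sorted by average accuracy. Panels with no available
#' features are skipped with a warning; duplicate names are suffixed
#' deterministically.
#'
#' @param panels named list of miRNA id vectors.
#' @param cohort a \linkS4class{MirnaCohort}.
#' @param kind,subtype task definition as in \code{\link{buildTask}}.
#' @param registry,folds,seed as in \code{\link{crossValidate}}.
#' @return data.frame with columns panel, n_features, one column per
#'   classifier, Average; attribute \code{skipped} lists skipped
#'   panels.
#' @export
comparePanels <- function(panels, cohort, kind = "tumor-vs-control",
                          subtype = NULL,
                          registry = classifierRegistry(), folds = 5,
                          seed = 0) {
  names(panels) <- make.unique(names(panels), sep = "_")
  available <- rownames(rpm(cohort))
  skipped <- character(0)
  rows <- list()
  for (nm in names(panels)) {
    feats <- intersect(panels[[nm]], available)
    if (!length(feats)) {
      warning("panel '", nm, "' has no available features; skipped")
      skipped <- c(skipped, nm)
      next
    }
    task <- buildTask(feats, cohort, kind = kind, subtype = subtype)
    cv <- crossValidate(task, registry, folds = folds, seed = seed)
    rows[[nm]] <- cbind(data.frame(panel = nm,
                                   n_features = length(feats)), cv)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(-out$Average, out$panel), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(panel = character(0), n_features = integer(0))
  }
  attr(out, "skipped") <- skipped
  out
}
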