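## Classifier evaluation: confusion matrix, K-fold cross-validation,
## leave-one-out, bootstrap and one-vs-rest ROC/AUC. Resampling re-fits
## only the classifier on the already-fixed feature columns; the feature
## selection or extraction stage is never re-run inside a replicate (it has
## its own evaluation criterion), so these estimates can be slightly
## optimistic when many features were screened.

subsetRows <- function(dm, rows) {
  new("DesignMatrix", X = dm@X[rows, , drop = FALSE], y = dm@y[rows],
      caseIds = dm@caseIds[rows],
      tissueTypes = if (length(dm@tissueTypes)) dm@tissueTypes[rows]
        else character(),
      featureDataset = dm@featureDataset,
      featurePpm = dm@featurePpm, classNames = dm@classNames,
      classDefs = dm@classDefs)
}

## Re-fit LDA on a row subset, tolerating single-member classes and muffling
## the singular-scatter warning (one warning per run is enough).
refitLDA <- function(dm, rows, priors = "frequency") {
  withCallingHandlers(
    fitFisherLDA(subsetRows(dm, rows), priors = priors, .minPerClass = 1L),
    mrsWarning = function(w) invokeRestart("muffleWarning"))
}

replicateSummary <- function(method, accs, perClassAcc, seed, details = list()) {
  new("ResamplingResult", method = method, perReplicate = accs,
      overallMean = mean(accs),
      overallSd = if (length(accs) > 1L) sd(accs) else 0,
      perClassMean = apply(perClassAcc, 2L, mean, na.rm = TRUE),
      perClassSd = apply(perClassAcc, 2L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1L) sd(v) else 0
      }),
      nReplicates = length(accs), seed = as.integer(seed), details = details)
}

#' Confusion matrix
#'
#' Rows are predicted classes, columns actual classes: a class that
#' actually contains 58 cases of which 52 are predicted correctly
#' contributes 52 to the diagonal and 58 to its column sum.
#'
#' @param actual,predicted equal-length class labels: integer indices into
#'   \code{classNames}, or the names themselves.
#' @param classNames the defined class names.
#' @return a \linkS4class{ConfusionMatrix}; see [accuracy()].
#' @export
confusionMatrix <- function(actual, predicted, classNames) {
  toIdx <- function(v, what) {
    if (is.numeric(v)) {
      v <- as.integer(v)
      if (any(v < 1L | v > length(classNames)))
        mrsStop("UnknownLabel", sprintf("%s label out of range", what))
      v
    } else {
      i <- match(as.character(v), classNames)
      if (anyNA(i)) mrsStop("UnknownLabel", sprintf(
        "unknown %s label '%s'", what, as.character(v)[which(is.na(i))[1L]]))
      i
    }
  }
  a <- toIdx(actual, "actual"); p <- toIdx(predicted, "predicted")
  if (length(a) != length(p))
    mrsStop("UnknownLabel", "actual and predicted differ in length")
  C <- length(classNames)
  m <- matrix(0L, C, C)
  for (i in seq_along(a)) m[p[i], a[i]] <- m[p[i], a[i]] + 1L
  new("ConfusionMatrix", counts = m, classNames = classNames)
}

## Stratified fold assignment: cases grouped by class (shuffled within
## class), fold labels cycled over the concatenated order so fold sizes are
## balanced and every class is spread across folds. Folds are reported in a
## canonical order (by smallest case index in the test fold); with K = n
## this makes the replicates line up one-to-one with leave-one-out.
stratifiedFolds <- function(y, K, shuffle = TRUE) {
  ord <- unlist(lapply(sort(unique(y)), function(c) {
    members <- which(y == c)
    if (shuffle && length(members) > 1L) sample(members) else members
  }))
  fold <- integer(length(y))
  fold[ord] <- rep_len(seq_len(K), length(y))
  byFold <- split(seq_along(y), fold)
  byFold[order(vapply(byFold, min, integer(1L)))]
}

#' K-fold cross-validation
#'
#' Stratified partition by class; each fold serves once as the test set
#' while the classifier is re-fitted on the remaining folds (on the fixed
#' feature columns). A partition that leaves a training split without any
#' member of some class is rejected and re-stratified. Results are
#' reproducible bit-for-bit given the seed.
#'
#' @param dm a \linkS4class{DesignMatrix}.
#' @param K number of folds, between 2 and the number of cases.
#' @param seed RNG seed for the stratified shuffle.
#' @param priors passed to the per-fold fit.
#' @return a \linkS4class{ResamplingResult} with per-fold accuracies (%).
#' @export
kfoldCV <- function(dm, K = 10L, seed = 1L, priors = "frequency") {
  n <- nrow(dm@X)
  C <- length(dm@classNames)
  K <- as.integer(K)
  if (K < 2L || K > n)
    mrsStop("TooFewCases", "K must be between 2 and the number of cases")
  if (any(tabulate(dm@y, nbins = C) < 2L))
    mrsStop("TooFewCases", "every class needs at least 2 cases")
  set.seed(as.integer(seed))
  folds <- NULL
  for (attempt in seq_len(100L)) {
    cand <- stratifiedFolds(dm@y, K, shuffle = K < n)
    ok <- all(vapply(cand, function(test)
      length(unique(dm@y[-test])) == C, logical(1L)))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds))
    mrsStop("TooFewCases", "could not stratify folds with all classes")

  accs <- numeric(length(folds))
  perClass <- matrix(NA_real_, length(folds), C)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    model <- refitLDA(dm, setdiff(seq_len(n), test), priors)
    pred <- predict(model, dm@X[test, , drop = FALSE])
    accs[f] <- 100 * mean(pred == dm@y[test])
    for (c in unique(dm@y[test]))
      perClass[f, c] <- 100 * mean(pred[dm@y[test] == c] == c)
  }
  replicateSummary("kfold", accs, perClass, seed, details = list(K = K))
}

#' Leave-one-out cross-validation
#'
#' Each case in turn is held out and predicted by a classifier fitted on
#' the remaining cases. Deterministic (no RNG); identical to K-fold
#' cross-validation with K equal to the number of cases.
#'
#' @param dm a \linkS4class{DesignMatrix}.
#' @param priors passed to the per-replicate fit.
#' @return a \linkS4class{ResamplingResult} with n replicates.
#' @export
loo <- function(dm, priors = "frequency") {
  n <- nrow(dm@X)
  C <- length(dm@classNames)
  if (n < C + 2L) mrsStop("TooFewCases", "too few cases for leave-one-out")
  if (any(tabulate(dm@y, nbins = C) < 2L))
    mrsStop("TooFewCases", "every class needs at least 2 cases")
  accs <- numeric(n)
  perClass <- matrix(NA_real_, n, C)
  for (i in seq_len(n)) {
    model <- refitLDA(dm, setdiff(seq_len(n), i), priors)
    pred <- predict(model, dm@X[i, , drop = FALSE])
    accs[i] <- 100 * (pred == dm@y[i])
    perClass[i, dm@y[i]] <- accs[i]
  }
  replicateSummary("loo", accs, perClass, seed = NA_integer_)
}

#' Bootstrap error estimation
#'
#' Each replicate draws n cases with replacement (a bootstrap sample of the
#' same size as the training set), re-fits the classifier on the resample
#' and scores it on the out-of-bag cases (those not drawn). Replicates
#' whose resample misses a class entirely, or whose out-of-bag set is
#' empty, are redrawn (the count is recorded in \code{details$redraws}).
#' With \code{evalOn = "full"} each replicate is scored on the complete
#' original set instead of the out-of-bag cases.
#'
#' @param dm a \linkS4class{DesignMatrix}.
#' @param N number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param evalOn "oob" (default) or "full".
#' @param priors passed to the per-replicate fit.
#' @return a \linkS4class{ResamplingResult}; \code{details} records the
#'   mean out-of-bag fraction and the redraw count.
#' @export
bootstrapEval <- function(dm, N = 1000L, seed = 1L,
                          evalOn = c("oob", "full"), priors = "frequency") {
  evalOn <- match.arg(evalOn)
  n <- nrow(dm@X)
  C <- length(dm@classNames)
  if (n < C + 2L) mrsStop("TooFewCases", "too few cases for bootstrap")
  set.seed(as.integer(seed))
  accs <- numeric(N)
  perClass <- matrix(NA_real_, N, C)
  oobFrac <- numeric(N)
  redraws <- 0L
  for (b in seq_len(N)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(dm@y[idx])) == C && length(oob) > 0L) break
      redraws <- redraws + 1L
      if (redraws > 1000L * N)
        mrsStop("TooFewCases", "bootstrap resampling keeps losing a class")
    }
    oobFrac[b] <- length(oob) / n
    test <- if (evalOn == "oob") oob else seq_len(n)
    model <- refitLDA(dm, idx, priors)
    pred <- predict(model, dm@X[test, , drop = FALSE])
    accs[b] <- 100 * mean(pred == dm@y[test])
    for (c in unique(dm@y[test]))
      perClass[b, c] <- 100 * mean(pred[dm@y[test] == c] == c)
  }
  replicateSummary("bootstrap", accs, perClass, seed,
                   details = list(N = N, evalOn = evalOn,
                                  meanOobFraction = mean(oobFrac),
                                  redraws = redraws))
}

#' Binary ROC curve and AUC
#'
#' The discrimination threshold is swept over the unique scores in
#' descending order; tied scores form a single step (under which the
#' trapezoidal AUC equals the Mann-Whitney concordant-pair statistic). The
#' curve runs monotonically from (0, 0) to (1, 1).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param positives logical (or 0/1) labels; both values must be present.
#' @return list with \code{fpr}, \code{tpr} and \code{auc}.
#' @export
rocCurve <- function(scores, positives) {
  positives <- as.logical(positives)
  nP <- sum(positives); nN <- sum(!positives)
  if (nP == 0L || nN == 0L)
    mrsStop("OneClassOnly", "both label values must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- positives[ord]
  lastOfGroup <- c(s[-1L] != s[-length(s)], TRUE)   # tied scores: one step
  tp <- cumsum(lab)[lastOfGroup]
  fp <- cumsum(!lab)[lastOfGroup]
  tpr <- c(0, tp / nP)
  fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Per-class ROC by dichotomisation
#'
#' A multiclass classifier is evaluated by one binary ROC per class: the
#' positives are that class's cases and the score is its posterior
#' probability (one-vs-rest dichotomisation).
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param dm a labelled \linkS4class{DesignMatrix}.
#' @return a \linkS4class{RocResult} with per-class curves and AUCs.
#' @export
multiclassRoc <- function(model, dm) {
  post <- posteriorProbabilities(model, projectCases(model, dm))
  perClass <- lapply(seq_along(model@classNames), function(c)
    rocCurve(post[, c], dm@y == c))
  names(perClass) <- model@classNames
  new("RocResult", perClass = perClass)
}
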