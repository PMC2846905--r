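test_that("confusion matrix orientation: rows predicted, columns actual", {
  cm <- confusionMatrix(actual = c("A", "A", "B"),
                        predicted = c("A", "B", "B"),
                        classNames = c("A", "B"))
  expect_identical(counts(cm), matrix(c(1L, 1L, 0L, 1L), 2, 2))

  perfect <- confusionMatrix(1:3, 1:3, c("x", "y", "z"))
  expect_true(all(counts(perfect)[upper.tri(counts(perfect))] == 0))
  expect_identical(accuracy(perfect), 100)

  # a class with 58 actual members, 52 predicted correctly: 52 on the
  # diagonal, 58 in its column sum
  actual <- rep(1L, 58)
  predicted <- c(rep(1L, 52), rep(2L, 5), 3L)
  cm58 <- confusionMatrix(c(actual, 2L, 3L), c(predicted, 2L, 3L),
                          c("a", "b", "c"))
  expect_identical(counts(cm58)[1, 1], 52L)
  expect_identical(sum(counts(cm58)[, 1]), 58L)

  expect_error(confusionMatrix(c("A", "Q"), c("A", "A"), c("A", "B")),
               class = "UnknownLabel")
})

test_that("K-fold CV: perfect on separated data, reproducible, stratified", {
  dm <- separatedDesignMatrix(12L, 12L)
  for (K in c(2L, 4L, 8L)) {
    r <- kfoldCV(dm, K = K, seed = 3L)
    expect_identical(r@overallMean, 100)
    expect_identical(r@overallSd, 0)
    expect_identical(r@nReplicates, K)
  }
  noisy <- randomDesignMatrix(n = 30L, C = 3L, seed = 9L, sep = 1.2)
  a <- kfoldCV(noisy, K = 5L, seed = 11L)
  b <- kfoldCV(noisy, K = 5L, seed = 11L)
  expect_identical(a@perReplicate, b@perReplicate)
  c2 <- kfoldCV(noisy, K = 5L, seed = 12L)
  expect_identical(length(c2@perReplicate), 5L)

  expect_error(kfoldCV(dm, K = 1L), class = "TooFewCases")
  expect_error(kfoldCV(dm, K = 25L), class = "TooFewCases")
})

test_that("leave-one-out equals K-fold with K = n, replicate by replicate", {
  for (seed in 1:4) {
    dm <- randomDesignMatrix(n = 21L, C = 3L, seed = seed, sep = 1.5)
    lo <- loo(dm)
    kf <- kfoldCV(dm, K = nCases(dm), seed = seed)
    expect_identical(lo@perReplicate, kf@perReplicate)
    expect_identical(lo@nReplicates, nCases(dm))
  }
  sep <- separatedDesignMatrix(3L, 3L)
  expect_identical(loo(sep)@overallMean, 100)
})

test_that("bootstrap scores out-of-bag cases and logs the OOB fraction", {
  dm <- separatedDesignMatrix(10L, 10L)
  r <- bootstrapEval(dm, N = 60L, seed = 5L)
  expect_identical(r@overallMean, 100)
  expect_identical(r@overallSd, 0)
  expect_identical(r@nReplicates, 60L)
  expect_identical(r@perClassMean, c(100, 100))

  # same seed, same replicates; different seed allowed to differ
  r2 <- bootstrapEval(dm, N = 60L, seed = 5L)
  expect_identical(r@perReplicate, r2@perReplicate)

  # a case is out-of-bag with probability (1 - 1/n)^n, so the distinct
  # in-bag fraction approaches 1 - (1 - 1/n)^n (~0.632 at n = 100)
  big <- separatedDesignMatrix(50L, 50L)
  rb <- bootstrapEval(big, N = 120L, seed = 2L)
  expect_lt(abs((1 - rb@details$meanOobFraction) - (1 - (1 - 1 / 100)^100)),
            0.02)

  # full-set evaluation variant
  rf <- bootstrapEval(dm, N = 20L, seed = 1L, evalOn = "full")
  expect_identical(rf@overallMean, 100)
})

test_that("resampling ignores columns outside the fixed feature set", {
  base <- randomDesignMatrix(n = 24L, p = 6L, C = 2L, seed = 13L, sep = 2)
  sel <- c(2L, 5L)
  corrupted <- base
  set.seed(1)
  corrupted@X[, -sel] <- matrix(rnorm(24L * 4L, sd = 50), 24L, 4L)

  a <- kfoldCV(selectColumns(base, sel), K = 4L, seed = 9L)
  b <- kfoldCV(selectColumns(corrupted, sel), K = 4L, seed = 9L)
  expect_identical(a@perReplicate, b@perReplicate)
  expect_identical(loo(selectColumns(base, sel))@perReplicate,
                   loo(selectColumns(corrupted, sel))@perReplicate)
})

test_that("ROC sweeps thresholds correctly and matches pair counting", {
  perfect <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(perfect$auc, 1)
  inverted <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(inverted$auc, 0)

  mixed <- rocCurve(c(0.8, 0.6, 0.5, 0.3), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(mixed$auc, 0.75)          # 3 of 4 concordant pairs

  # curve geometry: monotone from (0,0) to (1,1)
  expect_identical(c(mixed$fpr[1], mixed$tpr[1]), c(0, 0))
  expect_identical(c(tail(mixed$fpr, 1), tail(mixed$tpr, 1)), c(1, 1))
  expect_true(all(diff(mixed$fpr) >= 0) && all(diff(mixed$tpr) >= 0))

  # tied scores and the Mann-Whitney oracle, across seeds
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- rocCurve(scores, labels)
    expect_lt(abs(r$auc - mannWhitneyAuc(scores, labels)), 1e-12)
  }

  expect_error(rocCurve(c(1, 2), c(TRUE, TRUE)), class = "OneClassOnly")
})

test_that("one-vs-rest dichotomisation gives one AUC per class", {
  # C = 2: complementary posteriors give identical per-class AUCs
  dm2 <- randomDesignMatrix(n = 30L, C = 2L, seed = 17L, sep = 1.5)
  m2 <- fitFisherLDA(dm2)
  r2 <- multiclassRoc(m2, dm2)
  expect_equal(r2@perClass[[1]]$auc, r2@perClass[[2]]$auc,
               tolerance = 1e-12)

  # perfectly separated three classes: three unit AUCs
  sc <- balancedScenario(separation = 12, nPerClass = 8L)
  ds <- generateClassDataset(sc, seed = 3L)
  dm3 <- buildDesignMatrix(ds, scenarioClasses(sc),
                           RegionOfInterest(4.5, 0.5))
  cols <- vapply(scenarioMarkers(sc), function(p)
    which.min(abs(featureLabels(dm3)$ppm - p)), integer(1))
  m3 <- fitFisherLDA(selectColumns(dm3, cols))
  r3 <- multiclassRoc(m3, selectColumns(dm3, cols))
  expect_identical(vapply(r3@perClass, function(x) x$auc, numeric(1)),
                   setNames(c(1, 1, 1), names(r3@perClass)))

  # an independent AUC implementation agrees on a noisy problem
  dmn <- randomDesignMatrix(n = 40L, C = 3L, seed = 19L, sep = 1)
  mn <- fitFisherLDA(dmn)
  post <- posteriorProbabilities(mn, projectCases(mn, dmn))
  rn <- multiclassRoc(mn, dmn)
  for (c in 1:3) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = as.integer(classLabels(dmn) == c),
      predictor = post[, c], direction = "<", quiet = TRUE)))
    expect_equal(rn@perClass[[c]]$auc, as.numeric(ref), tolerance = 1e-10)
  }
})
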