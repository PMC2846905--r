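test_that("two-class canonical direction matches the closed-form solve", {
  # class A at {(0,0), (1,1)}, class B at {(4,0), (5,1)}
  X <- rbind(c(0, 0), c(1, 1), c(4, 0), c(5, 1))
  dm <- designMatrix(X, c(1L, 1L, 2L, 2L), classNames = c("A", "B"))
  model <- suppressWarnings(fitFisherLDA(dm))

  # direct 2x2 closed form: w proportional to pinv(Sw) (muB - muA); this
  # Sw is rank-1 (both classes vary along (1,1) only), hence the ginv
  muA <- colMeans(X[1:2, ]); muB <- colMeans(X[3:4, ])
  Sw <- crossprod(sweep(X[1:2, ], 2, muA)) +
    crossprod(sweep(X[3:4, ], 2, muB))
  wRef <- MASS::ginv(Sw) %*% (muB - muA)
  expect_lt(angleBetween(weights(model)[, 1], as.numeric(wRef)), 1e-8)

  # a well-conditioned variant agrees with the plain solve
  set.seed(21)
  Xw <- rbind(matrix(rnorm(20), 10, 2),
              sweep(matrix(rnorm(20), 10, 2), 2, c(4, 1), "+"))
  dmw <- designMatrix(Xw, rep(1:2, each = 10), classNames = c("A", "B"))
  mw <- fitFisherLDA(dmw)
  muA <- colMeans(Xw[1:10, ]); muB <- colMeans(Xw[11:20, ])
  SwW <- crossprod(sweep(Xw[1:10, ], 2, muA)) +
    crossprod(sweep(Xw[11:20, ], 2, muB))
  expect_lt(angleBetween(weights(mw)[, 1], solve(SwW, muB - muA)), 1e-10)
})

test_that("degenerate and multi-class geometry behave as specified", {
  X <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2),
             matrix(rnorm(10, sd = 0.1), 5, 2))
  dm <- designMatrix(sweep(X, 2, colMeans(X)), rep(1:2, each = 5))
  dm@X <- rbind(dm@X[1:5, ], dm@X[1:5, ])   # identical class means
  expect_error(fitFisherLDA(dm), class = "SingularProblem")

  dm3 <- randomDesignMatrix(n = 30L, C = 3L, seed = 2L)
  m3 <- fitFisherLDA(dm3)
  expect_identical(ncol(weights(m3)), 2L)    # C = 3 -> 2 canonical variables

  dm4 <- randomDesignMatrix(n = 40L, C = 4L, seed = 3L)
  expect_identical(ncol(weights(fitFisherLDA(dm4))), 3L)

  # more features than cases: warns and falls back to the pseudo-inverse
  wide <- randomDesignMatrix(n = 10L, p = 12L, C = 2L, seed = 4L)
  expect_warning(fitFisherLDA(wide), class = "SingularProblem")
})

test_that("canonical directions match the whitening generalized-eigensolver", {
  for (seed in 1:8) {
    set.seed(seed)
    C <- sample(2:4, 1L)
    p <- sample(2:5, 1L)
    dm <- randomDesignMatrix(n = 15L * C, p = p, C = C, seed = seed)
    model <- suppressWarnings(fitFisherLDA(dm))
    V <- fisherDirectionsOracle(designX(dm), classLabels(dm), C)
    for (j in seq_len(min(C - 1L, p))) {
      expect_lt(angleBetween(weights(model)[, j], V[, j]), 1e-8)
    }
  }
})

test_that("projection is a pure linear map", {
  dm <- randomDesignMatrix(n = 24L, C = 3L, seed = 6L)
  model <- fitFisherLDA(dm)
  expect_identical(projectCases(model, matrix(0, 1, 5)), matrix(0, 1, 2))
  z1 <- projectCases(model, designX(dm)[1, , drop = FALSE])
  z2 <- projectCases(model, 2 * designX(dm)[1, , drop = FALSE])
  expect_equal(z2, 2 * z1)
  expect_error(projectCases(model, matrix(0, 1, 3)),
               class = "DimensionMismatch")
})

test_that("posteriors are normalised, symmetric and sharp where they should be", {
  m <- twoClassModel(m1 = -1, m2 = 1)
  expect_equal(as.numeric(posteriorProbabilities(m, matrix(0, 1, 1))),
               c(0.5, 0.5))
  # at a class mean with the other >= 20 sigma away, certainty is extreme
  far <- twoClassModel(m1 = 0, m2 = 25)
  p <- posteriorProbabilities(far, matrix(0, 1, 1))
  expect_gte(p[1, 1], 1 - 1e-80)

  dm <- randomDesignMatrix(n = 30L, C = 3L, seed = 7L)
  model <- fitFisherLDA(dm)
  post <- posteriorProbabilities(model, projectCases(model, dm))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-12)

  # prediction is the posterior argmax, ties to the lowest class index
  pred <- predict(model, dm)
  expect_identical(as.integer(pred),
                   as.integer(apply(post, 1, which.max)))
  tie <- predict(twoClassModel(), matrix(0, 1, 1))
  expect_identical(as.integer(tie), 1L)
})

test_that("two-class boundary is the posterior-equality threshold", {
  expect_equal(computeBoundaries(twoClassModel())@intersectionPoint, 0)

  # unequal priors shift the threshold; posteriors still tie there
  m <- twoClassModel(m1 = -1, m2 = 1, sigma = 0.8, priors = c(0.7, 0.3))
  z <- computeBoundaries(m)@intersectionPoint
  p <- posteriorProbabilities(m, matrix(z, 1, 1))
  expect_lt(abs(p[1, 1] - p[1, 2]), 1e-12)
  expect_gt(z, 0)                            # larger prior claims more axis
})

test_that("three-class boundaries meet where all posteriors are equal", {
  m <- equilateralModel()
  b <- computeBoundaries(m)
  expect_equal(b@intersectionPoint, c(0, 0), tolerance = 1e-12)
  pCentre <- posteriorProbabilities(m, matrix(b@intersectionPoint, 1, 2))
  expect_equal(as.numeric(pCentre), rep(1 / 3, 3), tolerance = 1e-9)

  # every stored endpoint keeps its pair tied for the maximal posterior
  expect_identical(nrow(b@points), 3L)
  for (r in 1:3) {
    pp <- posteriorProbabilities(m, b@points[r, , drop = FALSE])
    pairIdx <- match(strsplit(b@pairs[r], "|", fixed = TRUE)[[1]],
                     classNames(m))
    expect_lt(abs(pp[1, pairIdx[1]] - pp[1, pairIdx[2]]), 1e-9)
    expect_gte(min(pp[1, pairIdx]), max(pp[1, -pairIdx]) - 1e-9)
  }

  # four-class models have no boundary representation
  dm4 <- randomDesignMatrix(n = 40L, C = 4L, seed = 8L)
  expect_null(computeBoundaries(fitFisherLDA(dm4)))
})

test_that("collinear class means give parallel boundary lines without intersection", {
  mu <- rbind(c(-2, 0), c(0, 0), c(2, 0))
  m <- new("FisherLDAModel", weights = diag(2), classMeansProj = mu,
           sigma = 1, priors = rep(1 / 3, 3), classNames = c("A", "B", "C"),
           featureDataset = c("DS1", "DS1"), featurePpm = c(2, 1))
  expect_warning(b <- computeBoundaries(m), class = "NoIntersection")
  expect_length(b@intersectionPoint, 0L)
  expect_identical(nrow(b@points), 6L)       # two endpoints per pair
})

test_that("training accuracy tracks the construction's Bayes accuracy on marker spectra", {
  # three classes separated by ~2.8-noise-sd markers: Bayes accuracy ~95%
  sep <- 2.772
  bayes <- integrate(function(t) dnorm(t - sep) * pnorm(t)^2,
                     -Inf, Inf)$value        # P(own channel wins)
  accs <- vapply(1:5, function(seed) {
    sc <- balancedScenario(separation = sep, noiseSd = 1, nPerClass = 60L)
    ds <- generateClassDataset(sc, seed = seed)
    dm <- buildDesignMatrix(ds, scenarioClasses(sc),
                            RegionOfInterest(4.5, 0.5))
    # the construction concentrates all class information in the three
    # marker channels; LDA on them should recover the Bayes rule
    markerCols <- vapply(scenarioMarkers(sc), function(ppmPos)
      which.min(abs(featureLabels(dm)$ppm - ppmPos)), integer(1))
    fit <- fitFisherLDA(selectColumns(dm, markerCols))
    pred <- predict(fit, designX(dm)[, markerCols])
    100 * mean(pred == classLabels(dm))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 * bayes), 3)
})
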