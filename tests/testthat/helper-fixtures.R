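# Fixture builders shared across test files. Everything is generated in
# code at test time; no data files ship with the tests.

# Two widely separated Gaussian clusters in feature space: any sensible
# classifier is perfect on every subset.
separatedDesignMatrix <- function(n1 = 10L, n2 = 10L, p = 4L, gap = 50,
                                  seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = gap), n2, p))
  designMatrix(X, c(rep(1L, n1), rep(2L, n2)),
               classNames = c("near", "far"))
}

# Small random labelled matrix for resampling determinism checks.
randomDesignMatrix <- function(n = 24L, p = 5L, C = 3L, seed = 1L,
                               sep = 3) {
  set.seed(seed)
  y <- rep(seq_len(C), length.out = n)
  centers <- matrix(rnorm(C * p, sd = sep), C, p)
  X <- centers[y, , drop = FALSE] + matrix(rnorm(n * p), n, p)
  designMatrix(X, y)
}

# Down-scaled three-super-class scenario for fast pipeline tests: same
# marker structure as defaultScenario(), smaller case counts.
tinyScenario <- function(separation = 10, noiseSd = 1, nPerType = 12L) {
  sc <- defaultScenario(separation = separation, noiseSd = noiseSd)
  lapply(sc, function(s) {
    s$tissueTypes <- setNames(rep(nPerType, length(s$tissueTypes)),
                              names(s$tissueTypes))
    s
  })
}

# A perfect class indicator, its exact duplicate, and one noise feature:
# the canonical instance where CFS must keep exactly one copy.
duplicateFeatureMatrix <- function(seed = 1L, n = 60L) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  f1 <- as.numeric(y == 1)
  designMatrix(cbind(f1, f1, rnorm(n)), y)
}

# Balanced marker-only scenario: one tissue type per class (uniform
# priors), one discriminative peak per class, fixed amplitude, and a peak
# width below the channel spacing so the signal lives in a single channel.
# Under this construction the Bayes-optimal rule compares the three marker
# channels and its accuracy has the closed form E[phi(t - sep) * Phi(t)^2].
balancedScenario <- function(separation = 10, noiseSd = 1,
                             nPerClass = 40L, widthPpm = 0.012) {
  # snap marker positions onto the 512-point canonical grid so the whole
  # peak height lands in one channel (the width is below the spacing)
  onGrid <- function(target) 7.2 - round((7.2 - target) * 511 / 10) * 10 / 511
  markers <- onGrid(c(3.21, 1.30, 3.55))
  mapply(function(ppmPos, tt, nm) {
    classSpec(nm, setNames(nPerClass, tt),
              list(peakSpec(ppmPos, widthPpm, separation * noiseSd)),
              noiseSd)
  }, markers, c("t1", "t2", "t3"), c("c1", "c2", "c3"),
  SIMPLIFY = FALSE)
}

# Hand-built 1-D and 2-D Gaussian-posterior models for boundary geometry
# tests (no data involved).
twoClassModel <- function(m1 = -1, m2 = 1, sigma = 1, priors = c(0.5, 0.5)) {
  new("FisherLDAModel", weights = matrix(1, 1, 1),
      classMeansProj = matrix(c(m1, m2), 2, 1), sigma = sigma,
      priors = priors, classNames = c("A", "B"),
      featureDataset = "DS1", featurePpm = 1)
}

equilateralModel <- function(sigma = 0.7) {
  mu <- rbind(c(0, 1), c(-sqrt(3) / 2, -0.5), c(sqrt(3) / 2, -0.5))
  new("FisherLDAModel", weights = diag(2), classMeansProj = mu,
      sigma = sigma, priors = rep(1 / 3, 3),
      classNames = c("A", "B", "C"),
      featureDataset = c("DS1", "DS1"), featurePpm = c(2, 1))
}
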