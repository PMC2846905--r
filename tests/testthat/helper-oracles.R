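# Independent oracles used to cross-check the package's own algorithms.
# Each deliberately takes a different computational route from the
# implementation it checks.

# Generalized-eigenproblem Fisher directions via symmetric whitening:
# Sw^(-1/2) Sb Sw^(-1/2) u = lambda u, v = Sw^(-1/2) u. The package instead
# takes eigenvectors of pinv(Sw) %*% Sb (non-symmetric route).
fisherDirectionsOracle <- function(X, y, C) {
  p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (c in seq_len(C)) {
    Xc <- X[y == c, , drop = FALSE]
    mc <- colMeans(Xc)
    Sw <- Sw + crossprod(sweep(Xc, 2, mc))
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  es <- eigen(Sw, symmetric = TRUE)
  WmHalf <- es$vectors %*% diag(1 / sqrt(es$values), p) %*% t(es$vectors)
  B <- WmHalf %*% Sb %*% WmHalf
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- WmHalf %*% eb$vectors[, seq_len(C - 1L), drop = FALSE]
  apply(V, 2, function(v) v / sqrt(sum(v^2)))
}

# Angle between directions (sign-agnostic), stable for tiny angles where
# acos of the normalised dot product loses all precision: for unit vectors
# the chord length gives angle = 2 asin(||a - b|| / 2).
angleBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  chord <- min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
  2 * asin(min(1, chord / 2))
}

# Exhaustive best-subset CFS merit over all non-empty subsets (p <= 12).
exhaustiveBestMerit <- function(rcf, rff) {
  p <- length(rcf)
  best <- -Inf
  for (mask in seq_len(2^p - 1L)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    best <- max(best, cfsMerit(subset, rcf, rff))
  }
  best
}

# Mann-Whitney concordant-pair AUC by brute-force pair counting.
mannWhitneyAuc <- function(scores, positives) {
  pos <- scores[as.logical(positives)]
  neg <- scores[!as.logical(positives)]
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}
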