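## Fisher linear discriminant analysis for 2-4 classes, with a
## spherical-Gaussian Bayes layer on top of the canonical-variate
## projection. Fisher LDA itself is distribution-free; class-membership
## probabilities are obtained by modelling each class's projected cases as
## a spherical Gaussian centred on the projected class mean, with one
## standard deviation common to all classes and dimensions, and applying
## Bayes' theorem over those densities.

#' Fit a Fisher LDA classifier
#'
#' Computes the within-class scatter Sw and between-class scatter Sb from
#' the class means, takes the top C - 1 eigenvectors of pinv(Sw) Sb as
#' canonical-variate weights (columns ordered by descending discriminant
#' eigenvalue, each unit-norm with its largest-magnitude loading positive),
#' projects the class means, and pools a single sigma as the
#' root-mean-square distance of projected cases from their class mean over
#' all cases and all canonical dimensions. Priors default to training class
#' frequencies; super-classes can be very unequal in size, so uniform
#' priors are available as an option.
#'
#' When the feature count reaches n - C the within-class scatter is
#' singular; a warning is raised and the Moore-Penrose pseudo-inverse is
#' used (parameter-free, deterministic).
#'
#' @param dm a \linkS4class{DesignMatrix} with 2-4 classes, each with at
#'   least 2 cases.
#' @param priors "frequency" (default) or "uniform", or a numeric vector of
#'   C class priors.
#' @return a \linkS4class{FisherLDAModel}.
#' @export
fitFisherLDA <- function(dm, priors = c("frequency", "uniform"),
                         .minPerClass = 2L) {
  stopifnot(is(dm, "DesignMatrix"))
  X <- dm@X; y <- dm@y
  C <- length(dm@classNames)
  if (C < 2L || C > 4L)
    mrsStop("TooFewCases", "Fisher LDA supports 2 to 4 classes")
  counts <- tabulate(y, nbins = C)
  if (any(counts < .minPerClass))
    mrsStop("TooFewCases", sprintf(
      "class '%s' has fewer than %d cases",
      dm@classNames[which(counts < .minPerClass)[1L]], .minPerClass))
  n <- nrow(X); p <- ncol(X); d <- C - 1L
  if (p < d)
    mrsStop("SingularProblem", sprintf(
      "%d feature(s) cannot span %d canonical variables (%d classes)",
      p, d, C))

  mu <- colMeans(X)
  M <- matrix(0, C, p)                       # class means
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (c in seq_len(C)) {
    Xc <- X[y == c, , drop = FALSE]
    M[c, ] <- colMeans(Xc)
    Dc <- sweep(Xc, 2L, M[c, ])
    Sw <- Sw + crossprod(Dc)
    db <- M[c, ] - mu
    Sb <- Sb + counts[c] * tcrossprod(db)
  }
  if (max(abs(Sb)) < 1e-12)
    mrsStop("SingularProblem", "all class means coincide (Sb = 0)")
  if (p >= n - C)
    mrsWarn("SingularProblem", sprintf(
      "%d features >= %d cases - %d classes: within-class scatter is singular, using its pseudo-inverse",
      p, n, C))

  ee <- eigen(MASS::ginv(Sw) %*% Sb)
  ord <- order(Re(ee$values), decreasing = TRUE)[seq_len(d)]
  W <- Re(ee$vectors[, ord, drop = FALSE])
  for (j in seq_len(d)) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }

  Z <- X %*% W
  Mz <- M %*% W
  ss <- sum((Z - Mz[y, , drop = FALSE])^2)
  sigma <- sqrt(ss / (n * d))
  if (sigma < 1e-12) sigma <- 1e-12          # degenerate zero-scatter data

  pri <- if (is.numeric(priors)) {
    if (length(priors) != C || any(priors < 0))
      mrsStop("TooFewCases", "priors must be C non-negative values")
    priors / sum(priors)
  } else if (match.arg(priors) == "uniform") {
    rep(1 / C, C)
  } else {
    counts / n
  }

  model <- new("FisherLDAModel", weights = W, classMeansProj = Mz,
               sigma = sigma, priors = pri, classNames = dm@classNames,
               featureDataset = dm@featureDataset, featurePpm = dm@featurePpm)
  attr(model, "classDefs") <- dm@classDefs
  model
}

asFeatureMatrix <- function(model, X) {
  if (is(X, "DesignMatrix")) X <- X@X
  X <- as.matrix(X)
  if (ncol(X) != nrow(model@weights))
    mrsStop("DimensionMismatch", sprintf(
      "data has %d features, model expects %d", ncol(X),
      nrow(model@weights)))
  X
}

#' Project cases into the canonical-variate space
#'
#' Pure linear map \code{X \%*\% weights}: no centring is applied, matching
#' the raw projection coordinates reported per case.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param X matrix or \linkS4class{DesignMatrix} with the model's features.
#' @return n x d coordinate matrix.
#' @export
projectCases <- function(model, X) {
  asFeatureMatrix(model, X) %*% model@weights
}

#' Class-membership posterior probabilities
#'
#' Bayes' theorem over spherical Gaussians in the projection space:
#' \code{p(c | z)} is proportional to
#' \code{prior_c * exp(-||z - mu_c||^2 / (2 sigma^2))}, evaluated via
#' log-sum-exp so rows sum to 1 within 1e-12 even for distant points.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param coords n x d projection coordinates (from [projectCases()]).
#' @return n x C matrix of probabilities, one column per class.
#' @export
posteriorProbabilities <- function(model, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != ncol(model@weights))
    mrsStop("DimensionMismatch", "coordinate dimension mismatch")
  C <- length(model@classNames)
  logp <- matrix(0, nrow(coords), C)
  for (c in seq_len(C)) {
    d2 <- rowSums(sweep(coords, 2L, model@classMeansProj[c, ])^2)
    logp[, c] <- log(model@priors[c]) - d2 / (2 * model@sigma^2)
  }
  mx <- apply(logp, 1L, max)
  num <- exp(logp - mx)
  out <- num / rowSums(num)
  colnames(out) <- model@classNames
  out
}

#' Predict class labels
#'
#' Argmax of the posterior probabilities; exact ties resolve to the
#' lowest-indexed class (deterministic).
#'
#' @param object a \linkS4class{FisherLDAModel}.
#' @param newdata matrix or \linkS4class{DesignMatrix}.
#' @return integer class indices (with class names as names).
#' @export
setMethod("predict", "FisherLDAModel", function(object, newdata) {
  post <- posteriorProbabilities(object, projectCases(object, newdata))
  idx <- apply(post, 1L, which.max)          # ties -> lowest class index
  setNames(as.integer(idx), object@classNames[idx])
})

#' Class boundaries in the projection space
#'
#' Computed for two-class (1-D projection) and three-class (2-D) models
#' only. For C = 2 the boundary is the single threshold where the two
#' posteriors are equal. For C = 3 each pairwise equal-posterior locus is a
#' straight line (equal spherical covariances); the intersection point
#' solves the 2 x 2 linear system of two pairwise equalities and a boundary
#' segment is drawn from it outward per class pair, clipped at 1.2 times
#' the bounding box of \code{coords} (or of the class means +/- 3 sigma
#' when no coordinates are supplied). When the class means are collinear
#' the pairwise lines are parallel: the lines are returned as point pairs
#' with the intersection point absent. For C = 4 no boundaries exist and
#' NULL is returned.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param coords optional training projection coordinates used only to set
#'   the display clip box.
#' @return a \linkS4class{Boundaries}, or NULL for 4-class models.
#' @export
computeBoundaries <- function(model, coords = NULL) {
  C <- length(model@classNames)
  if (C >= 4L) return(NULL)
  mu <- model@classMeansProj
  s2 <- model@sigma^2
  pri <- model@priors

  if (C == 2L) {
    m1 <- mu[1L, 1L]; m2 <- mu[2L, 1L]
    if (abs(m1 - m2) < 1e-12)
      mrsStop("SingularProblem", "projected class means coincide")
    z <- (m1 + m2) / 2 + s2 * log(pri[2L] / pri[1L]) / (m1 - m2)
    return(new("Boundaries", intersectionPoint = z,
               points = matrix(numeric(), 0L, 1L), pairs = character()))
  }

  ## C = 3: line for pair (i, j):  z . (mu_i - mu_j) = b_ij
  pairIdx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  normals <- t(vapply(pairIdx, function(pr) mu[pr[1L], ] - mu[pr[2L], ],
                      numeric(2L)))
  rhs <- vapply(pairIdx, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    s2 * log(pri[j] / pri[i]) +
      (sum(mu[i, ]^2) - sum(mu[j, ]^2)) / 2
  }, numeric(1L))
  pairName <- vapply(pairIdx, function(pr)
    paste(model@classNames[pr], collapse = "|"), character(1L))

  box <- if (!is.null(coords)) {
    rbind(apply(coords, 2L, min), apply(coords, 2L, max))
  } else {
    rbind(apply(mu, 2L, min) - 3 * model@sigma,
          apply(mu, 2L, max) + 3 * model@sigma)
  }
  ctr <- colMeans(box)
  half <- pmax((box[2L, ] - box[1L, ]) / 2, model@sigma) * 1.2
  exitT <- function(x0, dir) {               # step to the clip-box edge
    tt <- Inf
    for (k in 1:2) {
      if (abs(dir[k]) > 1e-15) {
        cands <- c((ctr[k] - half[k] - x0[k]) / dir[k],
                   (ctr[k] + half[k] - x0[k]) / dir[k])
        cands <- cands[cands > 0]
        if (length(cands)) tt <- min(tt, max(cands))
      }
    }
    if (!is.finite(tt)) 1 else tt
  }

  A <- normals[1:2, , drop = FALSE]
  if (abs(det(A)) < 1e-12 * max(1, max(abs(A)))^2) {
    # collinear class means: three parallel boundary lines
    pts <- NULL; prs <- character()
    for (r in 1:3) {
      nv <- normals[r, ]
      x0 <- rhs[r] * nv / sum(nv^2)          # foot point of the line
      dir <- c(-nv[2L], nv[1L]) / sqrt(sum(nv^2))
      pts <- rbind(pts, x0 + exitT(x0, dir) * dir,
                   x0 - exitT(x0, -dir) * dir)
      prs <- c(prs, pairName[r], pairName[r])
    }
    mrsWarn("NoIntersection",
            "collinear class means: boundary lines are parallel")
    return(new("Boundaries", intersectionPoint = numeric(),
               points = pts, pairs = prs))
  }
  x0 <- as.numeric(solve(A, rhs[1:2]))

  pts <- NULL
  for (r in 1:3) {
    nv <- normals[r, ]
    dir <- c(-nv[2L], nv[1L]) / sqrt(sum(nv^2))
    k <- setdiff(1:3, pairIdx[[r]])          # third class: draw away from it
    away <- x0 - mu[k, ]
    if (sum(away * dir) < 0) dir <- -dir
    pts <- rbind(pts, x0 + exitT(x0, dir) * dir)
  }
  new("Boundaries", intersectionPoint = x0, points = pts, pairs = pairName)
}
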