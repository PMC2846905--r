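#' PCA feature extraction with variance-coverage retention
#'
#' Eigendecomposition of the covariance matrix of the mean-centred design
#' matrix, components ranked by descending eigenvalue. The number of
#' retained components is the smallest for which the cumulative variance
#' fraction reaches \code{varianceTarget} (default 0.95). Each component's
#' sign is fixed so its largest-magnitude loading is positive, making
#' output files reproducible.
#'
#' @param dm a \linkS4class{DesignMatrix} (or plain numeric matrix) with at
#'   least 2 rows.
#' @param varianceTarget fraction of total variance to cover, in (0, 1].
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(dm, varianceTarget = 0.95) {
  X <- if (is(dm, "DesignMatrix")) dm@X else as.matrix(dm)
  if (nrow(X) < 2L) mrsStop("DegenerateData", "need at least 2 cases")
  if (varianceTarget <= 0 || varianceTarget > 1)
    mrsStop("DegenerateData", "varianceTarget must be in (0, 1]")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (all(abs(Xc) < 1e-12))
    mrsStop("DegenerateData", "all cases identical: no variance to analyse")
  ee <- eigen(stats::cov(X), symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {             # sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  frac <- cumsum(ev) / sum(ev)
  nRet <- which(frac >= varianceTarget - 1e-12)[1L]
  new("PCAModel", center = center, components = V, eigenvalues = ev,
      nRetained = as.integer(nRet), varianceTarget = varianceTarget)
}

#' Project data into the retained principal-component space
#'
#' @param model a \linkS4class{PCAModel}.
#' @param X numeric matrix with the model's feature count.
#' @return scores matrix, rows = cases, columns = retained components.
#' @export
pcaTransform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@center))
    mrsStop("DimensionMismatch", sprintf(
      "data has %d features, model expects %d", ncol(X),
      length(model@center)))
  sweep(X, 2L, model@center) %*%
    model@components[, seq_len(model@nRetained), drop = FALSE]
}

#' Filter data through the retained components
#'
#' Noise filtering by back-transformation: project into principal-component
#' space, drop the discarded (low-variance) components, and transform back
#' into the original feature space.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param X numeric matrix with the model's feature count.
#' @return filtered matrix of the same shape as \code{X}.
#' @export
pcaFilter <- function(model, X) {
  scores <- pcaTransform(model, X)
  Vr <- model@components[, seq_len(model@nRetained), drop = FALSE]
  sweep(scores %*% t(Vr), 2L, model@center, "+")
}
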