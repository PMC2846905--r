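## Correlation-based feature subset (CFS) selection with greedy stepwise
## ("hill climbing") search. CFS rewards subsets whose features correlate
## strongly with the class while correlating weakly with one another:
##
##   merit(S) = k * mean_rcf / sqrt(k + k (k - 1) * mean_rff)
##
## with k = |S|, mean_rcf the mean absolute feature-class correlation over S
## and mean_rff the mean absolute pairwise feature-feature correlation over
## S. Feature-class correlation for a continuous feature and a nominal class
## is estimated as the class-prior-weighted mean of absolute Pearson
## correlations against each class's 0/1 indicator (symmetric under label
## permutation); feature-feature correlation is absolute Pearson.

#' Feature-class correlation
#'
#' Prior-weighted mean over classes c of |Pearson(x, 1\{y = c\})|, the
#' weights being the class frequencies. A constant feature yields 0 with a
#' warning (rather than an error), so flat spectral channels are simply
#' never selected.
#'
#' @param x numeric feature column.
#' @param y integer or factor class labels (>= 2 distinct values).
#' @return a correlation in \[0, 1\].
#' @export
featureClassCorrelation <- function(x, y) {
  y <- as.integer(as.factor(y))
  if (length(unique(y)) < 2L)
    mrsStop("EmptyClass", "at least two distinct class labels required")
  if (var(x) == 0) {
    mrsWarn("ConstantFeature", "constant feature: correlation set to 0")
    return(0)
  }
  lev <- sort(unique(y))
  pri <- as.numeric(table(y)[as.character(lev)]) / length(y)
  r <- vapply(lev, function(c) abs(cor(x, as.numeric(y == c))), numeric(1L))
  sum(pri * r)
}

## Absolute correlation structure of a design matrix, computed once per
## search: rcf vector (feature-class) and rff matrix (feature-feature).
## Constant columns get 0 everywhere.
cfsCorrelations <- function(X, y) {
  p <- ncol(X)
  v <- apply(X, 2L, var)
  constant <- v == 0
  if (any(constant))
    mrsWarn("ConstantFeature", sprintf(
      "%d constant feature(s): correlations set to 0", sum(constant)))
  lev <- sort(unique(y))
  pri <- as.numeric(table(y)[as.character(lev)]) / length(y)
  rcf <- numeric(p)
  ok <- which(!constant)
  if (length(ok)) {
    for (j in seq_along(lev)) {
      r <- abs(suppressWarnings(cor(X[, ok, drop = FALSE],
                                    as.numeric(y == lev[j]))))
      rcf[ok] <- rcf[ok] + pri[j] * as.numeric(r)
    }
  }
  rff <- matrix(0, p, p)
  if (length(ok) >= 2L)
    rff[ok, ok] <- abs(suppressWarnings(cor(X[, ok, drop = FALSE])))
  rff[is.na(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

#' CFS merit of a feature subset
#'
#' @param subset integer feature indices (non-empty).
#' @param rcf per-feature feature-class correlations (full vector).
#' @param rff pairwise feature-feature correlation matrix (full matrix).
#' @return the merit \code{k * mean(rcf) / sqrt(k + k * (k - 1) * mean(rff))}
#'   over the subset.
#' @examples
#' cfsMerit(1L, rcf = 0.8, rff = matrix(1))  # 0.8
#' @export
cfsMerit <- function(subset, rcf, rff) {
  k <- length(subset)
  if (k == 0L) mrsStop("EmptySubset", "the feature subset is empty")
  mrcf <- mean(abs(rcf[subset]))
  if (k == 1L) return(mrcf)
  sub <- abs(rff[subset, subset, drop = FALSE])
  mrff <- (sum(sub) - k) / (k * (k - 1))     # off-diagonal mean
  k * mrcf / sqrt(k + k * (k - 1) * mrff)
}

#' Greedy stepwise feature selection under the CFS merit
#'
#' Forward search starts from the empty set and at each step adds the
#' feature that maximises the merit, stopping when no addition strictly
#' increases it (the first feature — the best singleton — is always
#' accepted); tied additions take the lowest feature index. Backward search
#' starts from the full set and removes the feature whose removal maximises
#' the merit, stopping when the best removal would strictly decrease it:
#' merit-preserving removals are accepted (a tie means the removed feature
#' was redundant, e.g. an exact duplicate), and tied removals drop the
#' highest-indexed feature. Both searches are deterministic.
#'
#' @param dm a \linkS4class{DesignMatrix} with >= 2 features.
#' @param direction "forward" or "backward".
#' @return a \linkS4class{FeatureSelectionResult}; \code{selected} holds
#'   column indices into \code{dm} (in selection order for forward, in
#'   column order for backward).
#' @export
greedyStepwiseFS <- function(dm, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is(dm, "DesignMatrix"))
  p <- ncol(dm@X)
  if (p < 2L) mrsStop("EmptySubset", "need at least 2 features to search")
  cc <- cfsCorrelations(dm@X, dm@y)
  rcf <- abs(cc$rcf)
  rff <- abs(cc$rff)
  trace <- numeric()

  ## Merit from running sums: sRcf = sum of |rcf| over the subset, sOff =
  ## sum of |rff| over unordered within-subset pairs. Equals cfsMerit() but
  ## lets each step update in O(p) instead of re-summing every candidate
  ## subset.
  meritFromSums <- function(k, sRcf, sOff) {
    if (k == 1L) return(sRcf)
    k * (sRcf / k) / sqrt(k + 2 * sOff)      # k(k-1) * mean_rff = 2 * sOff
  }

  if (direction == "forward") {
    S <- integer()
    inS <- logical(p)
    sRcf <- 0; sOff <- 0
    current <- -Inf
    crossSum <- numeric(p)                   # sum_{s in S} |rff[f, s]| per f
    repeat {
      cand <- which(!inS)
      if (!length(cand)) break
      merits <- meritFromSums(length(S) + 1L, sRcf + rcf[cand],
                              sOff + crossSum[cand])
      best <- which.max(merits)              # ties -> lowest index
      if (merits[best] <= current) break
      f <- cand[best]
      sRcf <- sRcf + rcf[f]
      sOff <- sOff + crossSum[f]
      crossSum <- crossSum + rff[, f]
      S <- c(S, f); inS[f] <- TRUE
      current <- merits[best]
      trace <- c(trace, current)
    }
  } else {
    ## Backward removals also accept merit-preserving steps (a tie means the
    ## removed feature was redundant, e.g. an exact duplicate); the set
    ## shrinks strictly, so no cycling is possible. Tied removals drop the
    ## highest-indexed feature, keeping the lowest-indexed copy.
    S <- seq_len(p)
    sRcf <- sum(rcf)
    sOff <- (sum(rff) - p) / 2
    current <- meritFromSums(p, sRcf, sOff)
    trace <- current
    rowS <- rowSums(rff) - 1                 # |rff[i, S \ i]| totals
    while (length(S) > 1L) {
      merits <- meritFromSums(length(S) - 1L, sRcf - rcf[S],
                              sOff - rowS[S])
      best <- max(which(merits == max(merits)))
      if (merits[best] < current - 1e-12) break
      i <- S[best]
      sRcf <- sRcf - rcf[i]
      sOff <- sOff - rowS[i]
      S <- S[-best]
      rowS[S] <- rowS[S] - rff[S, i]
      current <- merits[best]
      trace <- c(trace, current)
    }
  }
  new("FeatureSelectionResult",
      method = paste0("sequential-", direction),
      selected = as.integer(S),
      featureDataset = dm@featureDataset[S],
      featurePpm = dm@featurePpm[S],
      meritTrace = trace)
}
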