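#' @name accessors
#' @title Accessors for MRSclassify classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param object an MRSclassify object.
#' @return the slot value (see the individual generic).
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("mapPosition", function(object) standardGeneric("mapPosition"))
#' @rdname accessors
#' @export
setGeneric("cases", function(object) standardGeneric("cases"))
#' @rdname accessors
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))
#' @rdname accessors
#' @export
setGeneric("caseIds", function(object) standardGeneric("caseIds"))
#' @rdname accessors
#' @export
setGeneric("tissueTypes", function(object) standardGeneric("tissueTypes"))
#' @rdname accessors
#' @export
setGeneric("designX", function(object) standardGeneric("designX"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("weights", function(object, ...) standardGeneric("weights"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("sigma", function(object, ...) standardGeneric("sigma"))
#' @rdname accessors
#' @export
setGeneric("priors", function(object) standardGeneric("priors"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object)
  standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("meritTrace", function(object) standardGeneric("meritTrace"))
#' @rdname accessors
#' @export
setGeneric("nRetained", function(object) standardGeneric("nRetained"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

## ---- accessor methods ----

#' @rdname accessors
setMethod("intensities", "Spectrum", function(object) object@intensities)
#' @rdname accessors
setMethod("ppm", "Spectrum", function(object) object@ppm)
#' @rdname accessors
setMethod("mapPosition", "Spectrum", function(object) object@mapPosition)

#' @rdname accessors
setMethod("cases", "MrsDataset", function(object) object@cases)
#' @rdname accessors
setMethod("nCases", "MrsDataset", function(object) length(object@cases))
#' @rdname accessors
setMethod("caseIds", "MrsDataset", function(object)
  vapply(object@cases, function(cs) cs@id, character(1L)))
#' @rdname accessors
setMethod("tissueTypes", "MrsDataset", function(object)
  vapply(object@cases, function(cs) cs@tissueType, character(1L)))

#' @rdname accessors
setMethod("designX", "DesignMatrix", function(object) object@X)
#' @rdname accessors
setMethod("classLabels", "DesignMatrix", function(object) object@y)
#' @rdname accessors
setMethod("classNames", "DesignMatrix", function(object) object@classNames)
#' @rdname accessors
setMethod("caseIds", "DesignMatrix", function(object) object@caseIds)
#' @rdname accessors
setMethod("featureLabels", "DesignMatrix", function(object)
  data.frame(dataset = object@featureDataset, ppm = object@featurePpm))
#' @rdname accessors
setMethod("nCases", "DesignMatrix", function(object) nrow(object@X))

#' @rdname accessors
setMethod("weights", "FisherLDAModel", function(object, ...) object@weights)
#' @rdname accessors
setMethod("classMeans", "FisherLDAModel", function(object)
  object@classMeansProj)
#' @rdname accessors
setMethod("sigma", "FisherLDAModel", function(object, ...) object@sigma)
#' @rdname accessors
setMethod("priors", "FisherLDAModel", function(object) object@priors)
#' @rdname accessors
setMethod("classNames", "FisherLDAModel", function(object) object@classNames)
#' @rdname accessors
setMethod("featureLabels", "FisherLDAModel", function(object)
  data.frame(dataset = object@featureDataset, ppm = object@featurePpm))

#' @rdname accessors
setMethod("counts", "ConfusionMatrix", function(object) object@counts)
#' @rdname accessors
setMethod("classNames", "ConfusionMatrix", function(object) object@classNames)
#' @rdname accessors
setMethod("accuracy", "ConfusionMatrix", function(object)
  100 * sum(diag(object@counts)) / sum(object@counts))

#' @rdname accessors
setMethod("selectedFeatures", "FeatureSelectionResult", function(object)
  data.frame(index = object@selected, dataset = object@featureDataset,
             ppm = object@featurePpm))
#' @rdname accessors
setMethod("meritTrace", "FeatureSelectionResult", function(object)
  object@meritTrace)

#' @rdname accessors
setMethod("nRetained", "PCAModel", function(object) object@nRetained)
#' @rdname accessors
setMethod("eigenvalues", "PCAModel", function(object) object@eigenvalues)

## ---- show methods ----

setMethod("show", "Spectrum", function(object) {
  n <- length(object@intensities)
  cat(sprintf("Spectrum: %d points, [%.4g; %.4g] ppm", n,
              object@ppm[1L], object@ppm[n]))
  if (length(object@mapPosition))
    cat(sprintf(", voxel (%d, %d)", object@mapPosition[1L],
                object@mapPosition[2L]))
  cat("\n")
})

setMethod("show", "MrsDataset", function(object) {
  tt <- tissueTypes(object)
  cat(sprintf("MrsDataset: %d cases (%s)\n", length(object@cases),
              object@role))
  if (length(tt)) {
    tab <- table(tt)
    cat("  tissue types:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d cases x %d features, %d classes\n",
              nrow(object@X), ncol(object@X), length(object@classNames)))
  if (length(object@y)) {
    tab <- table(factor(object@classNames[object@y],
                        levels = object@classNames))
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "FisherLDAModel", function(object) {
  cat(sprintf(
    "FisherLDAModel: %d classes, %d features, %d canonical variable(s)\n",
    length(object@classNames), nrow(object@weights), ncol(object@weights)))
  cat(sprintf("  sigma = %.6g; priors = %s\n", object@sigma,
              paste(sprintf("%.3f", object@priors), collapse = ", ")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = predicted, columns = actual)\n")
  m <- object@counts
  dimnames(m) <- list(predicted = object@classNames,
                      actual = object@classNames)
  print(m)
  cat(sprintf("accuracy: %.2f%%\n", accuracy(object)))
})

setMethod("show", "ResamplingResult", function(object) {
  cat(sprintf("%s evaluation: %d replicates, mean %.2f%% (sd %.3f%%)\n",
              object@method, object@nReplicates, object@overallMean,
              object@overallSd))
})

setMethod("show", "FeatureSelectionResult", function(object) {
  cat(sprintf("%s selection: %d feature(s), final merit %.4f\n",
              object@method, length(object@selected),
              tail(object@meritTrace, 1L)))
})

setMethod("show", "PCAModel", function(object) {
  covered <- 100 * sum(object@eigenvalues[seq_len(object@nRetained)]) /
    sum(object@eigenvalues)
  cat(sprintf("PCAModel: %d of %d components retained (%.1f%% variance)\n",
              object@nRetained, ncol(object@components), covered))
})

setMethod("show", "RocResult", function(object) {
  cat("Per-class ROC (one-vs-rest):\n")
  for (nm in names(object@perClass))
    cat(sprintf("  %s: AUC = %.4f\n", nm, object@perClass[[nm]]$auc))
})
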