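#' Spectrum: one frequency-domain MRS trace
#'
#' A single pre-processed magnetic-resonance-spectroscopy spectrum: a vector
#' of intensities on a strictly descending chemical-shift (ppm) axis.
#' Multi-voxel acquisitions may attach the x-y position of the voxel in the
#' acquisition grid; arbitrary acquisition parameters are carried as opaque
#' key-value metadata and round-tripped through the XML dataset format.
#'
#' @slot intensities numeric vector of point intensities.
#' @slot ppm numeric vector, same length as \code{intensities}, strictly
#'   decreasing (spectra are conventionally plotted high-to-low ppm).
#' @slot mapPosition integer vector of length 0 (single voxel) or 2 (x, y
#'   grid position of a multi-voxel spectrum).
#' @slot params named character vector of opaque acquisition parameters.
#' @exportClass Spectrum
setClass("Spectrum", slots = c(
  intensities = "numeric",
  ppm         = "numeric",
  mapPosition = "integer",
  params      = "character"
))

setValidity("Spectrum", function(object) {
  if (length(object@intensities) < 2L)
    return("a spectrum needs at least 2 points")
  if (length(object@intensities) != length(object@ppm))
    return("intensities and ppm axis differ in length")
  if (any(diff(object@ppm) >= 0))
    return("ppm axis must be strictly decreasing")
  if (!length(object@mapPosition) %in% c(0L, 2L))
    return("mapPosition must be absent or an (x, y) pair")
  TRUE
})

#' Construct a Spectrum
#'
#' @param intensities numeric vector (length >= 2).
#' @param ppm descending ppm axis of the same length; alternatively supply
#'   \code{ppmMax}/\code{ppmMin} and a linear axis is built.
#' @param ppmMax,ppmMin endpoints of a linear axis when \code{ppm} is absent.
#' @param mapPosition optional integer (x, y) grid position.
#' @param params optional named character vector of metadata.
#' @return a \linkS4class{Spectrum}
#' @examples
#' s <- Spectrum(rnorm(512), ppmMax = 7.2, ppmMin = -2.8)
#' length(intensities(s))
#' @export
Spectrum <- function(intensities, ppm = NULL, ppmMax = NULL, ppmMin = NULL,
                     mapPosition = NULL, params = character()) {
  if (is.null(ppm)) {
    if (is.null(ppmMax) || is.null(ppmMin))
      mrsStop("ParseError", "supply either a ppm axis or ppmMax/ppmMin")
    ppm <- ppmAxis(length(intensities), ppmMax, ppmMin)
  }
  new("Spectrum",
      intensities = as.numeric(intensities),
      ppm = as.numeric(ppm),
      mapPosition = if (is.null(mapPosition)) integer() else
        as.integer(mapPosition),
      params = params)
}

#' Case: the spectra of one subject
#'
#' @slot id case identifier, unique within a dataset.
#' @slot tissueType tissue-type code (e.g. "mm", "gl", "me", "a2").
#' @slot spectra ordered list of \linkS4class{Spectrum}.
#' @exportClass MrsCase
setClass("MrsCase", slots = c(
  id         = "character",
  tissueType = "character",
  spectra    = "list"
))

setValidity("MrsCase", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("case id must be a non-empty string")
  if (length(object@spectra) < 1L)
    return("a case needs at least one spectrum")
  if (!all(vapply(object@spectra, is, logical(1L), "Spectrum")))
    return("spectra must all be Spectrum objects")
  TRUE
})

#' @rdname MrsCase-class
#' @param id,tissueType,spectra see slots.
#' @export
MrsCase <- function(id, tissueType, spectra) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  new("MrsCase", id = as.character(id), tissueType = as.character(tissueType),
      spectra = spectra)
}

#' MrsDataset: a study of cases
#'
#' The central container: a list of cases, each with an ID, a tissue type and
#' one or more spectra. Roles (training vs testing) are assigned explicitly,
#' never inferred from file contents.
#'
#' @slot cases list of \linkS4class{MrsCase} with unique IDs.
#' @slot role one of "training", "testing", "unassigned".
#' @slot provenance character vector of source file paths.
#' @exportClass MrsDataset
setClass("MrsDataset", slots = c(
  cases      = "list",
  role       = "character",
  provenance = "character"
))

setValidity("MrsDataset", function(object) {
  if (!all(vapply(object@cases, is, logical(1L), "MrsCase")))
    return("cases must all be MrsCase objects")
  ids <- vapply(object@cases, function(cs) cs@id, character(1L))
  if (anyDuplicated(ids))
    return(sprintf("duplicate case id '%s'", ids[anyDuplicated(ids)]))
  if (!object@role %in% c("training", "testing", "unassigned"))
    return("role must be training, testing or unassigned")
  TRUE
})

#' @rdname MrsDataset-class
#' @param cases,role,provenance see slots.
#' @export
MrsDataset <- function(cases, role = "unassigned", provenance = character()) {
  new("MrsDataset", cases = cases, role = role, provenance = provenance)
}

#' Classification class (possibly a super-class of tissue types)
#'
#' A class groups one or more tissue-type codes under a name, e.g. an
#' "aggressive" super-class pooling glioblastomas and metastases.
#'
#' @slot name class name.
#' @slot memberTypes tissue-type codes belonging to the class.
#' @exportClass ClassDefinition
setClass("ClassDefinition", slots = c(
  name        = "character",
  memberTypes = "character"
))

setValidity("ClassDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("class name must be a non-empty string")
  if (length(object@memberTypes) < 1L)
    return("a class needs at least one tissue type")
  if (anyDuplicated(object@memberTypes))
    return("duplicated tissue type within a class")
  TRUE
})

#' @rdname ClassDefinition-class
#' @param name,memberTypes see slots.
#' @export
ClassDefinition <- function(name, memberTypes) {
  new("ClassDefinition", name = name, memberTypes = as.character(memberTypes))
}

#' Region of interest on the ppm axis
#'
#' @slot ppmHigh upper chemical-shift bound (ppm).
#' @slot ppmLow lower bound; the interval is closed on both ends.
#' @exportClass RegionOfInterest
setClass("RegionOfInterest", slots = c(ppmHigh = "numeric",
                                       ppmLow = "numeric"))

setValidity("RegionOfInterest", function(object) {
  if (object@ppmHigh <= object@ppmLow) return("ppmHigh must exceed ppmLow")
  TRUE
})

#' @rdname RegionOfInterest-class
#' @param ppmHigh,ppmLow interval bounds in ppm.
#' @export
RegionOfInterest <- function(ppmHigh, ppmLow) {
  new("RegionOfInterest", ppmHigh = as.numeric(ppmHigh),
      ppmLow = as.numeric(ppmLow))
}

#' Design matrix: cases x ppm-features with class labels
#'
#' Rows are cases, columns are intensities at selected ppm positions (after
#' region-of-interest extraction and, optionally, concatenation of two
#' spectra per case). Each feature is labelled by the dataset it came from
#' ("DS1" or "DS2") and its ppm value.
#'
#' @slot X numeric matrix, cases x features.
#' @slot y integer class index (1-based) per case.
#' @slot caseIds case identifiers, one per row.
#' @slot tissueTypes tissue-type code per case.
#' @slot featureDataset "DS1"/"DS2" tag per column.
#' @slot featurePpm ppm value per column.
#' @slot classNames class names indexed by \code{y}.
#' @slot classDefs the \linkS4class{ClassDefinition} list used to build it.
#' @exportClass DesignMatrix
setClass("DesignMatrix", slots = c(
  X              = "matrix",
  y              = "integer",
  caseIds        = "character",
  tissueTypes    = "character",
  featureDataset = "character",
  featurePpm     = "numeric",
  classNames     = "character",
  classDefs      = "list"
))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@X) != length(object@y)) return("one label per row required")
  if (nrow(object@X) != length(object@caseIds)) return("one id per row required")
  if (length(object@tissueTypes) &&
      length(object@tissueTypes) != nrow(object@X))
    return("one tissue type per row required when present")
  if (ncol(object@X) != length(object@featurePpm) ||
      ncol(object@X) != length(object@featureDataset))
    return("one (dataset, ppm) label per column required")
  if (length(object@y) && (min(object@y) < 1L ||
      max(object@y) > length(object@classNames)))
    return("class index out of range")
  TRUE
})

#' Feature-selection result
#'
#' @slot method "sequential-forward", "sequential-backward" or "pca".
#' @slot selected integer column indices into the design matrix, in the
#'   order they entered (forward) or survived (backward) the search.
#' @slot featureDataset,featurePpm labels of the selected columns.
#' @slot meritTrace CFS merit after each accepted step.
#' @exportClass FeatureSelectionResult
setClass("FeatureSelectionResult", slots = c(
  method         = "character",
  selected       = "integer",
  featureDataset = "character",
  featurePpm     = "numeric",
  meritTrace     = "numeric"
))

#' PCA feature-extraction model
#'
#' Principal components of the mean-centred design matrix, ranked by
#' eigenvalue, with the minimal number of leading components retained to
#' cover a target fraction of total variance.
#'
#' @slot center per-feature mean removed before projection.
#' @slot components orthonormal eigenvector matrix (features x components).
#' @slot eigenvalues descending eigenvalues of the covariance matrix.
#' @slot nRetained number of retained components.
#' @slot varianceTarget variance-coverage target in (0, 1].
#' @exportClass PCAModel
setClass("PCAModel", slots = c(
  center         = "numeric",
  components     = "matrix",
  eigenvalues    = "numeric",
  nRetained      = "integer",
  varianceTarget = "numeric"
))

setValidity("PCAModel", function(object) {
  if (any(diff(object@eigenvalues) > 1e-8))
    return("eigenvalues must be sorted descending")
  if (object@nRetained < 1L || object@nRetained > ncol(object@components))
    return("nRetained out of range")
  TRUE
})

#' Fisher LDA classifier with spherical-Gaussian posteriors
#'
#' Canonical-variate weights from Fisher linear discriminant analysis of C
#' classes (C - 1 canonical variables), together with the spherical-Gaussian
#' class model fitted in the projection space: projected class means, one
#' standard deviation common to all classes and dimensions, and class
#' priors. Bayes' theorem over these Gaussians yields class-membership
#' probabilities.
#'
#' @slot weights features x d matrix of canonical-variate weights
#'   (d = C - 1), columns ordered by descending discriminant eigenvalue.
#' @slot classMeansProj C x d matrix of projected class means.
#' @slot sigma common scalar standard deviation in the projection space.
#' @slot priors class prior probabilities (sum to 1).
#' @slot classNames class names.
#' @slot featureDataset,featurePpm labels of the model's input features.
#' @exportClass FisherLDAModel
setClass("FisherLDAModel", slots = c(
  weights        = "matrix",
  classMeansProj = "matrix",
  sigma          = "numeric",
  priors         = "numeric",
  classNames     = "character",
  featureDataset = "character",
  featurePpm     = "numeric"
))

setValidity("FisherLDAModel", function(object) {
  C <- length(object@classNames)
  if (ncol(object@weights) != C - 1L)
    return("C classes require C - 1 canonical variables")
  if (nrow(object@classMeansProj) != C ||
      ncol(object@classMeansProj) != C - 1L)
    return("classMeansProj must be C x (C - 1)")
  if (object@sigma <= 0) return("sigma must be positive")
  if (any(object@priors < 0) || abs(sum(object@priors) - 1) > 1e-8)
    return("priors must be non-negative and sum to 1")
  TRUE
})

#' Class boundaries in the projection space
#'
#' For two-class (1-D) and three-class (2-D) classifiers only: the points of
#' equal maximal posterior probability that separate classes. In 2-D the
#' pairwise equal-posterior loci are straight lines (equal spherical
#' covariances); they meet at one intersection point from which a boundary
#' segment is drawn outward per class pair.
#'
#' @slot intersectionPoint numeric of length d, or length 0 when the
#'   pairwise boundaries are parallel (collinear class means).
#' @slot points matrix (one row per boundary endpoint) of d-space points.
#' @slot pairs character labels "i|j" naming the class pair of each point.
#' @exportClass Boundaries
setClass("Boundaries", slots = c(
  intersectionPoint = "numeric",
  points            = "matrix",
  pairs             = "character"
))

#' Confusion matrix (rows = predicted, columns = actual)
#'
#' @slot counts C x C integer matrix; entry \code{[p, a]} counts cases of
#'   actual class \code{a} predicted as class \code{p}.
#' @slot classNames class names for both dimensions.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix", slots = c(
  counts     = "matrix",
  classNames = "character"
))

setValidity("ConfusionMatrix", function(object) {
  if (nrow(object@counts) != ncol(object@counts))
    return("counts must be square")
  if (any(object@counts < 0)) return("negative count")
  TRUE
})

#' Resampling evaluation result
#'
#' Per-replicate accuracies (in percent) from K-fold cross-validation,
#' leave-one-out or bootstrap, with overall and per-class summaries. Sample
#' standard deviations use the n - 1 denominator.
#'
#' @slot method "kfold", "loo" or "bootstrap".
#' @slot perReplicate accuracy (%) of each replicate.
#' @slot overallMean,overallSd summary over replicates (%).
#' @slot perClassMean,perClassSd per-class recall summaries (%).
#' @slot nReplicates number of replicates.
#' @slot seed RNG seed used (NA for deterministic methods).
#' @slot details list of method-specific extras (e.g. mean out-of-bag
#'   fraction and redraw count for bootstrap).
#' @exportClass ResamplingResult
setClass("ResamplingResult", slots = c(
  method       = "character",
  perReplicate = "numeric",
  overallMean  = "numeric",
  overallSd    = "numeric",
  perClassMean = "numeric",
  perClassSd   = "numeric",
  nReplicates  = "integer",
  seed         = "integer",
  details      = "list"
))

#' Per-class ROC curves from one-vs-rest dichotomisation
#'
#' @slot perClass named list; each element holds \code{fpr}, \code{tpr} and
#'   \code{auc} for one class scored by its posterior probability.
#' @exportClass RocResult
setClass("RocResult", slots = c(perClass = "list"))
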