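## Text reports (per-case predictions, probabilities, weights matrix), the
## train pipeline orchestrator and the classifier-history log. Reports are
## TSV with '.' decimals at 6 significant digits; full precision lives in
## the CLASSIFIER XML.

#' Per-case classification report
#'
#' One row per case: identifier, tissue type, actual class, predicted
#' class, and the projection coordinates (one column per canonical
#' variable, named X, Y, Z as applicable).
#'
#' @param model a \linkS4class{FisherLDAModel} fitted on \code{dm}'s
#'   feature labels.
#' @param dm a \linkS4class{DesignMatrix}.
#' @return a data.frame.
#' @export
reportLdaResults <- function(model, dm) {
  coords <- projectCases(model, dm)
  pred <- predict(model, dm)
  d <- ncol(coords)
  colnames(coords) <- c("X", "Y", "Z")[seq_len(d)]
  data.frame(
    id = dm@caseIds,
    tissueType = if (length(dm@tissueTypes)) dm@tissueTypes else
      NA_character_,
    actualClass = dm@classNames[dm@y],
    predictedClass = model@classNames[as.integer(pred)],
    coords, check.names = FALSE)
}

#' Per-case class-membership probability report
#'
#' One row per case (training followed by testing when given), one
#' probability column per class in class-definition order; rows sum to 1.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param dmTrain training \linkS4class{DesignMatrix}.
#' @param dmTest optional independent test \linkS4class{DesignMatrix}.
#' @return a data.frame with columns id, set, then one column per class.
#' @export
reportProbabilities <- function(model, dmTrain, dmTest = NULL) {
  one <- function(dm, set) {
    post <- posteriorProbabilities(model, projectCases(model, dm))
    df <- as.data.frame(post)
    names(df) <- colnames(post)
    cbind(data.frame(id = dm@caseIds, set = set), df)
  }
  out <- one(dmTrain, "training")
  if (!is.null(dmTest)) out <- rbind(out, one(dmTest, "testing"))
  out
}

#' Classifier weights report
#'
#' The weights matrix, one row per feature labelled by dataset tag and ppm
#' value (never by raw index), one column per canonical variable.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @return a data.frame.
#' @export
reportWeights <- function(model) {
  W <- model@weights
  colnames(W) <- paste0("CV", seq_len(ncol(W)))
  data.frame(dataset = model@featureDataset, ppm = model@featurePpm, W,
             check.names = FALSE)
}

#' Write a report as tab-separated text
#'
#' Numeric columns are rendered with '.' decimals at 6 significant digits.
#'
#' @param df a report data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReportTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- formatC(signif(out[[j]], 6L),
                                                  format = "g", digits = 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Train a classifier end-to-end
#'
#' Runs the fixed pipeline: assemble the design matrix from the training
#' dataset (region of interest, optional second-dataset concatenation),
#' select or extract features, then fit the Fisher LDA classifier. Each
#' stage fails fast with a stage-named error.
#'
#' @param train training \linkS4class{MrsDataset}.
#' @param classes list of \linkS4class{ClassDefinition}.
#' @param roi a \linkS4class{RegionOfInterest}.
#' @param fs "forward", "backward", "pca" or "none".
#' @param varianceTarget PCA variance-coverage target (default 0.95).
#' @param priors "frequency" or "uniform".
#' @param second optional second dataset for two-spectra concatenation.
#' @return list with \code{model}, \code{dm} (full design matrix),
#'   \code{dmUsed} (after selection/filtering), \code{features}
#'   (\linkS4class{FeatureSelectionResult} or NULL) and \code{pca}
#'   (\linkS4class{PCAModel} or NULL).
#' @export
trainClassifier <- function(train, classes, roi,
                            fs = c("forward", "backward", "pca", "none"),
                            varianceTarget = 0.95, priors = "frequency",
                            second = NULL) {
  fs <- match.arg(fs)
  dm <- buildDesignMatrix(train, classes, roi, second = second)
  features <- NULL; pca <- NULL
  dmUsed <- dm
  if (fs %in% c("forward", "backward")) {
    features <- greedyStepwiseFS(dm, fs)
    dmUsed <- selectColumns(dm, features@selected)
  } else if (fs == "pca") {
    pca <- fitPCA(dm, varianceTarget)
    dmUsed <- dm
    dmUsed@X <- pcaFilter(pca, dm@X)         # noise-filtered, original space
  }
  model <- fitFisherLDA(dmUsed, priors = priors)
  list(model = model, dm = dm, dmUsed = dmUsed, features = features,
       pca = pca)
}

## 32-bit polynomial rolling hash over a config's serialised bytes: a
## stable content hash for telling runs apart in the history log (all
## arithmetic stays exact in double precision).
configHash <- function(config) {
  bytes <- serialize(config, NULL, version = 2L)
  h <- 5381
  for (b in as.integer(bytes)) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Append a run to the classifier history log
#'
#' The history is an append-only line-delimited JSON log storing the main
#' description of each classifier run (name, method, classes, feature
#' count, evaluation summary, config hash), so runs with different
#' parameters can be compared later.
#'
#' @param path log file path (created on first use).
#' @param name classifier name.
#' @param config the run configuration (any serialisable list).
#' @param model the fitted \linkS4class{FisherLDAModel}.
#' @param bootstrap optional bootstrap \linkS4class{ResamplingResult}.
#' @param roc optional \linkS4class{RocResult}.
#' @param timestamp ISO-8601 timestamp (defaults to now).
#' @return the new entry, invisibly.
#' @export
appendHistory <- function(path, name, config, model, bootstrap = NULL,
                          roc = NULL,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  entry <- list(
    timestamp = timestamp,
    name = name,
    method = "Fisher LDA",
    classes = model@classNames,
    nFeatures = nrow(model@weights),
    bootstrapMean = if (is.null(bootstrap)) NA else bootstrap@overallMean,
    bootstrapSd = if (is.null(bootstrap)) NA else bootstrap@overallSd,
    auc = if (is.null(roc)) NULL else
      vapply(roc@perClass, function(x) x$auc, numeric(1L)),
    configHash = configHash(config))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  invisible(entry)
}

#' Read the classifier history log
#'
#' @param path log file path.
#' @return a data.frame, one row per recorded run (empty when the log does
#'   not exist yet).
#' @export
readHistory <- function(path) {
  if (!file.exists(path))
    return(data.frame(timestamp = character(), name = character(),
                      method = character(), classes = character(),
                      nFeatures = integer(), bootstrapMean = numeric(),
                      bootstrapSd = numeric(), configHash = character()))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l)
    data.frame(timestamp = e$timestamp, name = e$name, method = e$method,
               classes = paste(e$classes, collapse = "+"),
               nFeatures = e$nFeatures,
               bootstrapMean = ifelse(is.null(e$bootstrapMean), NA,
                                      e$bootstrapMean),
               bootstrapSd = ifelse(is.null(e$bootstrapSd), NA,
                                    e$bootstrapSd),
               configHash = e$configHash)
  })
  do.call(rbind, rows)
}
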