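Package: MRSclassify
Title: Pattern Recognition for Magnetic Resonance Spectroscopy Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating classifiers of pre-processed
    frequency-domain 1H magnetic resonance spectroscopy (MRS) spectra, aimed
    at brain-tumour type discrimination. Reads five common text dialects of
    single-voxel, multi-voxel and HRMAS spectra plus an XML dataset
    interchange format; defines classes and super-classes of tissue types;
    extracts a ppm region of interest and optionally concatenates two spectra
    per case; selects features by greedy stepwise search under the
    correlation-based feature subset (CFS) merit or extracts them by PCA with
    a variance-coverage threshold; trains Fisher linear discriminant
    classifiers for two to four classes with spherical-Gaussian Bayes
    posterior probabilities and projection-space class boundaries; evaluates
    by confusion matrix, K-fold cross-validation, leave-one-out, bootstrap
    resampling and one-vs-rest ROC/AUC; and serialises trained classifiers to
    an XML interchange format. A synthetic-spectrum generator with known
    class structure supports testing and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'formats-read.R'
    'formats-dataset-xml.R'
    'formats-classifier-xml.R'
    'dataset.R'
    'features-cfs.R'
    'features-pca.R'
    'lda.R'
    'evaluation.R'
    'synthetic.R'
    'reports.R'
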