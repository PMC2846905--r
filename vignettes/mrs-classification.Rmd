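---
title: "Classifying MRS spectra with MRSclassify: models, parameters and design choices"
author: "MRSclassify authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying MRS spectra with MRSclassify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRSclassify)
```

## The problem

In vivo proton magnetic resonance spectroscopy (^1^H-MRS) measures the
resonances of tissue metabolites — choline, creatine, N-acetylaspartate,
lactate, lipids, myo-inositol — as a frequency-domain trace over the
chemical-shift (ppm) axis. Different brain-tumour types show different
metabolite profiles, so a spectrum can be treated as a feature vector and a
tumour-type question as a supervised classification problem. MRSclassify
implements that pattern-recognition layer for already pre-processed
spectra: reading the common text dialects, assembling a cases × ppm-features
design matrix, selecting informative frequencies, training a Fisher linear
discriminant classifier with class-membership probabilities, evaluating it,
and serialising everything to an XML interchange format. Raw-signal
processing (phasing, baseline, water removal) is deliberately out of scope:
inputs are frequency-domain spectra as exported by upstream tools.

The pipeline order is fixed: import → assign training/testing roles →
define classes → region of interest → feature selection or extraction →
train → evaluate → export.

## Data model and input formats

A `Spectrum` is an intensity vector on a strictly descending ppm axis; a
`MrsCase` groups the spectra of one subject under an ID and a tissue-type
code; an `MrsDataset` is a study. Index *i* (1-based) of an *N*-point
spectrum maps to

$$\mathrm{ppm}_i = \mathrm{ppm}_{\max} - (i-1)\,
  \frac{\mathrm{ppm}_{\max}-\mathrm{ppm}_{\min}}{N-1},$$

endpoints included — the convention that matches spectral ranges written
high-to-low, e.g. the canonical 512-point [7.2; −2.8] ppm single-voxel
format. Five text dialects are read (single-row canonical `.txt`/`.art`,
514-token-per-row `.dat` tables, jMRUI text exports, 3DiCSI `.bsp`
multi-voxel ASCII, single-column HRMAS text) plus the package's own DATASET
XML. Each reader parses only what it documents: the `.dat` header row, the
jMRUI columns other than *fft (real)* and the `.bsp` Imaginary column are
never inspected, and the test suite corrupts them to prove it.

Two choices worth knowing:

* **jMRUI ppm origin.** The header gives points, sampling interval (ms) and
  transmitter frequency (Hz), which fix the spectral *width*
  $(1000/\Delta t)\,/\,(f\cdot 10^{-6})$ ppm but not its origin. The axis is
  centred on a configurable reference, by default 4.7 ppm (water); the
  inferred range is reported at parse time so the user can verify it.
* **DATASET XML Parameters.** The `Parameters` node carries opaque
  key-value children, round-tripped verbatim. The writer adds `PpmMax` and
  `PpmMin` there so the axis survives a round trip; re-writing a re-read
  file is byte-identical.

## Classes, region of interest, design matrix

Classes are named groups of tissue-type codes ("super-classes"), pairwise
disjoint, two to four per classifier. The region of interest
$[\mathrm{ppm}_{lo}, \mathrm{ppm}_{hi}]$ is a closed interval (the boundary
channels are included; the underlying convention is not dictated by the
formats, so the inclusive reading was chosen and is stated here). Rows of
the design matrix are ROI intensities of each case's first spectrum; with a
second dataset, cases are matched by exact ID equality, unmatched cases are
dropped with a warning, and each row is the DS1 ROI followed by the DS2 ROI
(two acquisitions, e.g. at two echo times, concatenated). Mixed axis
lengths within a dataset are an error — no resampling or alignment is
attempted.

## Feature selection: CFS with greedy stepwise search

Subsets are scored by the correlation-based feature subset (CFS) merit

$$\mathrm{merit}(S) = \frac{k\,\overline{r}_{cf}}
  {\sqrt{k + k(k-1)\,\overline{r}_{ff}}},\qquad k = |S|,$$

with $\overline{r}_{cf}$ the mean absolute feature-class correlation and
$\overline{r}_{ff}$ the mean absolute pairwise feature-feature correlation
over $S$: reward relevance, penalise redundancy. For a continuous spectral
channel against a nominal class, the feature-class correlation is the
class-prior-weighted mean of $|\mathrm{Pearson}(x, \mathbf{1}\{y=c\})|$
over classes — symmetric under label permutation, deterministic and
testable; feature-feature correlation is absolute Pearson. A constant
channel scores 0 with a warning rather than erroring, so flat regions are
simply never selected. (Whether intensities should be discretised first,
as some subset evaluators do, is a genuinely open question; the continuous
estimator was chosen and is the single switch point if an alternative is
wanted.)

The search is hill-climbing: **forward** starts empty and adds the
merit-maximising feature until no addition strictly increases the merit
(the first feature, the best singleton, is always accepted; ties take the
lowest index). **Backward** starts full and removes the feature whose
removal maximises merit. Backward additionally accepts merit-*preserving*
removals: removing an exact duplicate of a kept feature ties the merit
rather than increasing it, yet a search that stops there has obviously not
finished pruning redundancy. Because the set strictly shrinks, accepting
ties cannot cycle; tied removals drop the highest-indexed feature so the
lowest-indexed copy survives. Forward keeps the strict rule, which is what
prevents cycling there.

One behaviour to expect on weakly separated data: the class structure
itself induces correlation between discriminative channels of *different*
classes, which the redundancy penalty counts against them. With weak
signals the forward search can therefore stop after a single channel. This
is faithful CFS behaviour, not a defect.

## PCA feature extraction

PCA is the eigendecomposition of the covariance matrix of the mean-centred
design matrix (covariance, not correlation: spectral channels share units,
standardisation is a config flag rather than the default), components
ranked by eigenvalue. The retained count is the *smallest* $m$ whose
cumulative variance fraction reaches the target (default 0.95,
user-modifiable). Noise filtering projects into component space, drops the
trailing components and transforms back. Each component's sign is fixed so
its largest-magnitude loading is positive, making serialised models
reproducible. The SVD route (`prcomp`) serves as an independent
cross-check in the tests, never as the implementation.

## Fisher LDA with spherical-Gaussian posteriors

For $C$ classes ($2 \le C \le 4$) with within-class scatter $S_w$ and
between-class scatter $S_b$, the canonical-variate weights are the top
$C-1$ eigenvectors of $S_w^{+} S_b$ (Moore–Penrose pseudo-inverse:
parameter-free and deterministic, unlike ridge regularisation; a warning is
raised when the feature count reaches $n - C$ and $S_w$ is necessarily
singular). Columns are ordered by discriminant eigenvalue, unit-norm, with
the largest-magnitude loading positive. Projection is the raw linear map
$Z = XW$ with no centring, so reported coordinates are reproducible from
the weights alone.

Fisher LDA itself is distribution-free; probabilities come from modelling
each class's projected cases as a spherical Gaussian centred on the
projected class mean with one standard deviation **common to all classes
and all canonical dimensions**:

$$\sigma^2 = \frac{1}{nd}\sum_{i=1}^{n} \lVert z_i - \mu_{y_i}\rVert^2 ,
\qquad
p(c \mid z) \propto \pi_c \exp\!\left(-\frac{\lVert z-\mu_c\rVert^2}
{2\sigma^2}\right).$$

A scalar pooled σ is the most literal reading of "spherical, common to
all"; a per-dimension alternative would weight the canonical axes
differently and is intentionally not offered. Posteriors are computed via
log-sum-exp, so rows sum to 1 within 10⁻¹² even for points far from every
mean. Priors default to training class frequencies — Bayes' theorem needs
priors and super-classes are often very unequal — with `priors = "uniform"`
available. Prediction is the posterior argmax with exact ties resolved to
the lowest class index.

**Boundaries.** With equal spherical covariances the equal-posterior loci
are points (1-D, two classes) or straight lines (2-D, three classes). The
two-class threshold is the midpoint of the projected means shifted by
$\sigma^2 \ln(\pi_2/\pi_1)/(\mu_1-\mu_2)$; the three-class intersection
point solves the 2×2 linear system of two pairwise equalities, and one
boundary segment per pair is drawn outward from it, away from the third
class's mean, clipped at 1.2× the data bounding box (a display convention;
every stored point satisfies its pair's posterior tie to 10⁻⁹). Collinear
class means make the three lines parallel: they are returned as point
pairs with the intersection absent, with a warning. Four-class models have
a 3-D projection and no boundary representation.

## Evaluation

All resampling re-fits **only the classifier** on the already-fixed feature
columns; the selection stage is never re-run inside a replicate (it has its
own evaluation criterion), so estimates can be slightly optimistic when
many features were screened — use an independent test set for final
numbers. Accuracies are reported in percent with sample (n−1) standard
deviations.

* **Confusion matrix**: rows are predicted classes, columns actual ones.
* **K-fold CV** (user-set K): stratified by class — unstratified folds on
  four-class imbalanced data frequently lose a class entirely. Cases are
  grouped by class, shuffled within class under the given seed, and fold
  labels cycled over the concatenated order; a partition leaving a training
  split without some class is rejected and re-stratified. Folds are
  reported in a canonical order (smallest case index in the test fold).
* **Leave-one-out**: deterministic, no RNG; exactly K-fold with K = n, and
  the test suite asserts replicate-by-replicate equality.
* **Bootstrap** (default N = 1000): each replicate draws n cases with
  replacement, re-fits, and scores the out-of-bag cases. Out-of-bag is the
  standard choice for discriminant error estimation; scoring the full
  original set instead is available as `evalOn = "full"`. Replicates whose
  resample misses a class or has no out-of-bag case are redrawn and
  counted. Per-class figures are recalls (the diagonal fraction of each
  actual class), which is what per-class accuracy means here.
* **ROC/AUC**: thresholds sweep the unique scores descending; tied scores
  form a single step, the convention under which the trapezoidal AUC equals
  the Mann–Whitney concordant-pair statistic (asserted to 10⁻¹²). A
  multiclass model is dichotomised one-vs-rest per class, scored by that
  class's posterior.

## The synthetic generator

Real clinical MRS studies cannot be redistributed, so the package carries a
generator whose ground truth is known by construction: spectra are sums of
Gaussian or Lorentzian lineshapes (FWHM parameterisation) plus i.i.d.
Gaussian noise; peak heights vary per case following a lognormal law
(concentrations stay positive) while positions stay fixed per class —
metabolite-concentration variation without chemical-shift drift. One global
seed drives a per-case seed sequence, so extending a class leaves earlier
cases bit-identical.

The packaged scenario imitates a short-echo-time single-voxel brain-tumour
study: 217 cases as 512-point spectra on [7.2; −2.8] ppm in three
super-classes — *low-grade m* (58 meningiomas), *aggressive* (86
glioblastomas + 38 metastases), *low-grade g* (22 low-grade astrocytomas +
6 oligoastrocytomas + 7 oligodendrogliomas). All classes share creatine
(3.03 ppm) and NAA (2.01 ppm) peaks; each has one marker — choline
(3.21 ppm), lipids/lactate (1.30 ppm), myo-inositol (3.55 ppm) — whose
height exceeds the other classes' by 10 noise standard deviations, with a
5% amplitude coefficient of variation. Under that construction the Bayes
accuracy is essentially 100% (per-pair error $2\Phi(-10/2\sigma_{\rm eff})
\approx 8\times10^{-6}$), the forward search should find every marker
within ±0.1 ppm, and a correct implementation should train at ~100%.

What the generator does **not** emulate: baseline distortion, residual
water, eddy-current lineshape asymmetry, chemical-shift drift, overlapping
multiplets, or inter-centre calibration differences. Passing tests
therefore demonstrate that the algorithms are implemented correctly, not
that any particular accuracy will be achieved on clinical data.

## Numerical choices and degenerate inputs

* Numbers are serialised at 17 significant digits; doubles round-trip
  exactly through both XML formats, and reports use 6 significant digits
  with full precision living in the XML.
* $S_b = 0$ (all class means equal) is an error; fewer features than
  canonical variables is an error; a class with fewer than two training
  cases is an error at the user-facing fit (resampling refits tolerate
  one).
* Perfectly separable toy data can give zero within-class scatter in the
  projection; σ is floored at 10⁻¹² to keep posteriors defined.
* All error conditions are classed (`ParseError`, `SchemaError`,
  `ClassOverlap`, `TooFewCases`, …) so callers can branch on the condition
  class rather than message text.

## Problem sizes in the test suite

The suite runs entirely on generated data: oracle comparisons use 50 random
discriminant problems (≤5 features, 2–4 classes) against a
symmetric-whitening generalized eigensolver, 30 CFS problems (≤12 features)
against exhaustive subset enumeration, and 100 score vectors against
Mann–Whitney pair counting; the pipeline check runs the packaged 217-case
scenario over 20 seeds. These sizes were chosen to make every contract
measurable at desk scale while keeping the whole suite in the tens of
seconds.

## Limitations

Only Fisher LDA is implemented (no QDA, shrinkage, kernels, >4 classes);
feature selection is filter-based (no wrappers or genetic search);
bootstrap confidence is mean ± sd (no .632/.632+ correction, no DeLong
tests); spectra of differing resolution are never resampled to a common
axis. These are scope decisions, not oversights: the package is the
pattern-recognition back end of an MRS workflow, not a pre-processing or
deep-modelling tool.
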