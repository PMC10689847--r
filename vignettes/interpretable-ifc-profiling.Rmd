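---
title: "Interpretable profiling of immunological synapses from imaging flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable profiling of immunological synapses from imaging flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synapsight)
```

## The measurement and its model

Imaging flow cytometry records, for every cell event, a small multichannel
microscopy image. In a T cell / B-LCL co-culture the biologically relevant
unit is the *conjugate configuration*: is the event a free B cell, a free
T cell with or without proximal TCR signaling, a genuine synapse, two
cells stacked in one focal layer, or a multi-cell cluster? `synapsight`
models each event as a `cell_record`: a C×H×W intensity stack on the
16-bit count scale, one binary segmentation mask per channel (produced
upstream by the instrument software or by the package's simulator), and
donor/experiment/condition metadata. Records are stored one per HDF5 file
so that feature extraction parallelizes trivially; a CSV manifest indexes
the files.

The panel is brightfield (BF), F-actin, MHCII, CD3, P-CD3ζ and a
viability stain. The nine-class taxonomy is organized by cell count
(singlet / doublet / multiplet) and signaling state; two classes
('T cell w/ small B-LCL', 'no cell-cell interaction') are experimental
artifacts that are kept during classifier training — they sharpen the
decision boundary — and excluded from every population-level statistic.

## Feature families and their conventions

All features are deterministic functions of one record. Conventions that
the definitions do not pin down uniquely were fixed once, as follows.

* **Morphology** (30 per mask): 16 scalar descriptors plus 7 Hu moment
  invariants and 7 intensity-weighted Hu invariants. Pixel coordinates
  are 0-based centers; the convex hull, Feret diameters and moment-based
  axis lengths are computed from pixel centers; the perimeter counts
  exposed 4-neighbor pixel edges; the Crofton perimeter uses intercept
  counts in four directions. Weighted Hu moments normalize the intensity
  weights to mean 1, which makes them invariant to global intensity
  scaling — without this the weighted set would scale with exposure,
  which is exactly the nuisance the invariants exist to remove.
* **Intensity** (17 per channel): 8 moment/order statistics (population
  standard deviation, Fisher kurtosis) plus the 9 deciles with linear
  interpolation between closest ranks (`quantile` type 7, matching the
  common scientific-Python default). The Shannon entropy uses a 256-bin
  histogram over the 16-bit range and the natural log.
* **Texture** (6 per channel): masked intensities are min-max rescaled
  and quantized to 32 gray levels; one symmetric co-occurrence matrix is
  accumulated at distance 1 over the four standard angles and then
  normalized. Computing the statistics from that angle-pooled matrix (and
  not averaging per-angle statistics) keeps the identity
  energy = sqrt(ASM) exact. A constant image yields the degenerate
  matrix: contrast 0, ASM 1, and correlation *defined* as 1.
* **Co-localization** (17 per channel pair): mask-overlap distances,
  intensity agreement over the union-of-masks pixel set, Manders split
  coefficients M1/M2 (the fraction of one channel's intensity lying on
  the other's mask, measured over the union set), the Manders overlap
  coefficient, the intensity correlation quotient (in [−0.5, 0.5]),
  full-frame single-window SSIM with a data-range dynamic, and the
  Hausdorff distance between the two mask point sets. Mutual information
  uses a 16×16 joint histogram with natural log.
* **Synaptic enrichment** (3 per fluorescent channel): the synapse mask
  is the *intersection* of the T-cell and B-cell masks after each is
  dilated with a disk of radius 3 px. A union would cover both cell
  bodies and force enrichment ≈ 1 by construction; the intersection
  isolates the contact zone. An empty synapse mask is a real
  "no contact" measurement and maps to enrichment 0; an all-zero channel
  (undefined ratio) maps to missing.
* **QC** (2 per channel): background mean outside the union of all
  masks, and the RMS Sobel gradient magnitude within the channel mask —
  the focus proxy used by the cleaning pipeline.

The fluorescent-relevant inventory is 27 features per channel
(8 statistics + 9 deciles + 6 GLCM + 3 enrichments + mask area) and 17
per unordered pair, the unique decomposition consistent with 210 columns
for four channels and 132 for three. The full inventory adds morphology
and QC blocks per panel channel; its total is deliberately configurable
rather than pinned to a single number, because the primitive counts admit
no single reconciliation with a fixed grand total.

Empty-mask semantics are "missing", never 0, and no stage silently
coerces missing to 0; imputation (per-feature median) happens explicitly
and, inside cross-validation, is refit on each training fold.

## Pre-selection, classification, explanation

The pre-selection pipeline prunes |Pearson| > 0.95 pairs (the survivor
chosen by seeded RNG), takes the union of the top-k features from six
rankings — kNN mutual information (Ross-type estimator, k = 3), linear
SVM weight magnitudes summed over one-vs-one classifiers, mean
|coefficient| along the L1 and L2 multinomial regularization paths,
random-forest Gini importance, gradient-boosting gain — and then runs
spectral clustering on the |Spearman| affinity of the candidates, keeping
one randomly drawn feature per cluster (m clusters, default k = m = 50).
Clustering on correlations addresses the multicollinearity that the
pairwise prune cannot see.

Classification offers logistic regression, linear discriminant analysis,
a linear SVM, a random forest and gradient boosting with 100 trees (the
reference model). Evaluation protocols: stratified 5-fold CV with 10
repetitions, leave-one-donor-out CV, learning curves on stratified
training fractions, and recursive channel elimination in which
brightfield is always kept (15 subsets for a 4-fluorochrome panel; the
full-panel feature table is extracted once and sliced per subset, which
is exactly equivalent to rebuilding the inventory and much cheaper).
Pre-selection, when enabled, is refit inside each training fold — the
alternative leaks test information. Class imbalance is not reweighted, so
the plain macro F1 is the comparison metric; per-class F1 values come
from the unweighted harmonic means.

Explanation uses average gain: for each feature, the loss improvements of
all splits that use it are summed and divided by the number of those
splits, then normalized to a simplex. The 500-model protocol (5 stratified
folds × 100 repeats, each with a pre-selection size top-k drawn uniformly
from [30, 200]) ranks features by their median normalized gain across the
models where they were available, which de-biases the in-model importance
against pre-selection luck and outliers.

## Cleaning

Nine rules run in order with first-match attribution and a conservation
guarantee (retained + Σ removed = input, disjoint). Percentile thresholds
are computed within the donor × condition sample being cleaned and frozen
before any rule applies — per-sample thresholds keep conditions
independent, which matters because the downstream tests compare
conditions. Rules: (1) viability mean ≥ its 90th percentile; (2) BF
gradient RMS outside its (2nd, 90th) percentile band; (3) prediction
entropy > 1.0 nats; (4–7) class-conditional MHCII/CD3 intensity and area
sanity cuts; (8) an isolation forest (100 trees, subsample 256, 20
features per tree, anomaly score > 0.5) over the top-30 importance
features; (9) DBSCAN (eps 0.09, min_samples 5) on a 2-D UMAP embedding
(15 neighbors, min-dist 0.1) of the standardized top-30 features,
removing noise points and clusters rarer than 10⁻⁴.

Two behaviors of the published parameterization are worth knowing. The
isolation-forest auto threshold (score 0.5) flags a nontrivial fraction
(~10–15%) of even a clean Gaussian cloud; the package's implementation
reproduces the reference implementation's scores on shared fixtures, so
this is a property of the rule, not of this implementation. And the
density rule's eps is a *density* parameter: at desk-scale sample sizes
(hundreds to thousands of records) a UMAP embedding has nearest-neighbor
spacing comparable to 0.09, so most points are classified as noise; at
the six-figure sample sizes the rule was designed for, clusters are far
denser. Both parameters are exposed in `clean_params()`, and
`embed = "none"` runs the density logic directly in standardized feature
space, which is also how its removal semantics are unit-tested.

## Population statistics

Class frequencies are computed per donor × condition over the seven
analysis classes. Condition effects are summarized per donor as
log2(F_antibody / F_control); a zero frequency in either arm leaves that
donor/class undefined (no pseudo-count) with a warning. Because the
design is donor-paired with n = 6–7 donors, the per-class test is the
*exact* two-sided Wilcoxon signed-rank test of the donor log2FCs against
zero, with the null distribution enumerated over all 2^n sign patterns;
with six donors of consistent sign this gives p = 2/2⁶ = 0.03125, and
BH over seven classes with one non-significant class gives
0.03125 × 7/6 ≈ 0.036 — the arithmetic the donor-paired design implies. A
two-sample rank-sum variant is available (`test = "rank-sum"`) for strict
literalism, since the two tests are easily conflated in prose.

Feature differences restrict to records predicted 'synapse w/ signaling'
and compare antibody vs control per donor and feature with the two-sided
Mann-Whitney U test — exact by full enumeration up to 8 per arm and no
ties, tie-corrected normal approximation with continuity correction
otherwise — BH-corrected across features *within* each donor's
comparison (the families are independent experiments, and this matches
per-donor columns of a difference heatmap). Entries are coded +1/−1 by
median direction when significant, else 0, and cross-donor consistency
counts donors sharing a nonzero sign.

## Functional regression

Only records predicted as one of the two synapse classes enter, on the
assumption that synapses drive the downstream readout. Each
donor × condition group is aggregated to the 5th/50th/95th percentile of
every (consistency-filtered) feature — a multiple-instance summary
capturing the extremes and the average. The regression is an L1
(lasso) linear model fitted per left-out donor on columns standardized on
the training rows; the penalty is chosen by inner leave-one-row-out CV
over an explicit lambda grid reaching an effectively unpenalized fit
(the path-based choice suits the very low row count). Feature importance
is the |coefficient| ordering on the standardized scale. The three
percentile aggregates of one feature are nearly collinear, so support
recovery should be read at the feature level, not the column level. A
condition-holdout scheme (train on controls plus one activator, predict
the other) is supported.

## The synthetic generator

The simulator is the package's study system. Each class renders as a
deterministic disk layout (T cell radius 8 px, B-LCL 10 px on a 64×64
frame): touching disks for synapses, heavily overlapping disks for the
one-layer class, separated disks for non-interacting doublets, three
cells for multi-synapse, and a 3-px B-LCL for the small-B artifact.
Channel supports define the masks; intensities are Poisson shot noise on
the class-specific mean counts plus additive Gaussian noise (sd 50),
with optional Gaussian defocus blur for QC fixtures. Signaling classes
put P-CD3ζ on the T cell; in synapses, signal accumulates at the contact
zone — the zone (the same dilated-mask intersection the feature engine
measures) is painted at ρ × the channel's body level (default ρ = 2.5)
for F-actin, MHCII and P-CD3ζ, so measured enrichment exceeds 1 without
being numerically equal to ρ. Donor effects are a shared log-normal
multiplicative intensity factor (sd 0.1); conditions shift class
frequencies and per-channel intensity scales; a planted functional model
computes y = β·(aggregated features) + ε from the rendered records
themselves. Dead-cell fixtures draw the viability channel from a
high-intensity component.

What the simulator does *not* emulate: point-spread functions, spectral
spillover, segmentation errors, intra-class shape variability beyond
noise, or the absolute intensity distributions of real instruments.
Passing tests therefore demonstrate that the pipeline's machinery —
features, selection, classification, statistics — recovers planted
structure; they do not certify instrument-level performance on real data.

## Numerical choices and problem sizes

Sizes used by the test-suite and acceptance runs were chosen as the
smallest that leave comfortable statistical margins: a 2,700-record
nine-class cohort (three donors) for the classification benchmark
(F1-macro ≈ 0.99 against the ≥ 0.95 gate), 500 records per arm and six
donors for difference-map sign recovery at a one-pooled-sd shift, and
8 donors × 4 conditions for functional-model recovery. Deciles and
aggregation percentiles use interpolation type 7 throughout; GLCM
correlation of a zero-variance input is 1; all RNG flows through
per-stage seeds derived from one global seed, and parallel feature
extraction is bitwise-identical to serial because records are
independent.

## Known limitations

Real IFC data require upstream segmentation and spectral compensation,
which are out of scope. The cleaning density rule is scale-sensitive as
discussed. Exact rank tests fall back to tie-corrected approximations
when ties occur, so borderline p-values near coarse quantization should
be read with care. The full-inventory feature total is a convention, not
a universal constant.
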