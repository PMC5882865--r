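---
title: "Identifying insect migrants from radar-observable features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying insect migrants from radar-observable features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The identification problem

Entomological radar observes nocturnal insect migrants without
disturbing them, but it does not see species. What it can retrieve, from
the radar cross-section and its wingbeat-induced modulation, are a few
physical features per target: body mass, wingbeat frequency, and the
body length-to-width ratio. Body length is a plausible future fourth
feature. This package treats species identification as multiclass
classification over those features for a fauna of 23 migratory species,
using only the per-species summary statistics (mean, standard deviation,
observed range of each feature) that a trapping campaign produces.

The features carry very different information. Wingbeat frequency is
crowded — most moths in the fauna beat between 20 and 80 Hz — but three
species sit in exclusive bands far above it (S at 182–289 Hz, V at
120–155 Hz, W at 74–92 Hz) and are essentially self-identifying. Mass
spans 14 mg to 473 mg across species with much narrower within-species
spread, so it does most of the discriminative work; the shape ratio
separates slender-bodied from broad-bodied species of similar mass.

## The decision-tree SVM

SVMs are binary classifiers; the multiclass problem is decomposed into a
binary tree of N−1 two-class classifiers with N species at the leaves.
The tree topology is *not* arbitrary — it is derived from a scalar
measure of how separable two class groups are, the inter-class
separability factor

$$ dm_{ij} \;=\; \frac{d(\mathbf m_i, \mathbf m_j)}{\sigma_i + \sigma_j}, $$

the Euclidean distance between the group centers scaled by the summed
group spreads. Construction is agglomerative:

1. compute $dm_{ij}$ for every pair of current groups;
2. merge the pair with the smallest value (the hardest pair), treating
   the merged group as a single class from then on (its center and
   spread are recomputed from the pooled samples, not averaged from the
   sub-groups);
3. repeat until one group remains, then read the hierarchy top-down, so
   the final — most separable — merge becomes the root split.

The rationale for the ordering is error containment: a cascade can only
propagate errors downward, so decisions with the lowest expected
misidentification rate are placed where the most samples pass through.

Two quantities in $dm_{ij}$ require a convention the formula itself does
not fix:

* **The center** $\mathbf m_i$ is the arithmetic mean vector of the
  group's samples (the one-cluster K-means solution).
* **The spread** $\sigma_i$ must compress a multivariate scatter into a
  scalar. We define $\sigma_i^2$ as the *total scatter*: the trace of
  the group's covariance matrix, i.e. the sum of per-feature sample
  variances (with the usual $n-1$ normalization). This is the unique
  rotation-invariant scalar consistent with using a Euclidean distance
  in the numerator; equivalently, it is the expected squared distance of
  a group member from the center.

### Standardization

Raw features are incommensurate — masses reach hundreds of mg while the
shape ratio stays below ~13 — and an unstandardized Euclidean distance
would be a mass ruler. All separability computations and all SVMs
therefore operate in z-score space, with center and scale fitted on the
training cohort only and replayed onto test data. `build_tree(...,
standardize = FALSE)` disables this for strictly literal experiments.

### Tie-breaking and determinism

If two pairs share the minimal separability exactly, the pair whose
concatenated sorted label string sorts lexicographically first is
merged; left/right child order is likewise lexicographic. With this rule
the tree, the trained cascade and every prediction are deterministic
functions of the training data and hyperparameters.

### A note on merge-value monotonicity

Agglomerative merge criteria are not monotone in general: merging two
groups can produce a pooled group that is *less* separable from a
neighbor than the minimum at the previous step (the same inversion
phenomenon familiar from centroid-linkage dendrograms). Small inversions
do occur on the real cohort, so the package records the merge value per
node but deliberately does not assert that values decrease along every
root-to-leaf path; the guaranteed property is weaker and structural —
the root corresponds to the final, most separable merge.

## The node classifiers

Each internal node holds a two-class radial-basis SVM (LIBSVM via
`e1071`), trained on the training samples of the node's label set,
relabeled by the side of the split their species belongs to.

The source experiments do not record SVM hyperparameters, so they are a
design choice here. Two reference points constrain it. First, for
cohorts drawn from independent Gaussians per class, the Bayes-optimal
classifier is known in closed form (diagonal quadratic discriminant
analysis), so the generator implies a *ceiling* on attainable accuracy —
and the published accuracies sit essentially at that ceiling. Second, a
grid sweep (`tune_dtsvm()`) over cost and kernel width on full-size
cohorts shows the cascade's test accuracy climbing toward that ceiling
as regularization is relaxed, flattening once the boundary is flexible
enough. The defaults, `cost = 100` and `gamma = 2` on standardized
features, are the smallest values on the grid at which the plateau is
reached; softer settings (e.g. `cost = 1`) visibly underfit the narrow
boundaries between overlapping mid-mass species. Inverse-frequency class
weighting is available (`class_weights = TRUE`) for the 1-species-vs-22
splits near the root, but balanced cohorts showed no benefit — the
samples near the boundary, not the totals, decide these SVMs — so it is
off by default. All three settings are plain arguments, and the sweep
utility is exported precisely so users with different fauna can redo
this selection.

## Synthetic cohorts

`generate_cohort()` emulates the sample-extension step that turned a few
dozen to a few hundred specimens per species into 5,000: each species is
drawn from a normal distribution with its per-feature mean and standard
deviation. Defaults, and what they represent:

| parameter | default | meaning |
|---|---|---|
| `n_per_class` | 5000 | cohort size per species of the source experiments |
| `features` | mass, wingbeat frequency, length-to-width ratio | the radar-retrievable set; add `body_length` for the four-feature experiments |
| `correlations` | independent | see below |
| `truncate_to_range` | `FALSE` | unbounded Gaussians; see below |
| split fraction | 0.5 | stratified 50/50 train/test |

**Independence.** The original extension used the specimens' covariance,
which the published statistics do not include; only means and standard
deviations are printed. The generator therefore defaults to a diagonal
covariance and accepts per-species correlation matrices
(`correlations = list(A = ...)`) for users who hold raw specimen data.
This is the one structural respect in which the synthetic cohorts are
known to differ from the originals — mass and body length in particular
are surely correlated within species — and it is the main reason
reproduced accuracies can sit a point or two from the published ones.
The acceptance tolerances in the test suite absorb exactly this.

**Positivity and truncation.** All four features are physically
positive. Draws at or below zero are redrawn rather than clipped (no
point mass at zero); with species means 4–50 standard deviations above
zero this changes moments negligibly. Whether the original extension
truncated samples to each species' observed range is unstated; the
smooth Gaussian shape of the reconstructed distributions suggests not,
so `truncate_to_range` defaults to `FALSE` and redraws out-of-range
samples when enabled.

**What passing tests do and do not show.** The cohorts are exactly
Gaussian, independent across features, balanced, and free of
measurement artifacts, labeling errors, seasonal drift or
between-individual physiological state. Accuracy on them measures the
*separability of the published statistics under the stated error
model* — a property of the fauna and the features — not field
performance of any radar. A species absent from the training fauna will
be confidently misassigned; there is no "none of the above" leaf.

**The bundled statistics table.** Shipped as plain CSV and test-guarded
by spot checks. Three printed mass ranges are internally inconsistent
(inverted bounds, or incompatible with the printed mean) for species E,
T and U; they are stored as printed, flagged `mass_range_suspect`, and
excluded from the range-containment validation and from truncation.
Means and standard deviations — the only quantities generation uses —
are unaffected.

## The measurement-error model

Radar retrieval precision is emulated at the feature level:

* **wingbeat frequency**: additive Gaussian noise, $x + e$,
  $e \sim N(0, \sigma)$, with $\sigma = 1$ Hz in all built-in cases
  (the retrieval uncertainty of current radar);
* **mass, length-to-width ratio, body length**: multiplicative relative
  error, $x(1 + e)$, $e \sim N(0, s)$, so the realized root mean square
  percent error (RMSPE) converges to the nominal level $s$.

The four built-in cases follow the precision ladder of the source
experiments: Case I at today's retrieval accuracy (40% RMSPE on mass and
shape), Cases II and III tightening both to 20% and 10%, Case IV adding
body length at 10%. Errors are injected into *both* the training and
testing halves, and the tree is rebuilt and the cascade retrained on the
noisy training data — the scenario models a radar that can only ever see
noisy features, including at training time.

Numerical details:

* Perturbations that would destroy positivity (additive results ≤ 0, or
  factors $1 + e \le 0$) are redrawn. At the 40% level this truncates
  the relative-error distribution measurably: the realized RMSPE of the
  sign-preserving model is $\sqrt{E[e^2 \mid e > -1]} \approx 0.391$
  rather than 0.400. The tests pin this closed form explicitly rather
  than pretending the untruncated value is achieved.
* Noise is drawn from an independent RNG sub-stream per species (keyed
  on the seed and the label), which makes injection commute with
  per-species subsetting — noising a subset reproduces the
  corresponding rows of the noised whole.
* A log-normal alternative for the relative errors was considered and
  rejected as default: the Gaussian factor model is the simplest whose
  realized RMSPE matches the nominal definition, and nothing in the
  precision ladder depends on the error tail shape at these levels.

## Experiment runners and reproducibility

`run_identification()` chains the whole pipeline — generate, split,
optionally corrupt, standardize, build, train, predict, score — under a
single master seed from which the generation, split and two noise
streams derive fixed sub-seeds. Identical configurations therefore
produce identical reports, byte-for-byte on disk (`write_report()`).
`run_accuracy_study()` (3- vs 4-feature, noise-free),
`run_error_study()` (Cases I–IV) and `run_precision_sweep()` (arbitrary
error grids) are matched-seed wrappers over it.

Per-species accuracy is recall — the diagonal of the confusion matrix
over its row sum — and the summary accuracy is the *unweighted* mean
over species, the natural choice for balanced test cohorts. Accuracies
are stored at full precision and rounded only for presentation.

```{r example}
library(dtsvm)
study <- run_accuracy_study(n_per_class = 5000, seed = 1)
accuracy_table(study)
errors <- run_error_study(n_per_class = 1000, seed = 1)
sapply(errors, `[[`, "mean_accuracy")
```

### Problem sizes in the shipped tests

The unit tests run the pipeline on reduced cohorts (tens of samples per
species, or a six-species subset) where only structure and determinism
are at stake. The scientific end-to-end checks use 1,000 samples per
species for the noise-free comparisons and 2,500 for the
measurement-error scenarios — sizes at which the mean accuracy is stable
to well under a percentage point of the full-scale value, chosen so the
whole suite stays comfortable to run routinely. The acceptance script
uses the full 5,000 per species for the noise-free studies.

## Known limitations

* Independence across features in generated cohorts (see above) — the
  dominant approximation.
* No rejection class: the cascade always ends in one of the training
  species.
* The separability factor is Euclidean after global standardization; no
  Mahalanobis or per-class metric variants are offered.
* Accuracies quantify the 23-species Bohai Gulf fauna; other sites and
  seasons require their own statistics tables (the pipeline accepts any
  table in the bundled CSV layout).
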