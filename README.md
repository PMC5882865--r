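# dtsvm

Species identification of migratory insects from the physical features an
entomological radar can retrieve.

## The problem

Zenith-pointing entomological radar can estimate three physical features
of an insect flying overhead from its radar cross-section: body **mass**
(mg), **wingbeat frequency** (Hz), and the body **length-to-width ratio**
(a shape descriptor). **Body length** (mm) is not yet radar-measurable
but is a natural fourth candidate. This package asks how far those
features go toward identifying *which species* is migrating — a
multiclass classification problem over 23 migratory species (Lepidoptera
and Odonata) trapped in the Bohai Gulf migration corridor — and how the
answer degrades at realistic radar measurement precision.

It is aimed at radar entomologists and quantitative ecologists who want
to (a) reproduce the published identification accuracies from the
published per-species statistics alone, (b) rerun the analysis with
their own trapped-specimen statistics, or (c) ask what measurement
precision a future radar needs.

## The method

A decision-tree SVM (DTSVM). The N-class problem is converted into N−1
two-class problems arranged in a binary tree:

1. For the current set of class groups, compute every pairwise
   **inter-class separability factor**

   dm_ij = d(m_i, m_j) / (σ_i + σ_j)

   where d(m_i, m_j) is the Euclidean distance between the group centers
   and σ_i² is the total scatter (trace of the covariance matrix) of
   group i, all in z-score-standardized feature space.
2. Merge the pair with the *smallest* dm_ij — the hardest pair to
   separate — and repeat until one group remains.
3. Read the merge hierarchy top-down: the final, most separable merge
   becomes the root split, so the easiest decisions are made first and
   misrouting on hard pairs cannot contaminate the rest of the cascade.

Each internal node gets a two-class radial-basis SVM (via
[e1071](https://cran.r-project.org/package=e1071)/LIBSVM) trained on the
samples of its label set; a test sample cascades from the root to a leaf,
and the leaf is the predicted species.

Training cohorts are regenerated from per-species summary statistics
(mean and standard deviation of each feature): each species is extended
to 5,000 Gaussian samples and split 50/50 into training and testing
halves. Radar measurement precision is emulated by injecting additive
Gaussian wingbeat noise (σ in Hz) and multiplicative relative errors
(calibrated by RMSPE, the root mean square percent error) into both
halves before the tree is rebuilt and retrained.

## Worked example

```r
library(dtsvm)

stats <- load_species_stats()          # bundled 23-species statistics
res <- run_identification(n_per_class = 1000, seed = 1)
res
#> Identification accuracy over 23 species
#>    A    B    C    D    E    F    G    H    I    J    K    L    M    N    O    P
#> 0.95 0.99 0.80 0.91 0.97 0.98 1.00 0.97 0.89 1.00 0.85 0.99 0.83 0.98 0.98 1.00
#>    Q    R    S    T    U    V    W
#> 1.00 1.00 1.00 0.82 1.00 1.00 1.00
#> Mean: 0.95
```

Each number is the per-species recall on the held-out test half: the
fraction of that species' test samples routed to the correct leaf. The
mean is unweighted across species. Species S (*Macroglossum
stellatarum*, wingbeat 182–289 Hz, far above every other species) is
identified perfectly; the residual confusion sits in the cluster of
mid-mass noctuids (C, M, K).

The trained cascade itself is inspectable:

```r
model <- attr(res, "model")
tree_to_text(model$tree)
#> (((((((((A,(E,(((F,K),N),I))),(T,U)),(B,(((C,M),L),D))),((G,P),Q)),(J,W)),V),R),(H,O)),S);
```

The root split isolates S — the most separable class — and the hardest
pairs (F/K, C/M) sit deepest in the tree, exactly as the separability
ordering intends.

Precision scenarios (Cases I–IV: wingbeat σ = 1 Hz throughout; mass and
length-to-width RMSPE 40% → 20% → 10%; Case IV adds body length at 10%):

```r
errors <- run_error_study(n_per_class = 1000, seed = 1)
sapply(errors, `[[`, "mean_accuracy")
#>         I        II       III        IV
#> 0.5273913 0.6919130 0.8234783 0.8667826
```

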