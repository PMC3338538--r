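---
title: "Decoding paced and self-paced fMRI sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding paced and self-paced fMRI sessions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpadecode)
```

## The problem

Multi-voxel pattern analysis (MVPA) decodes a mental state — here, which
of three image categories (faces, buildings, animals) a person is viewing
or imagining — from the joint activity of many voxels. Two session types
stress a decoder differently. A *paced* session presents stimuli on a
fixed schedule in blocks (27 images of 3 s each, 9 per category, the
whole maze traversed repeatedly), giving balanced classes and long,
clean category segments. A *self-paced imagery* session lets the subject
generate 54 short mental paths of 3–6 same-category images, pressing a
key per recalled image. Durations vary from 200 ms to 4 s, events of
different categories follow each other closely, and categories that are
harder to remember produce fewer events — the data are imbalanced and
temporally entangled. This package implements the full decoding pipeline
for both regimes and a synthetic-data generator that emulates them, so
every stage is testable without scanner data.

## Signal model and extraction

The BOLD signal is modelled per voxel as baseline plus the sum of each
category's event boxcar convolved with the canonical double-gamma
hemodynamic response (response gamma with shape 6 and rate 1, mode 5 s;
undershoot gamma with shape 16, amplitude ratio 1/6), plus
low-frequency drift, motion-coupled nuisance signal, and AR(1) Gaussian
noise. Note a geometric consequence used by the tests: the response to a
single 3 s stimulus peaks ≈ 6.6 s after onset (the argmax of the
convolved kernel), consistent with the conventional 6 s hemodynamic
delay used for window placement.

Extraction proceeds in the order the analysis assumes:

1. **Confound regression** on the whole session: OLS residuals of every
   voxel on an intercept, six motion regressors, and a discrete-cosine
   high-pass basis with cutoff 1/128 Hz (`floor(2 * n_scans * TR *
   cutoff)` columns). A strictly linear trend is attenuated to a few
   percent but not annihilated — only in-span drifts are removed
   exactly.
2. **Windowing.** Scans are assigned to events by their acquisition
   midpoints against half-open windows `[start, end)` — the package's
   convention wherever a scan meets an interval. For paced events the
   window is `[onset + 6 s, onset + 6 s + 3 s)`. For imagery events the
   window runs between consecutive delay-corrected key presses,
   truncated to the last 2 scans (4.08 s at TR 2.04 s) before the key
   press, so motor activity after the press and task-unrelated thought
   before it are excluded.
3. **Overlap exclusion.** A scan assignable to two different events is
   removed from both, so no TR mixes two stimuli. Events left without
   scans produce no sample; they are recorded in the sample set's
   provenance so class counts stay auditable.

The hemodynamic-delay shift is applied in continuous time (6 s is not a
multiple of TR = 2.04 s); rounding to whole scans would bias window
contents systematically.

## Feature selection

Two univariate filters operate on omnibus F statistics (every category
effect tested jointly against a confound-only model, per voxel): the
*global* filter keeps voxels with `F > 0.5` (strict inequality), the
*specific* filter keeps the 1000 largest-F voxels (ties at the boundary
broken by lowest index). Inside the cross-validation the F map is
computed from training samples only, as a one-way layout across the
three classes — equivalent in content to the time-series GLM route that
is also provided.

The multivariate step is Recursive Feature Addition (RFA): for each
binary comparison a linear SVM ranks voxels by `|w|`, and candidate sets
grow over the per-condition grid 5, 30, 55, 80, 105, 130, 150 (from 5
in steps of 25, capped at 150 — the cap honors the stated upper bound
that the step sequence does not land on). At each size the *global
accuracy* — the sum of the three binary accuracies on an inner left-out
block, averaged over all inner leave-one-block-out folds — is recorded.
Iteration stops when the global accuracy falls strictly below both of
the two preceding iterations; the selected size is the argmax over
everything evaluated, and the final voxel set is the union over
comparisons and conditions of the top-`n*` voxels ranked on the full
training set. Averaging over all inner folds (rather than using a
single fold) is the lower-variance reading of the procedure and is the
package's choice.

## Classifiers

**Linear SVM.** Soft-margin, `C = 1`, no feature scaling, no class
weights (LIBSVM via e1071). The fit object exposes the weight vector
(for RFA ranking), the support vectors and dual coefficients (for the
support-vector proportion analyses). A decision value of exactly zero
votes +1 — a documented tie convention.

**GP with expectation propagation.** Binary Gaussian-process
classification with a probit likelihood and an inhomogeneous linear
kernel `K = sigma^2 <x, x'> + sigma0^2`, both terms tied to the single
hyperparameter sigma (`sigma0^2 = sigma^2`). The kernel matrix is
centered independently for the training and test blocks (each block's
own row/column means; equivalent to subtracting each block's own feature
mean), which annihilates the bias term; the conventional
train-statistics centering is available as `centering = "train"` for
robustness checks. After centering, the training kernel is scaled to
unit mean diagonal (trace normalization). This is a numerical choice
with a modelling face: it makes sigma the latent prior scale regardless
of voxel count and signal units. Without it the latent scale grows like
the product of voxel count and signal variance, the probit saturates,
and EP site parameters diverge. EP runs damped sequential site updates
(damping 0.8) until the largest site-parameter change is below 1e-4 or
100 sweeps; site precisions are clamped nonnegative. `log(sigma)` is
initialized at 1; optional refinement maximizes the EP log marginal
likelihood from that starting point (`optimize_sigma = TRUE`). The
refinement is off by default in the pipeline: sigma only scales a fixed
centered kernel, class rankings are weakly sensitive to it, and the
refinement multiplies EP cost roughly eightfold per binary fit. The log
marginal likelihood is computed in a decomposition that stays finite as
site precisions tend to zero, and is verified against tensor-product
Gauss–Hermite quadrature on small instances.

## Multiclass assembly and evaluation

Three binary comparisons (F–B, F–A, B–A) are combined by
error-correcting output codes. SVM votes are compared with the
prediction codewords (faces 1,1,0; buildings −1,0,1; animals 0,−1,−1)
by Hamming distance, counting every mismatch including votes against
0-entries; GP probabilities (each oriented as the probability of the
comparison's first-named class) are compared with the probability
codewords (faces 1,1,0.5; buildings 0,0.5,1; animals 0.5,0,0) by the sum
of absolute differences. On hard probabilities the two distances are
affinely related (`d_prob = d_Hamming − 0.5` row-wise), so the schemes
rank classes identically there; exact ties are broken uniformly at
random, flagged in the output, and reproducible under the run seed.

Five procedures combine these parts: P1 specific/SVM, P2 specific/GP,
P3 global+RFA/GP, P4 specific+RFA/GP, P5 specific+RFA/SVM. Evaluation
is leave-one-block-out over blocks (27 consecutive paced images, or the
events of 6 consecutive imagery paths — 15 and 9 folds under the
default designs), with a double loop for the RFA procedures so feature
selection never sees the test block. The accuracy measure is balanced
accuracy, the unweighted mean of per-class accuracies. Significance
comes from permuting training labels *within each block* (preserving
per-block class frequencies, respecting temporal correlation), rerunning
the full procedure — including feature selection — and comparing the
observed balanced accuracy to 100 permutation replicates per
cross-validation step (1500 total label shuffles for the paced session,
900 for imagery). The r-th permutation of every fold is paired into one
subject-level null value by default (`mode = "paired"`, 100 nulls);
pooling all fold-level values is available as `mode = "pooled"`. The
p-value uses the finite-sample correction
`(1 + #{null ≥ observed}) / (1 + n_perm)`, which keeps p positive.

Group-level comparisons are rank-based throughout: Friedman tests with
mid-ranks and tie correction, paired Wilcoxon signed-rank tests (zeros
dropped, exact for up to 25 non-zero pairs, Bonferroni families of 3
for category tests and 10 for the five procedures' pairwise
comparisons), and Spearman correlations.

## The synthetic generator: what it emulates, what it does not

The generator reproduces the two sessions' statistical structure:
paced blocks of 27 stimuli (9 per category in fixed order, 3 s each,
15–18 s fixation between blocks, 5 traversals, TR 2.04 s), and 54
self-paced paths of 3–6 same-category images (lengths balanced so the
planned mean is 4.5; planned category counts equal). Class imbalance
arises mechanistically: each planned image is recalled with a
category-specific probability, so recall `(1, 0.65, 0.93)` yields mean
event proportions ≈ (0.39, 0.25, 0.36), the profile of the bundled
per-subject event-count table. Within a path, events follow each key
press after a 0–500 ms jitter — the generator's stand-in for unstated
inter-event pacing — with durations uniform on 0.2–4 s, a 4 s cue
before each path and 6 s between tests. Activation patterns assign each
category `n_informative` voxels at a constant amplitude with a
controllable pairwise overlap fraction. Noise defaults: AR(1)
coefficient 0.3 (the minimal temporally correlated model; the sessions'
true noise spectrum is unknown), unit marginal noise sd, drift and
motion leakage of order the signal.

What it does *not* emulate: scanner artifacts (spikes, field
inhomogeneity, slice-timing), anatomically realistic geometry or
spatial autocorrelation, genuine hemodynamic nonlinearity, or
subject-level variability in HRF shape. Passing tests therefore show
that the pipeline's inferential machinery is correct and recovers
planted structure under its own forward model — not that real scanner
data would reach any particular accuracy.

## Numerical choices and degenerate inputs

* Scan/window assignment: midpoints against half-open intervals; ties
  impossible off a measure-zero set.
* Rank-deficient confound matrices fall back to a pseudo-inverse fit
  with a warning; singular GLM designs are an error naming the
  collinear columns.
* RFA requires at least 3 outer folds (so the inner loop has ≥ 2
  blocks); filter-only procedures require 2.
* Training folds missing a class are skipped with a warning, not
  imputed; balanced-accuracy denominators stay correct.
* Ranking ties (equal `|w|`, equal F) break by lowest voxel index.
* EP guards: nonnegative site precisions, damped updates, skipped
  pathological cavities, error on non-finite site parameters.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run reduced problem sizes chosen to exercise every
code path at comfortable margins: exploration sessions of 1–2
traversals (3–6 blocks) at 120–400 voxels, imagery sessions of 54 paths
at 500 voxels with the top-250 filter, 10–20 seeded replicates for the
stochastic properties, and 3-point instances for the quadrature
oracles. These sizes are stated here as the package's reference
conditions for its own verification experiments; the defaults of the
user-facing functions remain the full reference settings (top-1000
filter, 5 traversals, 100 permutations per fold).

## Known limitations

* The imagery extraction assumes key presses mark event *ends*; designs
  where presses precede visualization would need a shifted window.
* The independent test-block kernel centering makes single-point test
  blocks degenerate (a centered 1×1 block is zero); the evaluation
  always classifies whole blocks, where this cannot occur.
* RFA cost grows with folds × grid × comparisons; the implementation
  reuses rankings across grid values but is deliberately faithful
  rather than approximate.
* Group statistics assume exchangeable subjects; no hierarchical model
  is provided.
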