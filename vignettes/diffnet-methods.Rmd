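---
title: "DiffNetR: model, training procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DiffNetR: model, training procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(DiffNetR)
```

This vignette is the package's account of the method it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A DiffNet is a supervised autoencoder over whitened backbone coordinates.
The pipeline is:

1. **Featurization.** Frames are restricted to backbone atoms without
   carbonyl oxygens (C, CA, CB, N; glycine contributes three atoms because
   it has no CB), rigid-body superposed onto an origin-centered reference
   (optimal least-squares rotation over all selected atoms, uniform
   weights), mean-shifted and whitened with the inverse square root of the
   pooled covariance. Whitening decorrelates the inputs and normalizes
   their variance, so the network does not simply chase the largest
   motions. The transform is fit once on the pooled frames of all training
   variants — never per variant — so all variants share one coordinate
   embedding. Internally everything is in nanometres; Angstroms appear only
   at reporting boundaries (e.g. the 4.2 Å hydrogen-bond rule used for
   compact/extended helix labels is converted once).

2. **Architecture.** Input → reduction → latent → expansion → output, with
   the whitening/unwhitening installed as frozen first/last layers. The
   reduction layer always performs a four-fold reduction
   (`ceiling(input/4)`). The architecture may be *split*: encoder A
   receives the atoms within a cutoff (default 1.0 nm) of a target residue,
   encoder B the rest, and the total latent dimension is divided between
   them proportionally to atom counts (largest-remainder rounding, minimum
   one per encoder; 30 latent variables over a 2:13 atom split give 4+26).
   Each encoder whitens only its own atoms' coordinates: the block
   transform is re-derived exactly from the pooled covariance submatrix, so
   the supervised sub-latent — and therefore the classifier — depends only
   on encoder A's atoms. The classification head is a logistic unit reading
   the *post-nonlinearity* values of the supervised sub-latent (the source
   is ambiguous in principle; reading the activated latent keeps the head a
   simple linear probe of the representation that downstream analyses also
   see, and the choice is documented here and pinned by tests).

3. **Losses.**
   `reconLoss` is the batch/node mean of `|e| + e²`: the L1 part funnels
   reconstructions toward the target, the L2 part penalizes outliers.
   Residuals are taken in whitened coordinates — the frozen layers live
   inside the model, so this is the natural space; reporting-level RMSD is
   computed after unwhitening. `classLoss` is the (negated) binary
   cross-entropy; it is linear in fractional targets, which is what the EM
   labels are. `corrLoss` sums squared off-diagonal latent covariances over
   the batch, with the biased (1/N) normalizer — a documented constant that
   does not change the minimizer. The total is the unweighted sum by
   default; the classification weight set to 0 (with EM off) gives the
   matched unsupervised-autoencoder baseline.

## Self-supervision by expectation maximization

Variant-level labels say nothing about individual frames, and the
ensembles overlap, so all-0/all-1 frame labels are a misleading
oversimplification (the classifier would simply memorize ensemble
membership). The E-step therefore replaces each frame's label by its
conditional expectation given per-class bounds on how many frames in its
batch may be "positive". Treating the batch as independent Bernoulli
variables parameterized by the classifier outputs, the batch count follows
a Poisson-binomial law computed by sequential convolution; each frame's
update divides the probability that the *leave-one-out* count stays in the
shifted window by the probability that the full count is in the window.
Numerical and structural choices:

* Fractional bounds convert to counts as `S_L = ceiling(lower * n)`,
  `S_U = floor(upper * n)`, then `S_L = min(S_L, S_U)`.
* E-step batches are class-homogeneous, seeded random partitions of each
  class's training frames, sized like the training batch (32) by default,
  so each class's own bounds apply; a trailing batch smaller than two is
  merged into its predecessor.
* Classifier outputs are clamped to `[1e-7, 1 - 1e-7]` before the
  Poisson-binomial computation; a window of zero probability raises a
  degenerate-constraint error naming the class and batch.
* Leave-one-out laws are recomputed without the frame (O(n²) per batch in
  compiled code) rather than deconvolved — exact, and cheap at n = 32.
* Default bounds are 0–30% for the negative class and 60–90% for the
  positive class; the duty-ratio preset uses 10–40% / 60–90%.
* With bounds (0, 1) on both classes the E-step is the identity on the
  classifier outputs; per batch, the updated labels always sum to the
  conditional expectation of the count, which lies inside `[S_L, S_U]`.
  Both properties, and exact agreement with 2ⁿ enumeration for n ≤ 12, are
  enforced by tests.

## Training procedure

Three progressive stages of 20 epochs each (Adam, learning rate 1e-4,
batch 32, optimizer state reset at stage boundaries, since the stages are
separate trainings):

1. a shallow autoencoder (input → reduction → output, no bottleneck)
   trained on reconstruction only, producing priors for the reduction
   layer;
2. the full network with those priors exactly frozen (verified bit-for-bit
   by tests), training bottleneck, decoder and classifier;
3. full fine-tuning of all non-whitening weights.

A 10% validation split, stratified per variant, is held out before
training; the returned model is the per-epoch snapshot (stages 2–3) with
the lowest *validation reconstruction* loss, earliest epoch on ties.
Validation frames are excluded from EM refinement so model selection stays
unbiased. When EM is enabled the E-step runs after every epoch that has a
classifier — stages 2 and 3; stage 1 has no classification head, so no
outputs exist to condition on. Everything is deterministic given the three
seeds (initialization, shuffling/validation split, EM batching); no
gradient clipping is applied.

Weight initialization is fan-in-scaled uniform, seeded. All hidden layers
(reduction, latent, expansion) use the logistic nonlinearity with a linear
final whitened-output layer; the hidden nonlinearity is configurable in
the architecture spec but the logistic default is what the tests pin.

## The synthetic-data generator

`generateToyEnsembles()` emulates the structure of the motivating setting:
two classes of variant ensembles that *overlap*, distinguished only by the
probability of a geometrically subtle feature under large-amplitude
irrelevant motion. The template is a regular 30-residue zig-zag
pseudo-backbone (four points N/CA/CB/C per residue, ~0.38 nm spacing) so
the backbone atom-name filters apply unchanged. Per frame, independently:

* the compact/extended state is drawn with the class probability
  (defaults 0.75 / 0.25 — chosen once so the true positive fractions sit
  inside the default EM bounds of 60–90% / 0–30%);
* the second feature atom is placed at exactly 0.50 nm (compact) or
  0.58 nm (extended) from the first — a 0.8 Å difference. The displacement
  is transverse to the template pair axis: the chain itself runs along
  that axis, and displacing along it would make every pair between the
  feature atom and a chain neighbor exactly as state-sensitive as the
  planted pair, i.e. a non-identifiable planting;
* a five-residue "loop" (residues 23–27) is displaced rigidly along one
  fixed random direction with a per-frame Gaussian coefficient of 0.5 nm
  RMS — a single low-rank collective nuisance mode, an order of magnitude
  larger than the feature;
* isotropic thermal jitter of 0.02 nm per coordinate is added — small
  enough that the 0.8 Å feature remains resolvable in principle
  (the distance noise is ~0.03 nm), which keeps the difficulty where it
  belongs: in the amplitude disparity, not in an unlearnable noise floor.

What the generator does **not** emulate: temporal autocorrelation (frames
are i.i.d.), force-field realism, sidechain or solvent degrees of freedom,
anharmonic or multi-mode nuisance structure, and sequence heterogeneity
across variants. Passing tests on this fixture therefore demonstrate that
the machinery does what it claims under controlled conditions — a planted,
subtle, probabilistic feature is found and attributed — not that any
particular real system will behave the same way.

## Numerical choices

* Whitening uses a symmetric eigendecomposition with an eigenvalue floor
  of 1e-8 nm²; eigenvalues at or below the floor are excluded
  (pseudo-inverse). Rank deficiency is expected — superposition removes
  six rigid-body degrees of freedom, and fewer frames than 3N leaves rank
  at most frames − 1. The whiten/unwhiten pair is exact on the retained
  subspace.
* The Kabsch rotation uses SVD with the determinant correction; degenerate
  (collinear/coincident) references raise an explicit error.
* Cross-entropy clamps outputs at 1e-7; Poisson-binomial windows are
  evaluated in plain double precision (an underflowing window is treated
  as infeasible, which is the conservative behavior).
* Checkpoint-selection ties break toward the earliest epoch; k-medoids
  refinement runs 5 sweeps with medoids chosen by minimal summed distance;
  greedy k-centers seeds its first center from the supplied seed.
* Distance-correlation scans skip zero-variance pairs (counted and
  reported with the selection denominator) and exclude intra-residue pairs
  up front — they are near-rigid and would be skipped anyway. The top-1%
  percentile is taken over non-skipped pairs.

## Problem sizes

The end-to-end checks run the default generator conditions: 4 variants ×
4000 frames × 120 atoms (16,000 frames, 360 coordinates), 30 latent
variables split 6+24 around the feature residue, three 20-epoch stages for
both the DiffNet and the matched baseline autoencoder, 200 cluster centers
for attribution and 100 label permutations as the negative control. These
sizes were chosen so a complete analysis is a desk-scale computation while
every qualitative phenomenon of interest — latent reorganization by the
classification task, the EM label continuum, attribution of the planted
pair — is measurable with margin.

## Known limitations

* The architecture is not rotation/translation invariant; results depend
  on the quality of the initial superposition, exactly as for the
  underlying method.
* Trajectory input is PDB + DCD; XTC is not read (no suitable reader
  exists in the R ecosystem this package builds on).
* Prediction on new variants is only meaningful inside the training
  distribution; frames outside the training whitened-feature range are
  flagged as extrapolating and summaries warn when every frame
  extrapolates.
* Multi-protein training (variants with different sequences) requires the
  user to supply a shared atom set; the package does not infer
  cross-sequence atom correspondences.
* Equilibrium reweighting (e.g. Markov-state-model populations) is out of
  scope; analyses weight frames uniformly.
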