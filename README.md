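# DiffNetR

Self-supervised autoencoders for comparing protein conformational ensembles.

## The problem

Molecular-dynamics simulations of protein variants produce enormous,
highly-overlapping ensembles of structures. The structural signature that
explains a biochemical difference between variants — say, a stability change
caused by a point mutation — is often a sub-Angstrom shift in the
*probability* of a subtle feature, buried under much larger irrelevant
motions. Standard dimensionality reduction (PCA, plain autoencoders)
emphasizes large geometric variance and misses such signals.

DiffNetR implements **DiffNets**: supervised autoencoders whose
low-dimensional latent space must simultaneously (i) reconstruct the input
structure and (ii) predict the biochemical label of the variant the
structure came from. The classification constraint reorganizes the latent
space around the label-relevant degrees of freedom, however geometrically
subtle. Because only variant-level labels are known (not per-frame labels),
a self-supervised expectation-maximization (EM) scheme refines the
per-frame training labels into a continuum.

The package is aimed at computational biophysicists with per-variant MD
trajectories (PDB topology + DCD trajectories) and a binary biochemical
label per variant, and at method developers: a synthetic-ensemble generator
reproduces the whole setting at desk scale, so every stage is testable
without MD data.

## The model

Frames are reduced to backbone coordinates without carbonyl oxygens
(C, CA, CB, N), superposed on a reference, mean-shifted and whitened,

&nbsp;&nbsp; x̃ = C₀₀^(−1/2) (x − x̄),

with the whitening and its inverse installed as frozen network layers. An
encoder (optionally split into a supervised encoder A over a region of
interest and an unsupervised encoder B over the rest) maps x̃ through a
four-fold reduction layer to a latent vector z; a decoder reconstructs x̃,
and a logistic head ŷ = σ(w·z_A + b) classifies from the supervised
sub-latent. Training minimizes

&nbsp;&nbsp; L = ℓ_recon + ℓ_class + ℓ_corr

where ℓ_recon is the mean of |x̃−x̂| + (x̃−x̂)² over batch and output nodes,
ℓ_class is binary cross-entropy against the (possibly fractional) per-frame
labels, and ℓ_corr = Σ_{i≠j} Cov(z_i, z_j)² decorrelates the latent
variables. Training is progressive (three 20-epoch stages: shallow
pretraining of the reduction layer, bottleneck training with frozen priors,
full fine-tuning; Adam, learning rate 1e-4, batch 32), with the checkpoint
chosen by validation reconstruction loss.

In the self-supervised mode, after each epoch the labels are replaced by
their conditional expectations given per-class bounds on how many frames of
a batch are "positive": with the batch count treated as a Poisson-binomial
variable parameterized by the classifier outputs ŷ,

&nbsp;&nbsp; y_i = ŷ_i · P(S_L−1 ≤ ŷ_r − ŷ_i ≤ S_U−1) / P(S_L ≤ ŷ_r ≤ S_U),

computed exactly by sequential convolution with leave-one-out recomputation.

Interpretation utilities quantify what the network learned: frozen-latent
cross-validated ROC/AUC, hybrid k-centers/k-medoids clustering,
distance-correlation scans ranking atom pairs whose distance tracks the
model output, label-binned distance profiles, and prediction on variants
never seen in training.

## Worked example

Generate a two-class synthetic ensemble (0.8 Å planted feature under a 5 Å
nuisance mode), train a split DiffNet with EM, and ask how well the
supervised sub-latent separates the planted states:

```r
library(DiffNetR)

spec <- toyEnsembleSpec(nFramesPerVariant = 500L)
ens  <- generateToyEnsembles(spec)
cfg  <- trainingConfig(learningRate = 1e-3, epochsPerStage = 10L, emEnabled = TRUE)
fit  <- trainDiffNet(ens$dataset, cfg, totalLatent = 30L, targetResidue = 14L)
fit
#> diffnetFit:
#>   DiffNet (split): input 75+285 -> reduction 19+72 -> latent 6+24 (classifier on latent A)
#>   selected checkpoint: stage 3 epoch 5 (validation recon 1.79196)
#>   1800 training / 200 validation frames

nA <- fit$model@spec@latentDims[1]
frozenLatentRoc(encode(fit$model, fit$dataset)[, 1:nA], ens$truth$compact)
#> rocResult: mean AUC 0.919 over 5 folds (sd 0.013)

10 * reconstructionRmsd(fit$model, fit$dataset)   # Angstrom
#> [1] 1.45
```

The AUC says a logistic regression on the six supervised latent variables
recovers the planted compact/extended state of each frame (0.92 here at
demo scale; ~0.99 at the full 4000-frames-per-variant conditions), even
though the feature is an 0.8 Å distance change under 5 Å nuisance motion —
the same matched unsupervised autoencoder stays near 0.74. The
reconstruction RMSD (~1.4 Å) confirms the latent space still encodes
structure. Per-variant mean output labels separate the classes
(`pos1/pos2` 0.466/0.467 vs `neg1/neg2` 0.448/0.449 in this run), and a
held-out variant generated from the negative class scores below every
positive training variant (mean label 0.451).

A thin command-line wrapper covering the same pipeline
(`simulate`, `featurize`, `train`, `analyze`, `predict`; YAML config, JSON
run manifests) is installed at `inst/scripts/diffnets.R`.

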