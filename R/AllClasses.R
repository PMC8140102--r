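#' @import methods
#' @importFrom stats cov rnorm runif sd setNames quantile
#' @importFrom utils head tail read.table write.table
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' EnsembleDataset: aligned backbone coordinates with variant provenance
#'
#' Container for a pooled set of molecular-dynamics frames across protein
#' variants. Coordinates are stored in nanometres as a frames x atoms x 3
#' array; every frame shares one atom table (backbone C, CA, CB, N only) and
#' each frame carries the id of the variant it came from. Each variant maps
#' to exactly one binary class label (e.g. stabilizing vs non-stabilizing).
#'
#' @slot coords numeric array, frames x atoms x 3, in nm.
#' @slot atoms data.frame with columns `resid`, `resname`, `name` (atom name,
#'   one of C, CA, CB, N), one row per atom, in coordinate order.
#' @slot variant factor of length frames: the variant each frame belongs to.
#' @slot classLabels named integer vector (0/1), one entry per variant level.
#' @slot reference numeric matrix atoms x 3: the reference structure used for
#'   superposition, in nm.
#'
#' @exportClass EnsembleDataset
setClass("EnsembleDataset",
  representation(
    coords = "array",
    atoms = "data.frame",
    variant = "factor",
    classLabels = "integer",
    reference = "matrix"
  )
)

setValidity("EnsembleDataset", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (!all(is.finite(object@coords)))
    return("coords must be finite")
  if (nrow(object@atoms) != d[2])
    return("atom table rows must equal the atom dimension of coords")
  if (!all(c("resid", "resname", "name") %in% names(object@atoms)))
    return("atom table needs columns resid, resname, name")
  if (!all(object@atoms$name %in% c("C", "CA", "CB", "N")))
    return("atom names must be C, CA, CB or N (backbone without carbonyl oxygens)")
  if (length(object@variant) != d[1])
    return("variant must have one entry per frame")
  if (is.null(names(object@classLabels)) ||
      !all(levels(object@variant) %in% names(object@classLabels)))
    return("every variant level must map to exactly one class label")
  if (!all(object@classLabels %in% c(0L, 1L)))
    return("class labels must be binary (0/1)")
  if (!identical(dim(object@reference), c(d[2], 3L)))
    return("reference must be an atoms x 3 matrix")
  if (!all(is.finite(object@reference)))
    return("reference coordinates must be finite")
  TRUE
})

#' WhiteningTransform: mean-shift plus covariance inverse-square-root
#'
#' Holds the featurization transform fit on pooled, aligned training frames:
#' the coordinate mean, the pooled covariance, and the whitening /
#' unwhitening matrices obtained by eigendecomposition with a variance floor
#' (eigenvalues below the floor are dropped, i.e. a pseudo-inverse square
#' root). In the model these act as frozen, untrainable input/output layers.
#'
#' @slot mean numeric, length 3N, nm.
#' @slot covariance numeric 3N x 3N pooled covariance (kept so that exact
#'   sub-region transforms can be derived for split architectures).
#' @slot whitening numeric 3N x 3N, the pseudo-inverse square root of the
#'   covariance.
#' @slot unwhitening numeric 3N x 3N, the matching square root.
#' @slot rank integer, retained rank.
#' @slot floor numeric, eigenvalue floor in nm^2.
#'
#' @exportClass WhiteningTransform
setClass("WhiteningTransform",
  representation(
    mean = "numeric",
    covariance = "matrix",
    whitening = "matrix",
    unwhitening = "matrix",
    rank = "integer",
    floor = "numeric"
  )
)

setValidity("WhiteningTransform", function(object) {
  n <- length(object@mean)
  if (!identical(dim(object@whitening), c(n, n)) ||
      !identical(dim(object@unwhitening), c(n, n)) ||
      !identical(dim(object@covariance), c(n, n)))
    return("matrix dimensions must match the mean vector length")
  if (object@rank < 1L || object@rank > n)
    return("retained rank must be in [1, 3N]")
  if (max(abs(object@whitening - t(object@whitening))) > 1e-8)
    return("whitening matrix must be symmetric")
  TRUE
})

#' RegionSplit: partition of atoms into the two encoder inputs
#'
#' Encoder A receives the atoms whose reference position lies within `cutoff`
#' of any atom of the target residue (the region of interest, e.g. around a
#' point mutation); encoder B receives the rest. The two sets always
#' partition the atom indices.
#'
#' @slot encoderA integer atom indices for the supervised encoder.
#' @slot encoderB integer atom indices for the unsupervised encoder.
#' @slot targetResidue integer residue id defining the region.
#' @slot cutoff numeric radius in nm.
#'
#' @exportClass RegionSplit
setClass("RegionSplit",
  representation(
    encoderA = "integer",
    encoderB = "integer",
    targetResidue = "integer",
    cutoff = "numeric"
  )
)

setValidity("RegionSplit", function(object) {
  if (length(object@encoderA) == 0L)
    return("encoder A atom set must be non-empty")
  if (length(intersect(object@encoderA, object@encoderB)) > 0L)
    return("encoder atom sets must be disjoint")
  if (any(duplicated(object@encoderA)) || any(duplicated(object@encoderB)))
    return("atom indices must be unique")
  TRUE
})

#' ArchitectureSpec: layer widths and latent allocation of a DiffNet
#'
#' The network depth is fixed (input -> reduction -> latent -> expansion ->
#' output); this object records the per-encoder widths. The reduction layer
#' always performs a four-fold reduction (`ceiling(input/4)`) and the total
#' latent dimension is divided between encoders proportionally to their atom
#' counts (largest-remainder rounding, minimum 1 each).
#'
#' @slot split logical, TRUE for the two-encoder architecture.
#' @slot inputDims integer per-encoder input widths (3 x atoms in region).
#' @slot reductionDims integer per-encoder reduction widths.
#' @slot latentDims integer per-encoder latent widths.
#' @slot classificationSource `"A"` (split: encoder A's sub-latent feeds the
#'   classifier) or `"full"` (unsplit).
#' @slot activation hidden nonlinearity name (`"sigmoid"`).
#' @slot seed integer seed for weight initialization.
#'
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
  representation(
    split = "logical",
    inputDims = "integer",
    reductionDims = "integer",
    latentDims = "integer",
    classificationSource = "character",
    activation = "character",
    seed = "integer"
  )
)

setValidity("ArchitectureSpec", function(object) {
  ne <- length(object@inputDims)
  if (object@split && ne != 2L) return("split architecture needs two encoders")
  if (!object@split && ne != 1L) return("unsplit architecture needs one encoder")
  if (length(object@reductionDims) != ne || length(object@latentDims) != ne)
    return("per-encoder dimension vectors must have equal length")
  if (any(object@inputDims < 1L) || any(object@latentDims < 1L))
    return("all dimensions must be >= 1")
  if (!all(object@reductionDims == pmax(1L, as.integer(ceiling(object@inputDims / 4)))))
    return("reduction dims must be ceiling(input/4) per encoder")
  if (!object@classificationSource %in% c("A", "full"))
    return("classificationSource must be 'A' or 'full'")
  if (!object@split && object@classificationSource != "full")
    return("unsplit architecture classifies from the full latent")
  if (object@activation != "sigmoid")
    return("only the logistic ('sigmoid') hidden activation is supported")
  TRUE
})

setClassUnion("RegionSplitOrNULL", c("RegionSplit", "NULL"))

#' DiffNet: a (split) supervised autoencoder with frozen whitening layers
#'
#' Bundles the architecture, the optional region split, per-encoder frozen
#' whitening transforms, and the trainable affine weights of the encoders,
#' decoder and classification head.
#'
#' @slot spec [ArchitectureSpec-class].
#' @slot split [RegionSplit-class] or NULL for the single-encoder variant.
#' @slot whitening list of per-encoder [WhiteningTransform-class] objects.
#' @slot weights named list of weight matrices/vectors (see `buildModel`).
#' @slot featureOrder integer permutation mapping internal (encoder-block)
#'   coordinate order to the dataset's coordinate order.
#'
#' @exportClass DiffNet
setClass("DiffNet",
  representation(
    spec = "ArchitectureSpec",
    split = "RegionSplitOrNULL",
    whitening = "list",
    weights = "list",
    featureOrder = "integer"
  )
)

setValidity("DiffNet", function(object) {
  if (length(object@whitening) != length(object@spec@inputDims))
    return("one whitening transform per encoder is required")
  for (i in seq_along(object@whitening)) {
    if (!is(object@whitening[[i]], "WhiteningTransform"))
      return("whitening entries must be WhiteningTransform objects")
    if (length(object@whitening[[i]]@mean) != object@spec@inputDims[i])
      return("whitening dimension must equal the encoder input dimension")
  }
  if (length(object@featureOrder) != sum(object@spec@inputDims))
    return("featureOrder must cover all input coordinates")
  TRUE
})

#' EMBounds: per-class bounds on the fraction of positive frames per batch
#'
#' The expectation step conditions the Poisson-binomial count of "positive"
#' frames in a batch to lie between these fractions. Bounds are given per
#' class: frames from negative-class variants use `negative`, frames from
#' positive-class variants use `positive`.
#'
#' @slot negative numeric length 2, (lower, upper) fraction for class 0.
#' @slot positive numeric length 2, (lower, upper) fraction for class 1.
#'
#' @exportClass EMBounds
setClass("EMBounds",
  representation(negative = "numeric", positive = "numeric")
)

setValidity("EMBounds", function(object) {
  for (b in list(object@negative, object@positive)) {
    if (length(b) != 2L) return("bounds must be (lower, upper) pairs")
    if (!(b[1] >= 0 && b[1] < b[2] && b[2] <= 1))
      return("bounds must satisfy 0 <= lower < upper <= 1")
  }
  if (any(object@positive < object@negative))
    return("positive-class bounds must be >= negative-class bounds elementwise")
  TRUE
})

#' LabelState: per-frame training labels refined by expectation maximization
#'
#' @slot labels numeric vector in `[0, 1]`, one per training frame.
#' @slot variant factor, the variant of each frame.
#' @slot iteration integer, number of E-steps applied so far.
#'
#' @exportClass LabelState
setClass("LabelState",
  representation(labels = "numeric", variant = "factor", iteration = "integer")
)

setValidity("LabelState", function(object) {
  if (length(object@labels) != length(object@variant))
    return("labels and variant map must have equal length")
  if (any(object@labels < 0 | object@labels > 1))
    return("labels must lie in [0, 1]")
  TRUE
})

#' TrainingConfig: optimizer and schedule settings
#'
#' Defaults follow the published training protocol: Adam with learning rate
#' 1e-4, batch size 32, 20 epochs per stage, a 10% validation split, and EM
#' bounds of 0-30% (negative class) and 60-90% (positive class).
#'
#' @slot learningRate numeric Adam step size.
#' @slot batchSize integer minibatch size.
#' @slot epochsPerStage integer epochs for each of the three stages.
#' @slot validationFraction numeric fraction of frames held out per variant.
#' @slot emEnabled logical, run the E-step after stage-2/3 epochs.
#' @slot emBounds [EMBounds-class].
#' @slot emBatchSize integer batch size for the E-step grouping.
#' @slot lossWeights numeric length 3: reconstruction, classification,
#'   latent-covariance weights (all 1 by default; classification 0 gives the
#'   unsupervised-autoencoder baseline).
#' @slot seedInit,seedShuffle,seedEm integer seeds for weight initialization,
#'   batch shuffling / validation split, and EM batching.
#'
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    learningRate = "numeric",
    batchSize = "integer",
    epochsPerStage = "integer",
    validationFraction = "numeric",
    emEnabled = "logical",
    emBounds = "EMBounds",
    emBatchSize = "integer",
    lossWeights = "numeric",
    seedInit = "integer",
    seedShuffle = "integer",
    seedEm = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  if (object@learningRate <= 0) return("learning rate must be positive")
  if (object@batchSize < 2L) return("batch size must be >= 2")
  if (object@epochsPerStage < 0L) return("epochs per stage must be >= 0")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    return("validation fraction must be in (0, 1)")
  if (length(object@lossWeights) != 3L || any(object@lossWeights < 0))
    return("loss weights must be three nonnegative numbers")
  TRUE
})

#' DistanceCorrelationReport: ranked distance-label correlations
#'
#' @slot pairs data.frame with one row per retained atom pair, sorted by
#'   decreasing `|r|`: atom indices, residue ids, atom names, Pearson `r`,
#'   and `direction` ("contracting" when the distance shrinks as the label
#'   rises, "expanding" otherwise).
#' @slot selection list describing the selection rule applied (`type` is
#'   `"top_percent"` or `"top_n"`, plus `value`).
#' @slot nEnumerated integer, pairs enumerated.
#' @slot nSkipped integer, zero-variance pairs skipped.
#'
#' @exportClass DistanceCorrelationReport
setClass("DistanceCorrelationReport",
  representation(
    pairs = "data.frame",
    selection = "list",
    nEnumerated = "integer",
    nSkipped = "integer"
  )
)

setValidity("DistanceCorrelationReport", function(object) {
  if (nrow(object@pairs) > 0) {
    if (any(abs(object@pairs$r) > 1 + 1e-12)) return("|r| must be <= 1")
    if (is.unsorted(rev(abs(object@pairs$r)))) return("pairs must be sorted by |r| descending")
  }
  TRUE
})
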