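#' ToyEnsembleSpec: parameters of the synthetic two-class ensemble generator
#'
#' The generator emulates the setting where two classes of variant ensembles
#' overlap structurally and differ only in the probability of a geometrically
#' subtle feature: a sub-Angstrom change in one pairwise distance (a compact
#' vs a slightly extended state), superimposed on a much larger collective
#' nuisance motion of a "loop" and isotropic thermal jitter. See
#' [toyEnsembleSpec()] for defaults.
#'
#' @slot nAtoms integer, total atoms (a multiple of 4: each pseudo-residue
#'   carries N, CA, CB, C).
#' @slot nVariantsPerClass integer.
#' @slot nFramesPerVariant integer.
#' @slot featureAtomPair integer length 2, the planted feature's atom pair.
#' @slot compactDistance,extendedDistance numeric, target feature-pair
#'   distances (nm) in the two states.
#' @slot pCompactPositive,pCompactNegative numeric, probability that a frame
#'   of a positive / negative class variant is in the compact state.
#' @slot nuisanceAtomSet integer atom indices displaced by the collective
#'   nuisance mode.
#' @slot nuisanceAmplitude numeric, RMS displacement of the mode (nm).
#' @slot thermalSigma numeric, isotropic per-coordinate noise sd (nm).
#' @slot seed integer.
#'
#' @exportClass ToyEnsembleSpec
setClass("ToyEnsembleSpec",
  representation(
    nAtoms = "integer",
    nVariantsPerClass = "integer",
    nFramesPerVariant = "integer",
    featureAtomPair = "integer",
    compactDistance = "numeric",
    extendedDistance = "numeric",
    pCompactPositive = "numeric",
    pCompactNegative = "numeric",
    nuisanceAtomSet = "integer",
    nuisanceAmplitude = "numeric",
    thermalSigma = "numeric",
    seed = "integer"
  )
)

setValidity("ToyEnsembleSpec", function(object) {
  if (object@nAtoms < 4L || object@nAtoms %% 4L != 0L)
    return("nAtoms must be a positive multiple of 4 (N, CA, CB, C per residue)")
  if (object@nVariantsPerClass < 1L) return("nVariantsPerClass must be positive")
  if (object@nFramesPerVariant < 1L) return("nFramesPerVariant must be positive")
  if (length(object@featureAtomPair) != 2L ||
      object@featureAtomPair[1] == object@featureAtomPair[2])
    return("featureAtomPair must be two distinct atom indices")
  if (any(object@featureAtomPair < 1L) || any(object@featureAtomPair > object@nAtoms))
    return("featureAtomPair indices out of range")
  if (object@compactDistance <= 0 || object@extendedDistance <= 0)
    return("feature distances must be positive")
  if (!(object@pCompactNegative >= 0 && object@pCompactNegative < object@pCompactPositive &&
        object@pCompactPositive <= 1))
    return("probabilities must satisfy 0 <= pCompactNegative < pCompactPositive <= 1")
  if (abs(object@extendedDistance - object@compactDistance) >= object@nuisanceAmplitude)
    return("|extendedDistance - compactDistance| must be < nuisanceAmplitude (the feature must be subtle relative to nuisance motion)")
  if (any(object@nuisanceAtomSet < 1L) || any(object@nuisanceAtomSet > object@nAtoms))
    return("nuisanceAtomSet indices out of range")
  if (any(object@featureAtomPair %in% object@nuisanceAtomSet))
    return("feature atoms must not belong to the nuisance atom set")
  if (object@nuisanceAmplitude < 0 || object@thermalSigma < 0)
    return("amplitudes must be nonnegative")
  TRUE
})

#' Construct a synthetic-ensemble specification
#'
#' Defaults are sized for desk-scale end-to-end runs: a 30-residue
#' pseudo-backbone (120 atoms), 2 variants per class with 4000 frames each, a
#' planted feature pair (CA of residues 14 and 16) whose distance is 0.50 nm
#' in the compact state and 0.58 nm in the extended state (a 0.8 Angstrom
#' difference), a rigid collective nuisance mode of 0.5 nm RMS amplitude on
#' the 5-residue "loop" 23-27, and 0.02 nm isotropic thermal jitter. Positive
#' class variants are compact with probability 0.75, negative ones 0.25, so
#' both states occur in both classes and the ensembles overlap.
#'
#' @param nAtoms,nVariantsPerClass,nFramesPerVariant counts.
#' @param featureAtomPair two atom indices; NULL (default) places the pair
#'   on the CA atoms of residues `round(0.45 * nResidues)` and that residue
#'   plus two — residues 14 and 16 for the default 30-residue template.
#' @param compactDistance,extendedDistance target distances in nm.
#' @param pCompactPositive,pCompactNegative per-class compact probabilities.
#' @param nuisanceAtomSet atom indices of the nuisance loop; NULL (default)
#'   uses up to five residues near the chain end, clear of the feature
#'   region — residues 23-27 for the default template.
#' @param nuisanceAmplitude RMS displacement in nm.
#' @param thermalSigma per-coordinate noise sd in nm.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a validated [ToyEnsembleSpec-class]
#' @export
toyEnsembleSpec <- function(nAtoms = 120L,
                            nVariantsPerClass = 2L,
                            nFramesPerVariant = 4000L,
                            featureAtomPair = NULL,
                            compactDistance = 0.50,
                            extendedDistance = 0.58,
                            pCompactPositive = 0.75,
                            pCompactNegative = 0.25,
                            nuisanceAtomSet = NULL,
                            nuisanceAmplitude = 0.5,
                            thermalSigma = 0.02,
                            seed = 1L) {
  nAtoms <- as.integer(nAtoms)
  if (nAtoms < 4L || nAtoms %% 4L != 0L)
    stop("nAtoms must be a positive multiple of 4 (N, CA, CB, C per residue)",
         call. = FALSE)
  nres <- nAtoms %/% 4L
  if (is.null(featureAtomPair)) {
    fr <- max(2L, min(nres - 2L, as.integer(round(0.45 * nres))))
    featureAtomPair <- c(caAtomIndex(fr), caAtomIndex(fr + 2L))
  }
  if (is.null(nuisanceAtomSet)) {
    fr2 <- (featureAtomPair[2] + 3L) %/% 4L + 1L  # residue after the feature
    start <- max(fr2 + 2L, nres - 7L)
    end <- min(start + 4L, nres - 1L)
    if (start > end)
      stop("template too small to place a nuisance loop; pass nuisanceAtomSet",
           call. = FALSE)
    nuisanceAtomSet <- residueAtomIndices(start:end)
  }
  new("ToyEnsembleSpec",
    nAtoms = as.integer(nAtoms),
    nVariantsPerClass = as.integer(nVariantsPerClass),
    nFramesPerVariant = as.integer(nFramesPerVariant),
    featureAtomPair = as.integer(featureAtomPair),
    compactDistance = compactDistance,
    extendedDistance = extendedDistance,
    pCompactPositive = pCompactPositive,
    pCompactNegative = pCompactNegative,
    nuisanceAtomSet = as.integer(nuisanceAtomSet),
    nuisanceAmplitude = nuisanceAmplitude,
    thermalSigma = thermalSigma,
    seed = as.integer(seed)
  )
}

#' Atom index of a residue's CA in the template
#' @param resid residue number(s)
#' @return integer atom index/indices
#' @export
caAtomIndex <- function(resid) 4L * (as.integer(resid) - 1L) + 2L

#' All four atom indices of the given template residues
#' @param resid residue numbers
#' @return integer atom indices
#' @export
residueAtomIndices <- function(resid) {
  as.vector(vapply(as.integer(resid), function(r) 4L * (r - 1L) + 1:4, integer(4)))
}

# Regular zig-zag pseudo-backbone: each residue carries N, CA, CB, C with
# ~0.38 nm CA-CA spacing, so the backbone atom-name filters of the
# featurization module apply unchanged.
toyTemplate <- function(nAtoms) {
  nres <- nAtoms %/% 4L
  xyz <- matrix(0, nAtoms, 3)
  atoms <- data.frame(
    resid = rep(seq_len(nres), each = 4L),
    resname = "ALA",
    name = rep(c("N", "CA", "CB", "C"), nres),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nres)) {
    s <- if (i %% 2L == 0L) 1 else -1
    ca <- c(0.362 * (i - 1), 0.07 * s, 0)
    base <- 4L * (i - 1L)
    xyz[base + 1L, ] <- ca + c(-0.125, 0.045 * s, 0.02)   # N
    xyz[base + 2L, ] <- ca                                 # CA
    xyz[base + 3L, ] <- ca + c(0.02, 0.11 * s, 0.14)       # CB
    xyz[base + 4L, ] <- ca + c(0.125, -0.045 * s, -0.02)   # C
  }
  list(xyz = xyz, atoms = atoms)
}

#' Generate toy two-class conformational ensembles with a planted feature
#'
#' Each frame starts from the fixed template, independently draws its
#' compact/extended state with the class probability, places the second
#' feature atom at exactly the state's target distance from the first
#' (displaced transverse to the template pair axis, so the planted pair is
#' the uniquely most sensitive distance reporter of the state), displaces
#' the nuisance atoms rigidly along a fixed random mode direction by a
#' per-frame Gaussian coefficient, and finally adds isotropic thermal noise
#' to every coordinate. Frames are i.i.d. (no temporal
#' autocorrelation is emulated) and generation is bit-reproducible given the
#' spec's seed.
#'
#' @param spec a [ToyEnsembleSpec-class]
#' @return list with `dataset` (an [EnsembleDataset-class], reference = the
#'   noise-free template) and `truth` (data.frame: frame, variant, class,
#'   compact flag)
#' @export
generateToyEnsembles <- function(spec) {
  validObject(spec)
  tpl <- toyTemplate(spec@nAtoms)
  i1 <- spec@featureAtomPair[1]
  i2 <- spec@featureAtomPair[2]
  # The displaced feature atom moves transverse to the template pair axis.
  # The chain runs along the pair axis, so a displacement along it would
  # make every pair (i2, chain neighbor) exactly as sensitive to the
  # compact/extended state as the feature pair itself (a degenerate,
  # non-identifiable planting); the transverse direction makes the planted
  # pair the uniquely most sensitive reporter of the state.
  u <- tpl$xyz[i2, ] - tpl$xyz[i1, ]
  u <- u / sqrt(sum(u^2))
  axis <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
  if (sum(axis^2) < 1e-6) axis <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  axis <- axis / sqrt(sum(axis^2))

  nv <- spec@nVariantsPerClass
  nf <- spec@nFramesPerVariant
  variants <- c(paste0("pos", seq_len(nv)), paste0("neg", seq_len(nv)))
  classes <- setNames(rep(c(1L, 0L), each = nv), variants)

  coordsList <- vector("list", length(variants))
  flagList <- vector("list", length(variants))
  localSeed(spec@seed, {
    modeDir <- rnorm(3)
    modeDir <- modeDir / sqrt(sum(modeDir^2))
    for (v in seq_along(variants)) {
      p <- if (classes[v] == 1L) spec@pCompactPositive else spec@pCompactNegative
      compact <- runif(nf) < p
      d <- ifelse(compact, spec@compactDistance, spec@extendedDistance)
      arr <- array(rep(tpl$xyz, each = nf), dim = c(nf, spec@nAtoms, 3))
      # plant the feature: atom i2 sits on the pair axis at the state distance
      for (k in 1:3) arr[, i2, k] <- tpl$xyz[i1, k] + d * axis[k]
      # shared rigid nuisance mode, per-frame coefficient
      coef <- rnorm(nf, 0, spec@nuisanceAmplitude)
      for (a in spec@nuisanceAtomSet) {
        for (k in 1:3) arr[, a, k] <- arr[, a, k] + coef * modeDir[k]
      }
      if (spec@thermalSigma > 0) {
        arr <- arr + array(rnorm(length(arr), 0, spec@thermalSigma), dim = dim(arr))
      }
      coordsList[[v]] <- arr
      flagList[[v]] <- compact
    }
  })

  coords <- array(0, dim = c(length(variants) * nf, spec@nAtoms, 3))
  for (v in seq_along(variants)) {
    coords[((v - 1) * nf + 1):(v * nf), , ] <- coordsList[[v]]
  }
  variant <- factor(rep(variants, each = nf), levels = variants)
  dataset <- new("EnsembleDataset",
    coords = coords,
    atoms = tpl$atoms,
    variant = variant,
    classLabels = classes,
    reference = tpl$xyz
  )
  truth <- data.frame(
    frame = seq_len(dim(coords)[1]),
    variant = as.character(variant),
    class = classes[as.character(variant)],
    compact = unlist(flagList),
    row.names = NULL
  )
  list(dataset = dataset, truth = truth)
}

#' Write a generated ensemble to disk in standard trajectory formats
#'
#' Writes one reference PDB (the template, in Angstroms per PDB convention),
#' one DCD trajectory per variant, a ground-truth table and the
#' variant-to-class table, so the featurization module can round-trip the
#' synthetic data exactly like real MD input.
#'
#' @param ensembles output of [generateToyEnsembles()]
#' @param dir output directory (created if needed)
#' @return invisibly, a named list of written file paths
#' @export
writeEnsembleFiles <- function(ensembles, dir) {
  dataset <- ensembles$dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "reference.pdb")
  writeReferencePdb(dataset, pdb)
  trajFiles <- character(0)
  for (v in levels(variantOf(dataset))) {
    sel <- variantOf(dataset) == v
    path <- file.path(dir, paste0(v, ".dcd"))
    writeDcd(coords(dataset)[sel, , , drop = FALSE] * 10, path)  # nm -> Angstrom
    trajFiles[v] <- path
  }
  truthPath <- file.path(dir, "ground_truth.tsv")
  write.table(ensembles$truth, truthPath, sep = "\t", row.names = FALSE, quote = FALSE)
  classPath <- file.path(dir, "classes.tsv")
  write.table(
    data.frame(variant = names(classLabels(dataset)), class = unname(classLabels(dataset))),
    classPath, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(list(topology = pdb, trajectories = trajFiles,
                 truth = truthPath, classes = classPath))
}
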