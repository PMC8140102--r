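# Shared fixtures and independent oracles.

# Small, fast toy spec: 12-residue chain, planted pair on residues 3/5,
# nuisance loop on residues 9-11.
smallToySpec <- function(nFramesPerVariant = 100L, seed = 7L, ...) {
  args <- list(
    nAtoms = 48L,
    nVariantsPerClass = 1L,
    nFramesPerVariant = nFramesPerVariant,
    featureAtomPair = c(caAtomIndex(3L), caAtomIndex(5L)),
    nuisanceAtomSet = residueAtomIndices(9:11),
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(toyEnsembleSpec, args)
}

smallDataset <- function(...) generateToyEnsembles(smallToySpec(...))

# Brute-force enumeration oracle for the Poisson-binomial count law:
# sums P(binary vector) over all 2^n outcomes.
pbOracle <- function(p) {
  n <- length(p)
  B <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(B, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  counts <- rowSums(B)
  vapply(0:n, function(k) sum(probs[counts == k]), numeric(1))
}

# Brute-force enumeration oracle for the conditional-expectation update:
# E[b_i | SL <= sum(b) <= SU] over all 2^n binary realizations.
emOracle <- function(p, SL, SU) {
  n <- length(p)
  B <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(B, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  counts <- rowSums(B)
  keep <- counts >= SL & counts <= SU
  denom <- sum(probs[keep])
  vapply(seq_len(n), function(i) sum(probs[keep & B[, i] == 1]) / denom,
         numeric(1))
}

# Brute-force rotation-grid oracle for superposition optimality: RMSD of the
# best rotation over a coarse grid of Euler angles.
gridBestRmsd <- function(P, Q, step = pi / 18) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  angles <- seq(0, 2 * pi - step, by = step)
  best <- Inf
  rot <- function(a, b, g) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  for (a in angles) for (b in angles) for (g in angles) {
    R <- rot(a, b, g)
    r <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
    if (r < best) best <- r
  }
  best
}

# Subset an EnsembleDataset to one variant (used for held-out prediction).
datasetForVariant <- function(dataset, v) {
  sel <- variantOf(dataset) == v
  new("EnsembleDataset",
      coords = coords(dataset)[sel, , , drop = FALSE],
      atoms = atomInfo(dataset),
      variant = droplevels(variantOf(dataset)[sel]),
      classLabels = classLabels(dataset)[v],
      reference = referenceCoords(dataset))
}
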