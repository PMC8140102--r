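#' @describeIn EnsembleDataset number of frames
#' @param x,object an `EnsembleDataset`
#' @export
setMethod("nFrames", "EnsembleDataset", function(x) dim(x@coords)[1])

#' @describeIn EnsembleDataset number of atoms
#' @export
setMethod("nAtoms", "EnsembleDataset", function(x) dim(x@coords)[2])

#' @describeIn EnsembleDataset coordinate array (frames x atoms x 3, nm)
#' @export
setMethod("coords", "EnsembleDataset", function(x) x@coords)

#' @describeIn EnsembleDataset atom metadata table
#' @export
setMethod("atomInfo", "EnsembleDataset", function(x) x@atoms)

#' @describeIn EnsembleDataset per-frame variant factor
#' @export
setMethod("variantOf", "EnsembleDataset", function(x) x@variant)

#' @describeIn EnsembleDataset named per-variant class labels
#' @export
setMethod("classLabels", "EnsembleDataset", function(x) x@classLabels)

#' @describeIn EnsembleDataset reference coordinates (atoms x 3, nm)
#' @export
setMethod("referenceCoords", "EnsembleDataset", function(x) x@reference)

setMethod("show", "EnsembleDataset", function(object) {
  cat("EnsembleDataset:", nFrames(object), "frames,", nAtoms(object), "atoms\n")
  tab <- table(object@variant)
  for (v in names(tab)) {
    cat(sprintf("  %s (class %d): %d frames\n", v, object@classLabels[[v]], tab[[v]]))
  }
})

# Optimal least-squares rotation (Kabsch, via SVD with determinant
# correction) aligning centered frame P onto centered reference Q.
kabschRotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  if (!is.finite(d) || d == 0)
    stop("degenerate coordinates: optimal rotation is ill-defined", call. = FALSE)
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition of every frame onto the reference
#'
#' Centers the reference at the origin and superposes each frame with the
#' optimal least-squares rotation and translation over all (backbone)
#' atoms, uniform weights. Idempotent: aligning an aligned dataset changes
#' nothing beyond ~1e-12 nm.
#'
#' @param dataset an [EnsembleDataset-class]
#' @return the dataset with aligned coordinates and origin-centered reference
#' @export
alignToReference <- function(dataset) {
  ref <- referenceCoords(dataset)
  refc <- sweep(ref, 2, colMeans(ref))
  if (max(svd(refc, nu = 0, nv = 0)$d) < 1e-12 ||
      sum(svd(refc, nu = 0, nv = 0)$d > 1e-12) < 2)
    stop("degenerate reference (collinear or coincident atoms)", call. = FALSE)
  arr <- coords(dataset)
  out <- arr
  for (f in seq_len(dim(arr)[1])) {
    P <- arr[f, , ]
    Pc <- sweep(P, 2, colMeans(P))
    R <- kabschRotation(Pc, refc)
    out[f, , ] <- Pc %*% R
  }
  initialize(dataset, coords = out, reference = refc)
}

#' Fit the mean-shift and whitening transform on pooled frames
#'
#' Computes the pooled mean and covariance of the flattened coordinates over
#' all frames of all variants (the transform is always shared across
#' variants so they live in one coordinate embedding), then the inverse
#' square root of the covariance by symmetric eigendecomposition.
#' Eigenvalues at or below `eigenvalueFloor` are excluded (pseudo-inverse),
#' so with fewer frames than 3N the retained rank is at most frames - 1.
#'
#' @param dataset an [EnsembleDataset-class] with aligned frames, or a
#'   frames x 3N numeric matrix.
#' @param eigenvalueFloor variance floor in nm^2 (default 1e-8).
#' @return a [WhiteningTransform-class]
#' @export
fitWhitening <- function(dataset, eigenvalueFloor = 1e-8) {
  X <- if (is(dataset, "EnsembleDataset")) flattenCoords(coords(dataset)) else dataset
  stopUnless(is.matrix(X), "input must be a dataset or a frames x 3N matrix")
  if (nrow(X) < 2L)
    stop("whitening requires at least 2 frames", call. = FALSE)
  mu <- colMeans(X)
  C <- cov(X)
  whiteningFromCovariance(mu, C, eigenvalueFloor)
}

whiteningFromCovariance <- function(mu, C, eigenvalueFloor) {
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > eigenvalueFloor
  stopUnless(any(keep), "covariance has no eigenvalue above the floor")
  V <- eig$vectors[, keep, drop = FALSE]
  lam <- eig$values[keep]
  W <- V %*% (t(V) / sqrt(lam))
  Winv <- V %*% (t(V) * sqrt(lam))
  W <- (W + t(W)) / 2
  Winv <- (Winv + t(Winv)) / 2
  new("WhiteningTransform",
    mean = mu, covariance = C, whitening = W, unwhitening = Winv,
    rank = sum(keep), floor = eigenvalueFloor)
}

#' Apply the whitening transform to coordinates
#' @param transform a [WhiteningTransform-class]
#' @param x frames x 3N matrix or length-3N vector (nm)
#' @return whitened feature matrix of the same shape
#' @export
applyWhitening <- function(transform, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopUnless(ncol(x) == length(transform@mean),
             "dimension mismatch between coordinates and transform")
  sweep(x, 2, transform@mean) %*% transform@whitening
}

#' Map whitened features back to coordinates
#'
#' Inverse of [applyWhitening()] on the retained subspace:
#' `unwhiten(applyWhitening(x))` reproduces the projection of `x` onto the
#' retained eigen-subspace (plus the mean).
#'
#' @param transform a [WhiteningTransform-class]
#' @param xw whitened frames x 3N matrix or length-3N vector
#' @return coordinate matrix (nm)
#' @export
unwhiten <- function(transform, xw) {
  if (is.null(dim(xw))) xw <- matrix(xw, nrow = 1)
  stopUnless(ncol(xw) == length(transform@mean),
             "dimension mismatch between features and transform")
  sweep(xw %*% transform@unwhitening, 2, transform@mean, FUN = "+")
}

#' Exact whitening transform for a coordinate sub-block
#'
#' For split architectures each encoder whitens only its own atoms'
#' coordinates. The sub-block transform is refit from the stored pooled
#' covariance's submatrix (the submatrix of a covariance is exactly the
#' covariance of the sub-coordinates), with the same eigenvalue floor.
#'
#' @param transform a full [WhiteningTransform-class]
#' @param coordIdx integer coordinate (column) indices of the block
#' @return a [WhiteningTransform-class] for the block
#' @export
subsetWhitening <- function(transform, coordIdx) {
  stopUnless(all(coordIdx >= 1 & coordIdx <= length(transform@mean)),
             "coordinate indices out of range")
  whiteningFromCovariance(
    transform@mean[coordIdx],
    transform@covariance[coordIdx, coordIdx, drop = FALSE],
    transform@floor
  )
}

setMethod("show", "WhiteningTransform", function(object) {
  cat(sprintf("WhiteningTransform: %d coordinates, retained rank %d (floor %.1e nm^2)\n",
              length(object@mean), object@rank, object@floor))
})

#' Partition atoms into the two encoder regions
#'
#' Encoder A receives every atom whose reference position lies within
#' `cutoff` of any reference atom of the target residue; encoder B receives
#' the remainder. A `cutoff` spanning the whole molecule leaves encoder B
#' empty, which is an error (use the unsplit architecture instead).
#'
#' @param dataset an [EnsembleDataset-class]
#' @param targetResidue residue id of the region of interest (e.g. the
#'   mutation site).
#' @param cutoff radius in nm (default 1.0).
#' @return a [RegionSplit-class]
#' @export
splitRegion <- function(dataset, targetResidue, cutoff = 1.0) {
  at <- atomInfo(dataset)
  tIdx <- which(at$resid == targetResidue)
  if (length(tIdx) == 0)
    stop("target residue ", targetResidue, " not present in the dataset",
         call. = FALSE)
  ref <- referenceCoords(dataset)
  target <- ref[tIdx, , drop = FALSE]
  # min distance of each atom to any target-residue atom
  d2 <- vapply(seq_len(nrow(ref)), function(a) {
    min(colSums((t(target) - ref[a, ])^2))
  }, numeric(1))
  A <- which(d2 <= cutoff^2)
  B <- setdiff(seq_len(nrow(ref)), A)
  if (length(B) == 0)
    stop("cutoff ", cutoff, " nm covers the whole molecule; encoder B would ",
         "be empty - use the unsplit (single-encoder) architecture instead",
         call. = FALSE)
  new("RegionSplit",
    encoderA = as.integer(A), encoderB = as.integer(B),
    targetResidue = as.integer(targetResidue), cutoff = cutoff)
}

setMethod("show", "RegionSplit", function(object) {
  cat(sprintf("RegionSplit: %d atoms within %.2f nm of residue %d (encoder A), %d atoms in encoder B\n",
              length(object@encoderA), object@cutoff, object@targetResidue,
              length(object@encoderB)))
})

#' Export whitened features and transform components to disk
#'
#' Writes the whitened feature matrix and the transform's mean, whitening
#' and unwhitening matrices as NPY arrays, plus a JSON sidecar recording the
#' atom metadata, units and retained rank.
#'
#' @param dataset an aligned [EnsembleDataset-class]
#' @param transform the fitted [WhiteningTransform-class]
#' @param dir output directory
#' @return invisibly, a named list of written paths
#' @export
exportFeaturization <- function(dataset, transform, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Xw <- applyWhitening(transform, flattenCoords(coords(dataset)))
  paths <- list(
    features = file.path(dir, "whitened_features.npy"),
    mean = file.path(dir, "mean.npy"),
    whitening = file.path(dir, "whitening.npy"),
    unwhitening = file.path(dir, "unwhitening.npy"),
    sidecar = file.path(dir, "featurization.json")
  )
  saveNpy(Xw, paths$features)
  saveNpy(transform@mean, paths$mean)
  saveNpy(transform@whitening, paths$whitening)
  saveNpy(transform@unwhitening, paths$unwhitening)
  jsonlite::write_json(
    list(
      units = "nm",
      n_frames = nFrames(dataset),
      n_atoms = nAtoms(dataset),
      retained_rank = transform@rank,
      eigenvalue_floor = transform@floor,
      atoms = atomInfo(dataset),
      variants = as.list(table(variantOf(dataset)))
    ),
    paths$sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
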