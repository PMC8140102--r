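#' Divide a total latent dimension between encoders
#'
#' Proportional to atom counts with largest-remainder rounding and a minimum
#' of 1 per encoder. With 30 total latent variables and encoders holding
#' 2/15 and 13/15 of the atoms this gives the 4 + 26 allocation.
#'
#' @param totalLatent total latent dimension.
#' @param atomCounts integer vector of atoms per encoder.
#' @return integer vector of per-encoder latent dims summing to `totalLatent`
#' @export
allocateLatent <- function(totalLatent, atomCounts) {
  stopUnless(totalLatent >= length(atomCounts),
             "total latent must be at least the number of encoders")
  shares <- totalLatent * atomCounts / sum(atomCounts)
  base <- floor(shares)
  rem <- totalLatent - sum(base)
  if (rem > 0) {
    ord <- order(shares - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  while (any(base < 1)) {
    base[which.max(base)] <- base[which.max(base)] - 1
    base[which.min(base)] <- base[which.min(base)] + 1
  }
  as.integer(base)
}

#' Construct an architecture specification
#'
#' @param inputDims integer per-encoder input widths (3 x atoms per region);
#'   length 2 for the split architecture, length 1 for the single-encoder
#'   variant.
#' @param totalLatent total latent dimension, divided between encoders by
#'   [allocateLatent()].
#' @param seed integer seed for weight initialization.
#' @return an [ArchitectureSpec-class]
#' @export
architectureSpec <- function(inputDims, totalLatent, seed = 1L) {
  inputDims <- as.integer(inputDims)
  split <- length(inputDims) == 2L
  stopUnless(length(inputDims) %in% 1:2, "one or two encoders are supported")
  new("ArchitectureSpec",
    split = split,
    inputDims = inputDims,
    reductionDims = pmax(1L, as.integer(ceiling(inputDims / 4))),
    latentDims = allocateLatent(as.integer(totalLatent), inputDims),
    classificationSource = if (split) "A" else "full",
    activation = "sigmoid",
    seed = as.integer(seed)
  )
}

#' Architecture spec matching a region split
#' @param split a [RegionSplit-class]
#' @param totalLatent total latent dimension
#' @param seed initialization seed
#' @return an [ArchitectureSpec-class]
#' @export
architectureFromSplit <- function(split, totalLatent, seed = 1L) {
  architectureSpec(3L * c(length(split@encoderA), length(split@encoderB)),
                   totalLatent, seed = seed)
}

initAffine <- function(nout, nin) {
  s <- 1 / sqrt(nin)
  list(W = matrix(runif(nout * nin, -s, s), nout, nin), b = rep(0, nout))
}

#' Build a DiffNet with frozen whitening layers
#'
#' Trainable weights are initialized with fan-in-scaled uniform draws,
#' deterministic given the spec's seed. For a split architecture the
#' whitening is routed per region: each encoder gets the exact transform for
#' its own atoms' coordinates (derived from the pooled covariance via
#' [subsetWhitening()]), so the encoder-A sub-latent and the classifier
#' output depend only on encoder-A atoms.
#'
#' @param spec an [ArchitectureSpec-class]
#' @param transform the full-coordinate [WhiteningTransform-class]
#' @param split a [RegionSplit-class] (required when `spec@split` is TRUE)
#' @return a [DiffNet-class] with untrained weights
#' @export
buildModel <- function(spec, transform, split = NULL) {
  validObject(spec)
  D <- length(transform@mean)
  if (spec@split) {
    stopUnless(!is.null(split), "a RegionSplit is required for a split architecture")
    idxA <- coordIdx(split@encoderA)
    idxB <- coordIdx(split@encoderB)
    stopUnless(identical(spec@inputDims, c(length(idxA), length(idxB))),
               "spec input dims do not match the region split")
    stopUnless(length(idxA) + length(idxB) == D,
               "transform dimension must equal the total input dimension")
    whitening <- list(subsetWhitening(transform, idxA),
                      subsetWhitening(transform, idxB))
    featureOrder <- c(idxA, idxB)
  } else {
    stopUnless(spec@inputDims[1] == D,
               "transform dimension must equal the input dimension")
    whitening <- list(transform)
    featureOrder <- seq_len(D)
  }
  ne <- length(spec@inputDims)
  expDim <- sum(spec@reductionDims)
  latTot <- sum(spec@latentDims)
  weights <- localSeed(spec@seed, {
    enc <- lapply(seq_len(ne), function(e) {
      r <- initAffine(spec@reductionDims[e], spec@inputDims[e])
      l <- initAffine(spec@latentDims[e], spec@reductionDims[e])
      list(W1 = r$W, b1 = r$b, W2 = l$W, b2 = l$b)
    })
    d1 <- initAffine(expDim, latTot)
    d2 <- initAffine(D, expDim)
    clsDim <- if (spec@classificationSource == "A") spec@latentDims[1] else latTot
    cw <- initAffine(1L, clsDim)
    list(enc = enc,
         dec = list(W1 = d1$W, b1 = d1$b, W2 = d2$W, b2 = d2$b),
         cls = list(w = as.vector(cw$W), b = 0))
  })
  new("DiffNet", spec = spec, split = split, whitening = whitening,
      weights = weights, featureOrder = as.integer(featureOrder))
}

setMethod("show", "DiffNet", function(object) {
  s <- object@spec
  cat(sprintf("DiffNet (%s): input %s -> reduction %s -> latent %s (classifier on %s)\n",
              if (s@split) "split" else "single encoder",
              paste(s@inputDims, collapse = "+"),
              paste(s@reductionDims, collapse = "+"),
              paste(s@latentDims, collapse = "+"),
              if (s@classificationSource == "A") "latent A" else "full latent"))
})

# --- internal forward helpers (whitened feature space, encoder-block order) -

# whiten raw coordinates (dataset order) into the concatenated block layout
whitenInput <- function(model, X) {
  stopUnless(all(is.finite(X)), "non-finite input coordinates")
  stopUnless(ncol(X) == length(model@featureOrder),
             "coordinate dimension does not match the model")
  dims <- model@spec@inputDims
  offs <- c(0L, cumsum(dims))
  Xo <- X[, model@featureOrder, drop = FALSE]
  blocks <- lapply(seq_along(dims), function(e) {
    applyWhitening(model@whitening[[e]], Xo[, (offs[e] + 1):offs[e + 1], drop = FALSE])
  })
  do.call(cbind, blocks)
}

# unwhiten a concatenated whitened matrix back to raw dataset coordinate order
unwhitenOutput <- function(model, Xw) {
  dims <- model@spec@inputDims
  offs <- c(0L, cumsum(dims))
  raw <- matrix(0, nrow(Xw), ncol(Xw))
  for (e in seq_along(dims)) {
    raw[, (offs[e] + 1):offs[e + 1]] <-
      unwhiten(model@whitening[[e]], Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE])
  }
  out <- matrix(0, nrow(raw), ncol(raw))
  out[, model@featureOrder] <- raw
  out
}

affine <- function(X, W, b) sweep(X %*% t(W), 2, b, FUN = "+")

# encoder pass on whitened (block-ordered) input; returns intermediates
encodeWhitened <- function(model, Xw) {
  dims <- model@spec@inputDims
  offs <- c(0L, cumsum(dims))
  R <- vector("list", length(dims))
  Z <- vector("list", length(dims))
  for (e in seq_along(dims)) {
    w <- model@weights$enc[[e]]
    R[[e]] <- sigmoid(affine(Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE], w$W1, w$b1))
    Z[[e]] <- sigmoid(affine(R[[e]], w$W2, w$b2))
  }
  list(R = R, Z = Z, latent = do.call(cbind, Z))
}

decodeToWhitened <- function(model, Z) {
  d <- model@weights$dec
  H <- sigmoid(affine(Z, d$W1, d$b1))
  list(H = H, Xhat = affine(H, d$W2, d$b2))
}

classifierLogit <- function(model, Z) {
  cls <- model@weights$cls
  src <- classifierColumns(model@spec)
  as.vector(Z[, src, drop = FALSE] %*% cls$w) + cls$b
}

classifierColumns <- function(spec) {
  if (spec@classificationSource == "A") seq_len(spec@latentDims[1])
  else seq_len(sum(spec@latentDims))
}

asCoordMatrix <- function(x) {
  if (is(x, "EnsembleDataset")) flattenCoords(coords(x))
  else if (is.null(dim(x))) matrix(x, nrow = 1)
  else x
}

#' @describeIn DiffNet encode raw coordinates (nm, dataset atom order) to
#'   the concatenated latent space (encoder A columns first)
#' @param object a `DiffNet`
#' @param x coordinate matrix or `EnsembleDataset`
#' @export
setMethod("encode", "DiffNet", function(object, x) {
  Xw <- whitenInput(object, asCoordMatrix(x))
  encodeWhitened(object, Xw)$latent
})

#' @describeIn DiffNet decode latent vectors to coordinates (nm, dataset
#'   atom order)
#' @param z latent matrix
#' @export
setMethod("decode", "DiffNet", function(object, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopUnless(ncol(z) == sum(object@spec@latentDims),
             "latent length does not match the architecture")
  unwhitenOutput(object, decodeToWhitened(object, z)$Xhat)
})

#' @describeIn DiffNet classification-head output, strictly inside (0, 1)
#' @export
setMethod("classifyLatent", "DiffNet", function(object, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopUnless(ncol(z) >= max(classifierColumns(object@spec)),
             "latent is missing the classification source columns")
  sigmoid(classifierLogit(object, z))
})

#' @describeIn DiffNet single shared forward pass
#' @export
setMethod("forwardPass", "DiffNet", function(object, x) {
  X <- asCoordMatrix(x)
  Xw <- whitenInput(object, X)
  enc <- encodeWhitened(object, Xw)
  dec <- decodeToWhitened(object, enc$latent)
  list(
    reconstruction = unwhitenOutput(object, dec$Xhat),
    latent = enc$latent,
    yhat = sigmoid(classifierLogit(object, enc$latent)),
    whitenedInput = Xw,
    whitenedOutput = dec$Xhat
  )
})

#' Per-atom reconstruction RMSD of a model on a dataset
#'
#' Mean over frames of the root-mean-square deviation per atom between the
#' input structure and its reconstruction, in nm.
#'
#' @param model a [DiffNet-class]
#' @param dataset an aligned [EnsembleDataset-class]
#' @return numeric scalar (nm)
#' @export
reconstructionRmsd <- function(model, dataset) {
  X <- flattenCoords(coords(dataset))
  Xhat <- forwardPass(model, X)$reconstruction
  E2 <- (X - Xhat)^2
  perFrame <- sqrt(rowSums(E2) / nAtoms(dataset))
  mean(perFrame)
}

# --- checkpoints -------------------------------------------------------------

#' Save a self-sufficient model checkpoint
#'
#' The checkpoint bundles the weights, architecture spec, region split and
#' whitening transforms plus a format-version field, so inference on new
#' trajectories needs nothing but the checkpoint.
#'
#' @param model a [DiffNet-class]
#' @param path output file
#' @param extra named list of additional objects to store (e.g. training
#'   feature ranges, final labels)
#' @return invisibly, `path`
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
  saveRDS(list(
    format = "DiffNetR-checkpoint", version = 1L,
    spec = model@spec, split = model@split, whitening = model@whitening,
    weights = model@weights, featureOrder = model@featureOrder,
    extra = extra
  ), path)
  invisible(path)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#' @param path checkpoint file
#' @return list with `model` (a [DiffNet-class]) and `extra`
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "DiffNetR-checkpoint"))
    stop("not a DiffNetR checkpoint: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("incompatible checkpoint version ", obj$version, call. = FALSE)
  model <- new("DiffNet", spec = obj$spec, split = obj$split,
               whitening = obj$whitening, weights = obj$weights,
               featureOrder = obj$featureOrder)
  list(model = model, extra = obj$extra)
}
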