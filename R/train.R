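#' Construct a training configuration
#'
#' Defaults follow the published protocol: Adam, learning rate 1e-4, batch
#' size 32, 20 epochs per stage, 10% validation split.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param epochsPerStage epochs in each of the three stages.
#' @param validationFraction per-variant fraction of frames held out for
#'   model selection (never used for gradient updates or EM).
#' @param emEnabled run the expectation step after each epoch with a
#'   classifier (stages 2 and 3).
#' @param emBounds an [EMBounds-class]; NULL (the default) means the
#'   stability preset, 0-30% negative / 60-90% positive.
#' @param emBatchSize E-step batch size (defaults to `batchSize`).
#' @param lossWeights numeric length 3 (recon, class, corr); class weight 0
#'   gives the unsupervised-autoencoder baseline.
#' @param seedInit,seedShuffle,seedEm integer seeds.
#' @return a [TrainingConfig-class]
#' @export
trainingConfig <- function(learningRate = 1e-4,
                           batchSize = 32L,
                           epochsPerStage = 20L,
                           validationFraction = 0.10,
                           emEnabled = FALSE,
                           emBounds = NULL,
                           emBatchSize = batchSize,
                           lossWeights = c(1, 1, 1),
                           seedInit = 1L,
                           seedShuffle = 2L,
                           seedEm = 3L) {
  if (is.null(emBounds))
    emBounds <- new("EMBounds", negative = c(0, 0.30), positive = c(0.60, 0.90))
  new("TrainingConfig",
    learningRate = learningRate,
    batchSize = as.integer(batchSize),
    epochsPerStage = as.integer(epochsPerStage),
    validationFraction = validationFraction,
    emEnabled = emEnabled,
    emBounds = emBounds,
    emBatchSize = as.integer(emBatchSize),
    lossWeights = as.numeric(lossWeights),
    seedInit = as.integer(seedInit),
    seedShuffle = as.integer(seedShuffle),
    seedEm = as.integer(seedEm))
}

# --- flat weight addressing --------------------------------------------------

flattenWeights <- function(weights) {
  out <- list()
  for (e in seq_along(weights$enc)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      out[[paste0("e", e, ".", nm)]] <- weights$enc[[e]][[nm]]
    }
  }
  for (nm in c("W1", "b1", "W2", "b2")) out[[paste0("dec.", nm)]] <- weights$dec[[nm]]
  out[["cls.w"]] <- weights$cls$w
  out[["cls.b"]] <- weights$cls$b
  out
}

unflattenWeights <- function(flat, nEncoders) {
  enc <- lapply(seq_len(nEncoders), function(e) {
    list(W1 = flat[[paste0("e", e, ".W1")]], b1 = flat[[paste0("e", e, ".b1")]],
         W2 = flat[[paste0("e", e, ".W2")]], b2 = flat[[paste0("e", e, ".b2")]])
  })
  list(enc = enc,
       dec = list(W1 = flat[["dec.W1"]], b1 = flat[["dec.b1"]],
                  W2 = flat[["dec.W2"]], b2 = flat[["dec.b2"]]),
       cls = list(w = flat[["cls.w"]], b = flat[["cls.b"]]))
}

# --- Adam --------------------------------------------------------------------

adamInit <- function(names) {
  setNames(lapply(names, function(n) list(m = NULL, v = NULL)), names)
}

adamUpdate <- function(state, params, grads, trainable, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- state[[nm]]
    if (is.null(s$m)) { s$m <- g * 0; s$v <- g * 0 }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- s
  }
  list(state = state, params = params)
}

# --- forward/backward passes on whitened features ---------------------------

encoderBlockOffsets <- function(spec) c(0L, cumsum(spec@inputDims))
latentBlockOffsets <- function(spec) c(0L, cumsum(spec@latentDims))

# Stage-1 shallow autoencoder: input -> reduction -> output (no bottleneck).
shallowGrad <- function(flat, Xw, spec) {
  B <- nrow(Xw); D <- ncol(Xw)
  offs <- encoderBlockOffsets(spec)
  ne <- length(spec@inputDims)
  R <- vector("list", ne)
  for (e in seq_len(ne)) {
    R[[e]] <- sigmoid(affine(Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE],
                             flat[[paste0("e", e, ".W1")]], flat[[paste0("e", e, ".b1")]]))
  }
  Rcat <- do.call(cbind, R)
  Xhat <- affine(Rcat, flat[["s1.W"]], flat[["s1.b"]])
  E <- Xw - Xhat
  loss <- mean(abs(E) + E^2)
  G <- -(sign(E) + 2 * E) / (B * D)
  grads <- list()
  grads[["s1.W"]] <- crossprod(G, Rcat)
  grads[["s1.b"]] <- colSums(G)
  GR <- G %*% flat[["s1.W"]]
  roffs <- c(0L, cumsum(spec@reductionDims))
  for (e in seq_len(ne)) {
    GRe <- GR[, (roffs[e] + 1):roffs[e + 1], drop = FALSE] * R[[e]] * (1 - R[[e]])
    grads[[paste0("e", e, ".W1")]] <-
      crossprod(GRe, Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE])
    grads[[paste0("e", e, ".b1")]] <- colSums(GRe)
  }
  list(loss = c(recon = loss, class = 0, corr = 0), grads = grads)
}

# Full DiffNet: whitened input -> reduction -> latent -> expansion -> output,
# plus the classification head on the configured sub-latent.
fullGrad <- function(flat, Xw, y, spec, lossWeights) {
  B <- nrow(Xw); D <- ncol(Xw)
  wr <- lossWeights[1]; wc <- lossWeights[2]; wz <- lossWeights[3]
  offs <- encoderBlockOffsets(spec)
  loffs <- latentBlockOffsets(spec)
  ne <- length(spec@inputDims)
  R <- vector("list", ne); Z <- vector("list", ne)
  for (e in seq_len(ne)) {
    R[[e]] <- sigmoid(affine(Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE],
                             flat[[paste0("e", e, ".W1")]], flat[[paste0("e", e, ".b1")]]))
    Z[[e]] <- sigmoid(affine(R[[e]], flat[[paste0("e", e, ".W2")]],
                             flat[[paste0("e", e, ".b2")]]))
  }
  Zc <- do.call(cbind, Z)
  H <- sigmoid(affine(Zc, flat[["dec.W1"]], flat[["dec.b1"]]))
  Xhat <- affine(H, flat[["dec.W2"]], flat[["dec.b2"]])

  E <- Xw - Xhat
  lr <- mean(abs(E) + E^2)
  grads <- list()
  G <- -(sign(E) + 2 * E) * (wr / (B * D))
  grads[["dec.W2"]] <- crossprod(G, H)
  grads[["dec.b2"]] <- colSums(G)
  GH <- (G %*% flat[["dec.W2"]]) * H * (1 - H)
  grads[["dec.W1"]] <- crossprod(GH, Zc)
  grads[["dec.b1"]] <- colSums(GH)
  GZ <- GH %*% flat[["dec.W1"]]

  lc <- 0
  srcCols <- if (spec@classificationSource == "A") seq_len(spec@latentDims[1])
             else seq_len(ncol(Zc))
  a <- as.vector(Zc[, srcCols, drop = FALSE] %*% flat[["cls.w"]]) + flat[["cls.b"]]
  yhat <- sigmoid(a)
  if (wc > 0) {
    yh <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
    lc <- -mean(y * log(yh) + (1 - y) * log(1 - yh))
    da <- wc * (yhat - y) / B
    grads[["cls.w"]] <- as.vector(crossprod(Zc[, srcCols, drop = FALSE], da))
    grads[["cls.b"]] <- sum(da)
    GZ[, srcCols] <- GZ[, srcCols, drop = FALSE] + outer(da, flat[["cls.w"]])
  } else {
    grads[["cls.w"]] <- flat[["cls.w"]] * 0
    grads[["cls.b"]] <- 0
  }

  Zm <- sweep(Zc, 2, colMeans(Zc))
  Cov <- crossprod(Zm) / B
  diag(Cov) <- 0
  lz <- sum(Cov^2)
  if (wz > 0) GZ <- GZ + (wz * 4 / B) * (Zm %*% Cov)

  for (e in seq_len(ne)) {
    Ze <- Z[[e]]
    GZe <- GZ[, (loffs[e] + 1):loffs[e + 1], drop = FALSE] * Ze * (1 - Ze)
    grads[[paste0("e", e, ".W2")]] <- crossprod(GZe, R[[e]])
    grads[[paste0("e", e, ".b2")]] <- colSums(GZe)
    GRe <- (GZe %*% flat[[paste0("e", e, ".W2")]]) * R[[e]] * (1 - R[[e]])
    grads[[paste0("e", e, ".W1")]] <-
      crossprod(GRe, Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE])
    grads[[paste0("e", e, ".b1")]] <- colSums(GRe)
  }
  list(loss = c(recon = lr, class = lc, corr = lz), grads = grads,
       yhat = yhat)
}

# Validation reconstruction loss (whitened space) of the full network.
fullValRecon <- function(flat, Xw, spec) {
  offs <- encoderBlockOffsets(spec)
  Z <- lapply(seq_along(spec@inputDims), function(e) {
    Re <- sigmoid(affine(Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE],
                         flat[[paste0("e", e, ".W1")]], flat[[paste0("e", e, ".b1")]]))
    sigmoid(affine(Re, flat[[paste0("e", e, ".W2")]], flat[[paste0("e", e, ".b2")]]))
  })
  Zc <- do.call(cbind, Z)
  H <- sigmoid(affine(Zc, flat[["dec.W1"]], flat[["dec.b1"]]))
  Xhat <- affine(H, flat[["dec.W2"]], flat[["dec.b2"]])
  E <- Xw - Xhat
  mean(abs(E) + E^2)
}

fullClassifierOutputs <- function(flat, Xw, spec) {
  offs <- encoderBlockOffsets(spec)
  Z <- lapply(seq_along(spec@inputDims), function(e) {
    Re <- sigmoid(affine(Xw[, (offs[e] + 1):offs[e + 1], drop = FALSE],
                         flat[[paste0("e", e, ".W1")]], flat[[paste0("e", e, ".b1")]]))
    sigmoid(affine(Re, flat[[paste0("e", e, ".W2")]], flat[[paste0("e", e, ".b2")]]))
  })
  Zc <- do.call(cbind, Z)
  srcCols <- if (spec@classificationSource == "A") seq_len(spec@latentDims[1])
             else seq_len(ncol(Zc))
  sigmoid(as.vector(Zc[, srcCols, drop = FALSE] %*% flat[["cls.w"]]) + flat[["cls.b"]])
}

# Seeded minibatch index list; a trailing batch of size 1 is folded into the
# previous batch (the covariance term needs >= 2 samples).
makeBatches <- function(n, batchSize, seed) {
  perm <- localSeed(seed, sample.int(n))
  starts <- seq(1L, n, by = batchSize)
  batches <- lapply(starts, function(s) perm[s:min(s + batchSize - 1L, n)])
  if (length(batches) > 1 && length(batches[[length(batches)]]) < 2) {
    nb <- length(batches)
    batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

# One training stage. stage 1 trains the shallow net (reduction priors),
# stage 2 trains the full net with reduction weights frozen, stage 3 trains
# all weights. Optimizer state is reset at every stage boundary.
runStage <- function(stage, flat, XwTrain, XwVal, labels, frameClassTrain,
                     spec, config, collectCheckpoints = stage >= 2) {
  epochs <- config@epochsPerStage
  names1 <- unlist(lapply(seq_along(spec@inputDims),
                          function(e) paste0("e", e, c(".W1", ".b1"))))
  trainable <- switch(stage,
    c(names1, "s1.W", "s1.b"),
    setdiff(names(flat), c(names1, "s1.W", "s1.b")),
    setdiff(names(flat), c("s1.W", "s1.b"))
  )
  adam <- adamInit(trainable)
  log <- data.frame()
  checkpoints <- list()
  labelHistory <- list()
  t <- 0L
  nTrain <- nrow(XwTrain)
  if (epochs > 0) for (epoch in seq_len(epochs)) {
    batches <- makeBatches(nTrain, config@batchSize,
                           config@seedShuffle + 1000L * stage + epoch)
    comp <- c(recon = 0, class = 0, corr = 0)
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      res <- if (stage == 1L) {
        shallowGrad(flat, XwTrain[idx, , drop = FALSE], spec)
      } else {
        fullGrad(flat, XwTrain[idx, , drop = FALSE], labels@labels[idx],
                 spec, config@lossWeights)
      }
      if (!all(is.finite(res$loss)))
        stop("non-finite loss in stage ", stage, " epoch ", epoch, " batch ", b,
             call. = FALSE)
      comp <- comp + res$loss
      t <- t + 1L
      upd <- adamUpdate(adam, flat, res$grads, trainable, config@learningRate, t)
      adam <- upd$state
      flat <- upd$params
    }
    comp <- comp / length(batches)
    valRecon <- if (stage == 1L) {
      NA_real_
    } else {
      fullValRecon(flat, XwVal, spec)
    }
    if (stage >= 2 && config@emEnabled) {
      yhatAll <- fullClassifierOutputs(flat, XwTrain, spec)
      labels <- emStep(labels, yhatAll, frameClassTrain, config@emBounds,
                       config@emBatchSize,
                       seed = config@seedEm + 1000L * stage + epoch)
      labelHistory[[length(labelHistory) + 1L]] <- labels@labels
    }
    if (collectCheckpoints) {
      checkpoints[[length(checkpoints) + 1L]] <-
        list(stage = stage, epoch = epoch, flat = flat, valRecon = valRecon)
    }
    log <- rbind(log, data.frame(
      stage = stage, epoch = epoch,
      recon = comp[["recon"]], class = comp[["class"]], corr = comp[["corr"]],
      total = sum(config@lossWeights * comp), valRecon = valRecon))
  }
  list(flat = flat, log = log, labels = labels, checkpoints = checkpoints,
       labelHistory = labelHistory)
}

stageScaffold <- function(model, dataset, config) {
  stopUnless(is(model, "DiffNet"), "model must be a DiffNet")
  X <- flattenCoords(coords(dataset))
  Xw <- whitenInput(model, X)
  flat <- flattenWeights(model@weights)
  spec <- model@spec
  s1 <- localSeed(config@seedInit + 1L,
                  initAffine(ncol(Xw), sum(spec@reductionDims)))
  flat[["s1.W"]] <- s1$W
  flat[["s1.b"]] <- s1$b
  list(Xw = Xw, flat = flat, spec = spec)
}

withWeights <- function(model, flat) {
  initialize(model, weights = unflattenWeights(flat, length(model@spec@inputDims)))
}

#' Stage 1: pretrain the reduction layer as a shallow autoencoder
#'
#' Trains input -> reduction -> output (the bottleneck is bypassed) with the
#' reconstruction loss only, producing priors for the reduction-layer
#' weights.
#'
#' @param model an untrained [DiffNet-class]
#' @param dataset the aligned training [EnsembleDataset-class]
#' @param config a [TrainingConfig-class]
#' @return list with `model` (reduction weights updated), `log`
#' @export
trainStage1 <- function(model, dataset, config = trainingConfig()) {
  sc <- stageScaffold(model, dataset, config)
  lbl <- labelState(dataset)
  res <- runStage(1L, sc$flat, sc$Xw, sc$Xw[0, , drop = FALSE], lbl,
                  integer(0), sc$spec, config, collectCheckpoints = FALSE)
  list(model = withWeights(model, res$flat), log = res$log)
}

#' Stage 2: train the bottleneck with frozen reduction priors
#'
#' Adds the bottleneck (latent) layer, decoder and classification head to
#' the pretrained reduction layer and trains them while the reduction-layer
#' weights stay exactly frozen. With EM enabled the expectation step runs
#' after every epoch. This is a building block; [trainDiffNet()] orchestrates
#' the full procedure with a validation split.
#'
#' @param model a [DiffNet-class] with stage-1 reduction priors
#' @param dataset the aligned training [EnsembleDataset-class]
#' @param config a [TrainingConfig-class]
#' @param labels optional [LabelState-class] (default: initialized from the
#'   variant classes)
#' @return list with `model`, `log`, `labels`, `labelHistory`, `checkpoints`
#' @export
trainStage2 <- function(model, dataset, config = trainingConfig(),
                        labels = labelState(dataset)) {
  runStageOnDataset(2L, model, dataset, config, labels)
}

#' Stage 3: fine-tune all non-whitening weights
#'
#' Unfreezes the reduction priors and polishes every trainable weight; the
#' whitening layers remain frozen, and a checkpoint is kept after every
#' epoch.
#'
#' @inheritParams trainStage2
#' @return list with `model`, `log`, `labels`, `labelHistory`, `checkpoints`
#' @export
trainStage3 <- function(model, dataset, config = trainingConfig(),
                        labels = labelState(dataset)) {
  runStageOnDataset(3L, model, dataset, config, labels)
}

runStageOnDataset <- function(stage, model, dataset, config, labels) {
  X <- flattenCoords(coords(dataset))
  Xw <- whitenInput(model, X)
  flat <- flattenWeights(model@weights)
  frameClass <- as.integer(
    classLabels(dataset)[as.character(variantOf(dataset))])
  res <- runStage(stage, flat, Xw, Xw, labels, frameClass, model@spec, config)
  list(model = withWeights(model, res$flat), log = res$log,
       labels = res$labels, labelHistory = res$labelHistory,
       checkpoints = res$checkpoints)
}

validationSplit <- function(dataset, fraction, seed) {
  v <- variantOf(dataset)
  valIdx <- localSeed(seed, {
    unlist(lapply(levels(v), function(lev) {
      idx <- which(v == lev)
      sample(idx, max(1L, round(fraction * length(idx))))
    }))
  })
  sort(valIdx)
}

#' Train a DiffNet with the three-stage progressive procedure
#'
#' Aligns the dataset, fits the pooled whitening transform, builds the model
#' (split per `targetResidue`/`cutoff`, or single-encoder when
#' `targetResidue` is NULL), and runs the three stages: (1) shallow
#' autoencoder pretraining of the reduction layer, (2) training of the full
#' network with the reduction priors frozen, (3) fine-tuning of all
#' non-whitening weights. A model snapshot is kept after every epoch of
#' stages 2 and 3 and the returned model is the snapshot with the lowest
#' validation reconstruction loss (earliest epoch on ties). With
#' `config@emEnabled` the expectation step refines the per-frame labels after
#' every epoch that has a classifier (stages 2 and 3); labels are only
#' refined on training frames, never on validation frames. Setting the
#' classification loss weight to 0 with EM off trains the matched
#' unsupervised-autoencoder baseline.
#'
#' @param dataset an [EnsembleDataset-class] (will be aligned internally).
#' @param config a [TrainingConfig-class].
#' @param totalLatent total latent dimension (default 30).
#' @param targetResidue residue id for the split region, or NULL for the
#'   single-encoder architecture.
#' @param cutoff split radius in nm (default 1.0).
#' @param eigenvalueFloor whitening eigenvalue floor (nm^2).
#' @return a list of class `diffnetFit`: `model` (selected [DiffNet-class]),
#'   `log` (per-epoch loss table), `labelHistory` (per-epoch label snapshots
#'   when EM is enabled, else empty), `finalLabels`, `trainFrames`,
#'   `valFrames`, `split`, `transform`, `selected` (stage/epoch of the chosen
#'   checkpoint), `trainRange` (per-feature whitened min/max, used for
#'   extrapolation flags at prediction time).
#' @export
trainDiffNet <- function(dataset, config = trainingConfig(), totalLatent = 30L,
                         targetResidue = NULL, cutoff = 1.0,
                         eigenvalueFloor = 1e-8) {
  validObject(config)
  dataset <- alignToReference(dataset)
  transform <- fitWhitening(dataset, eigenvalueFloor)
  split <- if (!is.null(targetResidue)) splitRegion(dataset, targetResidue, cutoff)
           else NULL
  spec <- if (!is.null(split)) {
    architectureFromSplit(split, totalLatent, seed = config@seedInit)
  } else {
    architectureSpec(3L * nAtoms(dataset), totalLatent, seed = config@seedInit)
  }
  model <- buildModel(spec, transform, split)

  X <- flattenCoords(coords(dataset))
  Xw <- whitenInput(model, X)
  valIdx <- validationSplit(dataset, config@validationFraction,
                            config@seedShuffle)
  trainIdx <- setdiff(seq_len(nFrames(dataset)), valIdx)
  XwTrain <- Xw[trainIdx, , drop = FALSE]
  XwVal <- Xw[valIdx, , drop = FALSE]
  labels <- labelState(dataset, trainIdx)
  frameClassTrain <- as.integer(
    classLabels(dataset)[as.character(variantOf(dataset)[trainIdx])])

  flat <- flattenWeights(model@weights)
  s1 <- localSeed(config@seedInit + 1L,
                  initAffine(ncol(Xw), sum(spec@reductionDims)))
  flat[["s1.W"]] <- s1$W
  flat[["s1.b"]] <- s1$b

  logs <- list(); checkpoints <- list(); labelHistory <- list()
  for (stage in 1:3) {
    res <- runStage(stage, flat, XwTrain, XwVal, labels, frameClassTrain,
                    spec, config)
    flat <- res$flat
    labels <- res$labels
    logs[[stage]] <- res$log
    checkpoints <- c(checkpoints, res$checkpoints)
    labelHistory <- c(labelHistory, res$labelHistory)
  }
  log <- do.call(rbind, logs)
  if (config@lossWeights[2] == 0) {
    log$class <- NULL  # baseline autoencoder mode: no classification term
  }

  if (length(checkpoints) > 0) {
    valLosses <- vapply(checkpoints, function(cp) cp$valRecon, numeric(1))
    best <- which.min(valLosses)  # which.min returns the earliest minimum
    bestFlat <- checkpoints[[best]]$flat
    selected <- list(stage = checkpoints[[best]]$stage,
                     epoch = checkpoints[[best]]$epoch,
                     valRecon = valLosses[best])
  } else {
    bestFlat <- flat
    selected <- list(stage = NA_integer_, epoch = NA_integer_,
                     valRecon = NA_real_)
  }
  finalModel <- withWeights(model, bestFlat)
  structure(list(
    model = finalModel,
    lastModel = withWeights(model, flat),
    log = log,
    labelHistory = labelHistory,
    finalLabels = labels,
    trainFrames = trainIdx,
    valFrames = valIdx,
    split = split,
    transform = transform,
    dataset = dataset,
    selected = selected,
    trainRange = rbind(min = apply(XwTrain, 2, min),
                       max = apply(XwTrain, 2, max))
  ), class = "diffnetFit")
}

#' @export
print.diffnetFit <- function(x, ...) {
  cat("diffnetFit:\n  ")
  show(x$model)
  cat(sprintf("  selected checkpoint: stage %s epoch %s (validation recon %.5f)\n",
              x$selected$stage, x$selected$epoch, x$selected$valRecon))
  cat(sprintf("  %d training / %d validation frames\n",
              length(x$trainFrames), length(x$valFrames)))
  invisible(x)
}

#' Write the per-epoch training log as delimited text
#' @param fit a `diffnetFit`
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeTrainingLog <- function(fit, path) {
  write.table(fit$log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
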