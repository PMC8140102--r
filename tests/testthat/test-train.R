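smallFit <- function(epochs = 3L, emEnabled = FALSE, lossWeights = c(1, 1, 1),
                     frames = 150L, seedInit = 31L, learningRate = 1e-4) {
  ens <- smallDataset(nFramesPerVariant = frames)
  cfg <- trainingConfig(learningRate = learningRate,
                        epochsPerStage = epochs, emEnabled = emEnabled,
                        lossWeights = lossWeights, seedInit = seedInit,
                        seedShuffle = 32L, seedEm = 33L)
  trainDiffNet(ens$dataset, cfg, totalLatent = 10L, targetResidue = 3L,
               cutoff = 0.8)
}

test_that("stage 1 reduces the shallow reconstruction loss and respects epoch counts", {
  ens <- smallDataset(nFramesPerVariant = 150L)
  ds <- alignToReference(ens$dataset)
  tf <- fitWhitening(ds)
  sp <- splitRegion(ds, 3L, 0.8)
  model <- buildModel(architectureFromSplit(sp, 10L, seed = 31L), tf, sp)
  cfg <- trainingConfig(epochsPerStage = 6L, seedInit = 31L)
  res <- trainStage1(model, ds, cfg)
  expect_identical(nrow(res$log), 6L)
  expect_lt(res$log$recon[6], res$log$recon[1])
  # zero epochs: parameters untouched
  cfg0 <- trainingConfig(epochsPerStage = 0L, seedInit = 31L)
  res0 <- trainStage1(model, ds, cfg0)
  expect_identical(res0$model@weights, model@weights)
  expect_identical(nrow(res0$log), 0L)
})

test_that("stage 2 keeps the reduction priors exactly frozen", {
  ens <- smallDataset(nFramesPerVariant = 120L)
  ds <- alignToReference(ens$dataset)
  tf <- fitWhitening(ds)
  sp <- splitRegion(ds, 3L, 0.8)
  model <- buildModel(architectureFromSplit(sp, 10L, seed = 31L), tf, sp)
  cfg <- trainingConfig(epochsPerStage = 2L, seedInit = 31L)
  s1 <- trainStage1(model, ds, cfg)
  s2 <- trainStage2(s1$model, ds, cfg)
  for (e in 1:2) {
    expect_identical(s2$model@weights$enc[[e]]$W1, s1$model@weights$enc[[e]]$W1)
    expect_identical(s2$model@weights$enc[[e]]$b1, s1$model@weights$enc[[e]]$b1)
  }
  expect_false(identical(s2$model@weights$dec, s1$model@weights$dec))
  expect_true(all(is.finite(vapply(s2$checkpoints,
                                   function(cp) cp$valRecon, numeric(1)))))
})

test_that("EM changes the labels between epochs unless the bounds are vacuous", {
  ens <- smallDataset(nFramesPerVariant = 120L)
  ds <- alignToReference(ens$dataset)
  tf <- fitWhitening(ds)
  sp <- splitRegion(ds, 3L, 0.8)
  model <- buildModel(architectureFromSplit(sp, 10L, seed = 31L), tf, sp)
  init <- labelState(ds)
  cfg <- trainingConfig(epochsPerStage = 2L, emEnabled = TRUE, seedInit = 31L)
  s2 <- trainStage2(model, ds, cfg, labels = init)
  expect_length(s2$labelHistory, 2L)
  expect_false(identical(s2$labels@labels, init@labels))
  expect_true(all(s2$labels@labels >= 0 & s2$labels@labels <= 1))
})

test_that("stage 3 checkpoints every epoch and never touches the whitening", {
  fit <- smallFit(epochs = 3L)
  stage3 <- fit$log[fit$log$stage == 3, ]
  expect_identical(nrow(stage3), 3L)
  # frozen whitening: bit-identical to a fresh fit of the aligned data
  tf <- fitWhitening(fit$dataset)
  idxA <- DiffNetR:::coordIdx(fit$split@encoderA)
  expect_identical(fit$model@whitening[[1]]@whitening,
                   subsetWhitening(tf, idxA)@whitening)
})

test_that("training is deterministic and selects the best validation checkpoint", {
  f1 <- smallFit(epochs = 2L)
  f2 <- smallFit(epochs = 2L)
  expect_identical(f1$model@weights, f2$model@weights)
  expect_identical(f1$selected, f2$selected)
  f3 <- smallFit(epochs = 2L, seedInit = 99L)
  expect_false(identical(f1$model@weights, f3$model@weights))
  # the selected checkpoint has the minimal recorded validation loss
  expect_equal(f1$selected$valRecon, min(f1$log$valRecon, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("baseline autoencoder mode has no labels and no classification column", {
  fit <- smallFit(epochs = 2L, emEnabled = FALSE, lossWeights = c(1, 0, 1))
  expect_length(fit$labelHistory, 0L)
  expect_false("class" %in% names(fit$log))
})

test_that("EM training keeps labels on training frames only, within [0,1]", {
  fit <- smallFit(epochs = 2L, emEnabled = TRUE)
  expect_length(fit$finalLabels@labels, length(fit$trainFrames))
  expect_true(all(fit$finalLabels@labels >= 0 & fit$finalLabels@labels <= 1))
  for (snap in fit$labelHistory) {
    expect_true(all(snap >= 0 & snap <= 1))
  }
  expect_length(intersect(fit$trainFrames, fit$valFrames), 0L)
})

test_that("a trained model reconstructs better than the mean structure", {
  # short schedule with a larger step size so the toy run actually converges
  fit <- smallFit(epochs = 10L, frames = 250L, learningRate = 3e-3)
  ds <- fit$dataset
  X <- DiffNetR:::flattenCoords(coords(ds))
  meanRmsd <- mean(sqrt(rowSums(sweep(X, 2, colMeans(X))^2) / nAtoms(ds)))
  expect_lt(reconstructionRmsd(fit$model, ds), meanRmsd)
})

test_that("the training log can be written and re-read", {
  fit <- smallFit(epochs = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingLog(fit, path)
  log <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(log), nrow(fit$log))
  expect_true(all(c("stage", "epoch", "recon", "valRecon") %in% names(log)))
})
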