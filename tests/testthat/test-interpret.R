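test_that("compact-state labeling applies the strict all-below-threshold rule", {
  expect_identical(labelCompactState(c(4.0, 4.1, 4.19)), "compact")
  expect_identical(labelCompactState(c(4.0, 4.3, 4.0)), "extended")
  expect_identical(labelCompactState(c(4.2, 4.2, 4.2)), "extended")  # strict <
  m <- rbind(c(4.0, 4.0, 4.0), c(4.0, 4.5, 4.0))
  expect_identical(labelCompactState(m), c("compact", "extended"))
  expect_error(labelCompactState(c(-1, 4, 4)), "nonnegative")
})

test_that("frozen-latent ROC separates separable latents and nulls out permuted ones", {
  set.seed(41)
  y <- rep(c(0, 1), each = 100)
  sep <- matrix(y * 10 + rnorm(200, sd = 0.1), ncol = 1)
  roc <- frozenLatentRoc(sep, y, seed = 1L)
  expect_equal(roc$auc, rep(1, 5))
  # permutation null at n = 2000
  lat <- matrix(rnorm(2000 * 3), ncol = 3)
  yp <- sample(rep(c(0, 1), each = 1000))
  rocNull <- frozenLatentRoc(lat, yp, seed = 2L)
  expect_gt(rocNull$meanAuc, 0.4)
  expect_lt(rocNull$meanAuc, 0.6)
  expect_error(frozenLatentRoc(sep, rep(1, 200)), "each state")
})

test_that("AUCs of a score and its negation sum to one", {
  set.seed(43)
  y <- rep(c(0, 1), each = 60)
  score <- y + rnorm(120, sd = 0.8)
  a1 <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                       levels = c(0, 1), direction = "<")))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, -score, quiet = TRUE,
                                       levels = c(0, 1), direction = "<")))
  expect_equal(a1 + a2, 1, tolerance = 1e-9)
})

test_that("hybrid clustering saturates, is deterministic, and assigns to nearest center", {
  set.seed(47)
  X <- matrix(rnorm(60 * 4), 60, 4)
  # saturation: every frame its own center
  sat <- clusterConformations(X, 60L, seed = 1L)
  expect_setequal(sat$centers, 1:60)
  expect_error(clusterConformations(X, 61L, seed = 1L), "exceed")
  # k = 1: medoid equals the brute-force medoid over all frames
  one <- clusterConformations(X, 1L, seed = 1L)
  D <- as.matrix(dist(X))
  expect_identical(one$centers, unname(which.min(colSums(D))))
  # determinism
  a <- clusterConformations(X, 5L, seed = 3L)
  b <- clusterConformations(X, 5L, seed = 3L)
  expect_identical(a, b)
  # nearest-center assignment invariant
  d2 <- vapply(seq_len(nrow(X)), function(i) {
    min(rowSums(sweep(X[a$centers, , drop = FALSE], 2, X[i, ])^2))
  }, numeric(1))
  own <- rowSums((X - X[a$centers[a$assignments], , drop = FALSE])^2)
  expect_equal(own, d2, tolerance = 1e-9)
})

test_that("cluster radius is non-increasing in k", {
  set.seed(53)
  X <- matrix(rnorm(200 * 3), 200, 3)
  radius <- vapply(c(2L, 5L, 10L, 25L, 50L), function(k) {
    cl <- clusterConformations(X, k, seed = 1L)
    max(sqrt(rowSums((X - X[cl$centers[cl$assignments], , drop = FALSE])^2)))
  }, numeric(1))
  expect_true(all(diff(radius) <= 1e-9))
})

test_that("distance-correlation scan finds self-correlated pairs and skips rigid ones", {
  ens <- smallDataset(nFramesPerVariant = 50L)
  spec <- smallToySpec()
  ds <- ens$dataset
  frames <- seq_len(nFrames(ds))
  atoms <- sort(unique(c(spec@featureAtomPair, residueAtomIndices(c(2L, 6L)))))
  d <- pairDistances(ds, spec@featureAtomPair)
  rep1 <- distanceCorrelationScan(ds, frames, atoms, labels = d,
                                  selection = "top_n", value = 1)
  expect_identical(c(rep1@pairs$atomI[1], rep1@pairs$atomJ[1]),
                   sort(spec@featureAtomPair))
  expect_equal(rep1@pairs$r[1], 1, tolerance = 1e-9)
  expect_identical(rep1@pairs$direction[1], "expanding")
  # negated label: same rank, contracting sign
  rep2 <- distanceCorrelationScan(ds, frames, atoms, labels = max(d) - d,
                                  selection = "top_n", value = 1)
  expect_identical(rep2@pairs$direction[1], "contracting")
  # intra-residue pairs are excluded up front
  expect_true(all(rep1@pairs$residI != rep1@pairs$residJ))
  # two-frame sanity: any pair across two distinct frames has |r| = 1
  rep3 <- distanceCorrelationScan(ds, 1:3, atoms, labels = c(0, 0.5, 1),
                                  selection = "top_n", value = 3)
  expect_true(all(abs(rep3@pairs$r) <= 1 + 1e-12))
})

test_that("zero-variance pairs are skipped and counted in the metadata", {
  arr <- array(0, dim = c(6, 4, 3))
  arr[, 1, 1] <- seq(0.1, 0.6, by = 0.1)  # only atom 1 moves
  arr[, 2, ] <- rep(c(1, 0, 0), each = 6)
  arr[, 3, ] <- rep(c(0, 1, 0), each = 6)
  arr[, 4, ] <- rep(c(0, 0, 1), each = 6)
  rep <- distanceCorrelationScan(arr, 1:6, 1:4, labels = seq(0, 1, length.out = 6),
                                 selection = "top_n", value = 10)
  expect_identical(rep@nEnumerated, 6L)
  expect_identical(rep@nSkipped, 3L)  # the three pairs not involving atom 1
  expect_identical(rep@selection$denominator, 3L)
})

test_that("the occupancy PDB flags exactly the atoms of selected pairs", {
  ens <- smallDataset(nFramesPerVariant = 30L)
  spec <- smallToySpec()
  d <- pairDistances(ens$dataset, spec@featureAtomPair)
  rep <- distanceCorrelationScan(ens$dataset, seq_len(nFrames(ens$dataset)),
                                 sort(unique(c(spec@featureAtomPair,
                                               residueAtomIndices(2L)))),
                                 labels = d, selection = "top_n", value = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeTopPairPdb(ens$dataset, rep, path)
  pdb <- bio3d::read.pdb(path)
  flagged <- which(pdb$atom$o == 1)
  expect_setequal(flagged, sort(spec@featureAtomPair))
})

test_that("label-binned profiles bin correctly and report empty bins as missing", {
  p1 <- labelBinnedProfile(rep(0.05, 10), rnorm(10, 5))
  expect_identical(p1$n[1], 10L)
  expect_true(all(p1$n[-1] == 0L))
  expect_true(all(is.na(p1$mean[-1])))
  # monotone construction: labels proportional to distances
  d <- seq(1, 2, length.out = 200)
  lab <- (d - 1) / 1
  p2 <- labelBinnedProfile(lab, d)
  expect_true(all(diff(p2$mean) > 0))
  expect_error(labelBinnedProfile(c(-0.1, 0.5), c(1, 2)), "\\[0, 1\\]")
})

test_that("prediction on a training variant reproduces the stored outputs", {
  ens <- smallDataset(nFramesPerVariant = 80L)
  cfg <- trainingConfig(epochsPerStage = 2L, seedInit = 61L)
  fit <- trainDiffNet(ens$dataset, cfg, totalLatent = 10L, targetResidue = 3L,
                      cutoff = 0.8)
  pred <- predictNewVariant(fit, datasetForVariant(fit$dataset, "pos1"))
  stored <- forwardPass(fit$model, fit$dataset)$yhat[variantOf(fit$dataset) == "pos1"]
  expect_equal(pred$labels, stored, tolerance = 1e-9)
  expect_lte(pred$summary$fractionExtrapolating, 1)
  # checkpoint round trip gives the same prediction
  path <- withr::local_tempfile(fileext = ".rds")
  saveFitCheckpoint(fit, path)
  pred2 <- predictNewVariant(path, datasetForVariant(fit$dataset, "pos1"))
  expect_equal(pred2$labels, pred$labels, tolerance = 1e-12)
  # atom mismatch is rejected
  bigger <- generateToyEnsembles(toyEnsembleSpec(nAtoms = 120L,
                                                 nVariantsPerClass = 1L,
                                                 nFramesPerVariant = 3L))
  expect_error(predictNewVariant(fit, bigger$dataset), "atom mismatch")
})

test_that("frames far outside the training range carry a dominant extrapolation warning", {
  ens <- smallDataset(nFramesPerVariant = 60L)
  cfg <- trainingConfig(epochsPerStage = 1L, seedInit = 67L)
  fit <- trainDiffNet(ens$dataset, cfg, totalLatent = 10L, targetResidue = 3L,
                      cutoff = 0.8)
  far <- datasetForVariant(fit$dataset, "neg1")
  arr <- coords(far) * 3  # grossly rescaled structures
  farDs <- methods::initialize(far, coords = arr)
  pred <- predictNewVariant(fit, farDs)
  expect_true(all(pred$extrapolating))
  expect_match(pred$summary$warning, "extrapolation")
})
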