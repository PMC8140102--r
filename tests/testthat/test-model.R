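test_that("latent allocation is proportional with largest-remainder rounding", {
  expect_identical(allocateLatent(30L, c(2L, 13L)), c(4L, 26L))
  expect_identical(allocateLatent(25L, c(25L, 95L)), c(5L, 20L))
  expect_identical(sum(allocateLatent(7L, c(3L, 5L, 11L))), 7L)
  # minimum of one latent per encoder
  expect_identical(allocateLatent(2L, c(1L, 1000L)), c(1L, 1L))
})

test_that("architecture spec enforces the four-fold reduction and split rules", {
  a <- architectureSpec(c(75L, 285L), 30L)
  expect_true(a@split)
  expect_identical(a@reductionDims, c(19L, 72L))
  expect_identical(a@classificationSource, "A")
  u <- architectureSpec(360L, 30L)
  expect_false(u@split)
  expect_identical(u@classificationSource, "full")
})

makeSmallModel <- function(seed = 9L, nFramesPerVariant = 60L) {
  ens <- smallDataset(nFramesPerVariant = nFramesPerVariant)
  ds <- alignToReference(ens$dataset)
  tf <- fitWhitening(ds)
  sp <- splitRegion(ds, 3L, 0.8)
  arch <- architectureFromSplit(sp, 10L, seed = seed)
  list(model = buildModel(arch, tf, sp), ds = ds, tf = tf, sp = sp, arch = arch)
}

test_that("weight initialization is deterministic given the seed", {
  m1 <- makeSmallModel(seed = 9L)$model
  m2 <- makeSmallModel(seed = 9L)$model
  m3 <- makeSmallModel(seed = 10L)$model
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m1@weights, m3@weights))
})

test_that("encoder output has the configured latent width and composition", {
  ctx <- makeSmallModel()
  z <- encode(ctx$model, ctx$ds)
  expect_identical(ncol(z), sum(ctx$arch@latentDims))
  expect_identical(nrow(z), nFrames(ctx$ds))
  # zero latent-layer weights force latent = sigmoid(offsets)
  m <- ctx$model
  for (e in 1:2) {
    m@weights$enc[[e]]$W2[] <- 0
    m@weights$enc[[e]]$b2[] <- 0.3
  }
  z0 <- encode(m, ctx$ds)
  expect_equal(unname(z0[1, ]), rep(DiffNetR:::sigmoid(0.3), ncol(z0)),
               tolerance = 1e-12)
  expect_error(encode(ctx$model, matrix(NaN, 1, 3L * nAtoms(ctx$ds))),
               "non-finite")
})

test_that("split encoders are structurally independent", {
  ctx <- makeSmallModel()
  x1 <- DiffNetR:::flattenCoords(coords(ctx$ds))[1, , drop = FALSE]
  x2 <- x1
  bIdx <- DiffNetR:::coordIdx(ctx$sp@encoderB)
  x2[, bIdx] <- x2[, bIdx] + 5
  nA <- ctx$arch@latentDims[1]
  z1 <- encode(ctx$model, x1); z2 <- encode(ctx$model, x2)
  expect_identical(z1[, 1:nA], z2[, 1:nA])
  expect_false(identical(z1[, -(1:nA)], z2[, -(1:nA)]))
  expect_identical(classifyLatent(ctx$model, z1),
                   classifyLatent(ctx$model, z2))
})

test_that("classifier output is logistic and bounded in (0,1)", {
  ctx <- makeSmallModel()
  m <- ctx$model
  m@weights$cls$w[] <- 0
  m@weights$cls$b <- 0
  z <- encode(m, ctx$ds)
  expect_equal(unname(classifyLatent(m, z)), rep(0.5, nrow(z)))
  # monotone in the logit: scaling the weights up pushes yhat toward 0/1
  m2 <- ctx$model
  y1 <- classifyLatent(m2, z)
  m2@weights$cls$w <- m2@weights$cls$w * 50
  m2@weights$cls$b <- m2@weights$cls$b * 50
  y2 <- classifyLatent(m2, z)
  expect_true(all((y2 - 0.5) * (y1 - 0.5) >= 0))
  expect_true(all(abs(y2 - 0.5) >= abs(y1 - 0.5) - 1e-12))
  y <- forwardPass(ctx$model, ctx$ds)$yhat
  expect_true(all(y > 0 & y < 1))
})

test_that("decode inverts shapes and matches the forward pass", {
  ctx <- makeSmallModel()
  X <- DiffNetR:::flattenCoords(coords(ctx$ds))
  fw <- forwardPass(ctx$model, X)
  expect_identical(dim(fw$reconstruction), dim(X))
  expect_true(all(is.finite(fw$reconstruction)))
  expect_equal(decode(ctx$model, fw$latent), fw$reconstruction, tolerance = 1e-12)
  expect_error(decode(ctx$model, fw$latent[, 1:3]), "latent length")
})

test_that("checkpoints round-trip and reject incompatible versions", {
  ctx <- makeSmallModel()
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(ctx$model, path, extra = list(note = "x"))
  cp <- loadCheckpoint(path)
  expect_identical(cp$model@weights, ctx$model@weights)
  expect_identical(cp$extra$note, "x")
  obj <- readRDS(path)
  obj$version <- 99L
  saveRDS(obj, path)
  expect_error(loadCheckpoint(path), "incompatible checkpoint version")
  saveRDS(list(a = 1), path)
  expect_error(loadCheckpoint(path), "not a DiffNetR checkpoint")
})
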