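test_that("count distribution matches degenerate and hand-enumerated cases", {
  expect_equal(countDistribution(c(0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(countDistribution(c(0.9, 0.1)), c(0.09, 0.82, 0.09),
               tolerance = 1e-12)
  expect_error(countDistribution(numeric(0)), "empty")
  expect_error(countDistribution(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("count distribution matches 2^n enumeration and sums to one", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    p <- runif(n)
    f <- countDistribution(p)
    expect_lt(max(abs(f - pbOracle(p))), 1e-10)
    expect_lt(abs(sum(f) - 1), 1e-12)
    # the compiled kernel agrees with the R implementation
    expect_equal(DiffNetR:::.pbCountDistribution(p), f, tolerance = 1e-12)
  }
})

test_that("expectation update reproduces closed-form and limiting cases", {
  # vacuous window: labels unchanged
  p <- c(0.2, 0.5, 0.9)
  expect_equal(expectationUpdate(p, 0, 3), p, tolerance = 1e-12)
  # two-frame enumeration: SL = SU = 1
  y <- expectationUpdate(c(0.9, 0.1), 1, 1)
  expect_equal(y, c(0.81 / 0.82, 0.01 / 0.82), tolerance = 1e-12)
  # near-certain frame stays near-certain under feasible bounds
  eps <- 1e-9
  y2 <- expectationUpdate(c(1 - eps, 0.5, 0.5), 1, 3)
  expect_gt(y2[1], 1 - 1e-6)
  expect_error(expectationUpdate(c(0.5, 0.5), 2, 1), "SL <= SU")
  expect_error(expectationUpdate(rep(1e-7, 50), 50, 50), "infeasible")
})

test_that("expectation update matches 2^n enumeration with conserved batch sums", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    p <- runif(n, 0.01, 0.99)
    SU <- sample(0:n, 1)
    SL <- sample(0:SU, 1)
    f <- countDistribution(p)
    if (sum(f[(SL + 1):(SU + 1)]) < 1e-12) next
    y <- expectationUpdate(p, SL, SU)
    expect_lt(max(abs(y - emOracle(p, SL, SU))), 1e-10)
    expect_gte(sum(y), SL - 1e-9)
    expect_lte(sum(y), SU + 1e-9)
    # conservation: sum(y) equals E[X | SL <= X <= SU]
    w <- f[(SL + 1):(SU + 1)]
    expect_equal(sum(y), sum((SL:SU) * w) / sum(w), tolerance = 1e-9)
  }
})

test_that("the E-step is deterministic, bounded, and vacuous under (0,1) bounds", {
  ens <- smallDataset(nFramesPerVariant = 80L)
  ds <- ens$dataset
  ls <- labelState(ds)
  expect_identical(ls@labels,
                   as.numeric(classLabels(ds)[as.character(variantOf(ds))]))
  fc <- as.integer(classLabels(ds)[as.character(variantOf(ds))])
  set.seed(19)
  yhat <- runif(nFrames(ds), 0.05, 0.95)
  # (0,1) bounds on both classes leave the classifier outputs untouched
  vac <- emStep(ls, yhat, fc, emBounds(negative = c(0, 1), positive = c(0, 1)),
                emBatchSize = 32L, seed = 5L)
  expect_equal(vac@labels, yhat, tolerance = 1e-12)
  expect_identical(vac@iteration, 1L)
  # default bounds: deterministic given the seed, labels stay in [0,1]
  a <- emStep(ls, yhat, fc, emBounds(), emBatchSize = 32L, seed = 5L)
  b <- emStep(ls, yhat, fc, emBounds(), emBatchSize = 32L, seed = 5L)
  expect_identical(a@labels, b@labels)
  d <- emStep(ls, yhat, fc, emBounds(), emBatchSize = 32L, seed = 6L)
  expect_false(identical(a@labels, d@labels))
  cur <- a
  for (i in 1:5) {
    cur <- emStep(cur, yhat, fc, emBounds(), emBatchSize = 32L, seed = 5L + i)
    expect_true(all(cur@labels >= 0 & cur@labels <= 1))
  }
})

test_that("per-batch label sums respect the fraction-derived count bounds", {
  # single positive-class batch of 32 with bounds (0.6, 0.9):
  # counts ceil(0.6*32) = 20 and floor(0.9*32) = 28
  set.seed(23)
  yhat <- runif(32, 0.3, 0.8)
  y <- expectationUpdate(yhat, ceiling(0.6 * 32), floor(0.9 * 32))
  expect_gte(sum(y), 20)
  expect_lte(sum(y), 28)
})

test_that("E-step failures name the class and batch", {
  ens <- smallDataset(nFramesPerVariant = 50L)
  ds <- ens$dataset
  ls <- labelState(ds)
  fc <- as.integer(classLabels(ds)[as.character(variantOf(ds))])
  yhat <- rep(1e-7, nFrames(ds))
  expect_error(
    emStep(ls, yhat, fc, emBounds(negative = c(0, 0.3), positive = c(0.999, 1)),
           emBatchSize = 50L, seed = 1L),
    "class 1 batch")
})
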