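test_that("loader keeps backbone C/CA/CB/N and handles glycine's missing CB", {
  dir <- withr::local_tempdir()
  # topology with one ALA (incl. O) and one GLY (no CB): 9 atoms total
  pdb <- file.path(dir, "mixed.pdb")
  xyz <- as.vector(t(matrix(seq_len(27), ncol = 3)))
  bio3d::write.pdb(file = pdb, xyz = xyz,
                   resno = c(1, 1, 1, 1, 1, 2, 2, 2, 2),
                   resid = c(rep("ALA", 5), rep("GLY", 4)),
                   elety = c("N", "CA", "CB", "C", "O", "N", "CA", "C", "O"),
                   chain = rep("A", 9))
  traj <- file.path(dir, "t.dcd")
  writeDcd(array(rnorm(2 * 9 * 3), dim = c(2, 9, 3)), traj)
  ds <- loadEnsemble(pdb, c(v1 = traj), data.frame(variant = "v1", class = 0L))
  expect_equal(nAtoms(ds), 7L)  # 4 (ALA) + 3 (GLY, no CB)
  expect_equal(sum(atomInfo(ds)$resname == "GLY"), 3L)
  expect_false("O" %in% atomInfo(ds)$name)
})

test_that("loader rejects malformed input", {
  dir <- withr::local_tempdir()
  ens <- smallDataset(nFramesPerVariant = 5L)
  paths <- writeEnsembleFiles(ens, dir)
  # atom-count mismatch
  bad <- file.path(dir, "bad.dcd")
  writeDcd(array(rnorm(2 * 10 * 3), dim = c(2, 10, 3)), bad)
  expect_error(loadEnsemble(paths$topology, c(pos1 = bad),
                            data.frame(variant = "pos1", class = 1L)),
               "atom-count mismatch")
  # empty trajectory file is a format error, not an empty dataset
  empty <- file.path(dir, "empty.dcd")
  file.create(empty)
  expect_error(loadEnsemble(paths$topology, c(pos1 = empty),
                            data.frame(variant = "pos1", class = 1L)))
  # unknown variant
  expect_error(loadEnsemble(paths$topology, paths$trajectories,
                            data.frame(variant = "pos1", class = 1L)),
               "unknown variant")
})

test_that("superposition recovers an exact rigid-body transform", {
  ens <- smallDataset(nFramesPerVariant = 3L)
  ds <- ens$dataset
  ref <- referenceCoords(ds)
  refc <- sweep(ref, 2, colMeans(ref))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg about z
  arr <- coords(ds)
  arr[1, , ] <- sweep(refc %*% t(Rz), 2, c(1, 1, 1), FUN = "+")
  moved <- methods::initialize(ds, coords = arr)
  aligned <- alignToReference(moved)
  rmsd <- sqrt(mean(rowSums((coords(aligned)[1, , ] - refc)^2)))
  expect_lt(rmsd, 1e-9)
})

test_that("superposition is idempotent and preserves intra-frame distances", {
  ens <- smallDataset(nFramesPerVariant = 10L)
  once <- alignToReference(ens$dataset)
  twice <- alignToReference(once)
  expect_lt(max(abs(coords(twice) - coords(once))), 1e-9)
  p <- c(caAtomIndex(2L), caAtomIndex(7L))
  expect_lt(max(abs(pairDistances(once, p) - pairDistances(ens$dataset, p))), 1e-9)
})

test_that("superposition is optimal against a brute-force rotation grid", {
  set.seed(11)
  Q <- matrix(rnorm(12), 4, 3)  # 4-atom toy
  P <- Q + matrix(rnorm(12, sd = 0.3), 4, 3)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  R <- DiffNetR:::kabschRotation(Pc, Qc)
  kabschRmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  expect_lte(kabschRmsd, gridBestRmsd(P, Q) + 1e-12)
  # and never worse than no rotation at all
  expect_lte(kabschRmsd, sqrt(mean(rowSums((Pc - Qc)^2))))
})

test_that("whitening of identity-covariance data is the identity", {
  set.seed(4)
  X <- matrix(rnorm(300), 50, 6)
  pre <- fitWhitening(X)
  Xw <- applyWhitening(pre, X)  # exactly unit covariance by construction
  tf <- fitWhitening(Xw)
  expect_lt(max(abs(tf@whitening - diag(6))), 1e-6)
})

test_that("an independent coordinate of variance 4 gets whitening scale 0.5", {
  set.seed(5)
  n <- 40
  M <- matrix(rnorm(n * 3), n, 3)
  M <- sweep(M, 2, colMeans(M))  # mean-zero columns so cov() sees them exactly
  Q <- qr.Q(qr(M))
  X <- Q %*% diag(sqrt((n - 1) * c(4, 1, 1)))  # sample covariance exactly diag(4,1,1)
  tf <- fitWhitening(X)
  expect_equal(tf@whitening[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(tf@whitening[2, 2], 1, tolerance = 1e-9)
  expect_lt(max(abs(tf@whitening[upper.tri(tf@whitening)])), 1e-9)
})

test_that("rank-deficient data keeps rank <= frames - 1 with a consistent round trip", {
  set.seed(6)
  X <- matrix(rnorm(10 * 30), 10, 30)  # fewer frames than dimensions
  tf <- fitWhitening(X)
  expect_lte(tf@rank, 9L)
  Xw <- applyWhitening(tf, X)
  # projection property: whiten(unwhiten(whiten(x))) == whiten(x)
  again <- applyWhitening(tf, unwhiten(tf, Xw))
  expect_lt(max(abs(again - Xw)), 1e-5)
})

test_that("whitened pooled data has zero mean and unit covariance on the retained subspace", {
  ens <- smallDataset(nFramesPerVariant = 250L)
  ds <- alignToReference(ens$dataset)
  tf <- fitWhitening(ds)
  Xw <- applyWhitening(tf, DiffNetR:::flattenCoords(coords(ds)))
  expect_lt(max(abs(colMeans(Xw))), 1e-6)
  e <- eigen(tf@covariance, symmetric = TRUE)
  keep <- e$values > tf@floor
  P <- Xw %*% e$vectors[, keep]
  expect_lt(max(abs(cov(P) - diag(sum(keep)))), 1e-5)
  # mean maps to zero; round trip within 1e-5 nm
  expect_lt(max(abs(applyWhitening(tf, tf@mean))), 1e-9)
  X <- DiffNetR:::flattenCoords(coords(ds))
  expect_lt(max(abs(unwhiten(tf, Xw) - X)), 1e-5)
  expect_error(applyWhitening(tf, X[, 1:10]), "dimension mismatch")
})

test_that("sub-block whitening equals refitting on the sub-coordinates", {
  set.seed(8)
  X <- matrix(rnorm(60 * 12), 60, 12)
  X[, 4] <- X[, 3] + 0.5 * X[, 4]  # induce correlation
  tf <- fitWhitening(X)
  idx <- c(2L, 3L, 4L, 9L)
  sub <- subsetWhitening(tf, idx)
  direct <- fitWhitening(X[, idx])
  expect_equal(sub@whitening, direct@whitening, tolerance = 1e-9)
  expect_equal(sub@mean, direct@mean, tolerance = 1e-12)
})

test_that("region split partitions the atoms around the target residue", {
  ens <- smallDataset(nFramesPerVariant = 5L)
  ds <- ens$dataset
  sp <- splitRegion(ds, 3L, 1.0)
  expect_length(intersect(sp@encoderA, sp@encoderB), 0)
  expect_equal(sort(c(sp@encoderA, sp@encoderB)), seq_len(nAtoms(ds)))
  expect_true(all(smallToySpec()@featureAtomPair %in% sp@encoderA))
  # cutoff 0: only the target residue's own atoms
  sp0 <- splitRegion(ds, 3L, 0)
  expect_setequal(sp0@encoderA, residueAtomIndices(3L))
  # whole-molecule cutoff: error steering to the unsplit architecture
  expect_error(splitRegion(ds, 3L, 100), "unsplit")
  expect_error(splitRegion(ds, 999L, 1.0), "not present")
})
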