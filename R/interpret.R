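# Post-hoc interpretation: compact-state labeling, frozen-latent ROC,
# conformation clustering, distance-correlation attribution, label-binned
# distance profiles and held-out-variant prediction.

#' Label a helix as compact or extended from hydrogen-bond distances
#'
#' A frame is "compact" iff every listed donor-acceptor distance is strictly
#' below the threshold (default 4.2 Angstroms, the helix-compaction rule for
#' the backbone N to carbonyl O distances of residue pairs i/i+4).
#'
#' @param hbondDistances numeric vector of distances in Angstroms for one
#'   frame, or a frames x pairs matrix.
#' @param threshold Angstroms (default 4.2); the comparison is strict (`<`).
#' @return character `"compact"`/`"extended"` per frame
#' @export
labelCompactState <- function(hbondDistances, threshold = 4.2) {
  if (is.null(dim(hbondDistances)))
    hbondDistances <- matrix(hbondDistances, nrow = 1)
  if (any(hbondDistances < 0))
    stop("distances must be nonnegative", call. = FALSE)
  ifelse(apply(hbondDistances < threshold, 1, all), "compact", "extended")
}

#' Frozen-latent classification performance (cross-validated ROC)
#'
#' Holds a latent representation constant and measures how well a logistic
#' regression trained on it separates two states: per stratified fold, the
#' classifier is fit on the training folds' latents and evaluated on the
#' held-out fold. This quantifies class separability of a representation
#' without fine-tuning it.
#'
#' @param latents frames x latent-dim matrix.
#' @param stateLabels binary labels (0/1, logical, or 2-level factor).
#' @param nFolds folds (default 5).
#' @param seed shuffling seed.
#' @return object of class `rocResult`: `auc` (per fold), `meanAuc`,
#'   `nFolds`, `curves` (data.frame fold/fpr/tpr)
#' @export
frozenLatentRoc <- function(latents, stateLabels, nFolds = 5L, seed = 1L) {
  if (is.null(dim(latents))) latents <- matrix(latents, ncol = 1)
  y <- if (is.factor(stateLabels)) as.integer(stateLabels) - 1L
       else as.integer(as.logical(stateLabels))
  stopUnless(length(y) == nrow(latents), "labels must match latent rows")
  if (length(unique(y)) < 2 || min(table(y)) < nFolds)
    stop("need at least nFolds instances of each state", call. = FALSE)
  folds <- integer(length(y))
  localSeed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  df <- as.data.frame(latents)
  names(df) <- paste0("L", seq_len(ncol(latents)))
  aucs <- numeric(nFolds)
  curves <- list()
  for (f in seq_len(nFolds)) {
    test <- folds == f
    fit <- suppressWarnings(stats::glm(y[!test] ~ ., family = stats::binomial(),
                                       data = df[!test, , drop = FALSE]))
    scores <- suppressWarnings(
      stats::predict(fit, newdata = df[test, , drop = FALSE], type = "response"))
    r <- pROC::roc(response = y[test], predictor = scores, quiet = TRUE,
                   levels = c(0, 1), direction = "<")
    aucs[f] <- as.numeric(pROC::auc(r))
    curves[[f]] <- data.frame(fold = f,
                              fpr = rev(1 - r$specificities),
                              tpr = rev(r$sensitivities))
  }
  structure(list(auc = aucs, meanAuc = mean(aucs), nFolds = nFolds,
                 curves = do.call(rbind, curves)),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("rocResult: mean AUC %.3f over %d folds (sd %.3f)\n",
              x$meanAuc, x$nFolds, sd(x$auc)))
  invisible(x)
}

#' Hybrid k-centers / k-medoids clustering of conformations
#'
#' Greedy k-centers (farthest-point, Euclidean metric, seeded first center)
#' followed by a fixed number of k-medoids refinement sweeps in which each
#' cluster's center moves to the member minimizing the summed distance to
#' the other members. Centers are always actual frames.
#'
#' @param x frames x features matrix (e.g. whitened features or flattened
#'   coordinates) or an [EnsembleDataset-class].
#' @param k number of clusters (`k <=` frames).
#' @param seed seed for the initial center.
#' @param medoidSweeps refinement sweeps (default 5).
#' @return list with `centers` (frame indices) and `assignments` (nearest
#'   center index per frame, into `centers`)
#' @export
clusterConformations <- function(x, k, seed = 1L, medoidSweeps = 5L) {
  X <- if (is(x, "EnsembleDataset")) flattenCoords(coords(x)) else x
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of frames", call. = FALSE)
  sq <- rowSums(X^2)
  d2To <- function(i) pmax(sq + sq[i] - 2 * as.vector(X %*% X[i, ]), 0)
  centers <- integer(k)
  centers[1] <- localSeed(seed, sample.int(n, 1))
  minD2 <- d2To(centers[1])
  assign <- rep(1L, n)
  if (k > 1) for (j in 2:k) {
    centers[j] <- which.max(minD2)
    dj <- d2To(centers[j])
    better <- dj < minD2
    minD2[better] <- dj[better]
    assign[better] <- j
  }
  for (sweep in seq_len(medoidSweeps)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) < 3) next
      D <- as.matrix(stats::dist(X[members, , drop = FALSE]))
      med <- members[which.min(colSums(D))]
      if (med != centers[j]) { centers[j] <- med; changed <- TRUE }
    }
    # reassign every frame to its nearest (possibly moved) center
    CD <- outer(sq, numeric(k), "+")
    for (j in seq_len(k)) CD[, j] <- sq + sq[centers[j]] - 2 * as.vector(X %*% X[centers[j], ])
    assign <- max.col(-CD, ties.method = "first")
    if (!changed) break
  }
  list(centers = centers, assignments = assign)
}

#' Distance-correlation attribution scan over an atom subset
#'
#' Enumerates all unordered atom pairs within the subset (pairs within the
#' same residue excluded by default: they are near-rigid and would be
#' skipped as zero-variance anyway), computes each pair's distance at the
#' given frames (typically cluster centers) and the Pearson correlation of
#' that distance with the per-frame label (typically the model output at the
#' centers). Pairs are ranked by `|r|`; a negative slope (atoms approach as
#' the label rises) is reported as "contracting", a positive one as
#' "expanding". Zero-variance pairs are skipped and counted.
#'
#' @param coordArr frames x atoms x 3 array (nm) or an
#'   [EnsembleDataset-class].
#' @param frames integer frame indices to use (e.g. cluster centers).
#' @param atomSubset integer atom indices to enumerate pairs from (e.g.
#'   encoder A's atoms).
#' @param labels numeric per-frame labels, same length as `frames`.
#' @param selection `"top_percent"` or `"top_n"`.
#' @param value percentile (of non-skipped pairs) or count for the selection.
#' @param atoms optional atom metadata data.frame (taken from the dataset if
#'   available) for residue/atom names in the report.
#' @param excludeSameResidue drop intra-residue pairs (default TRUE).
#' @return a [DistanceCorrelationReport-class]
#' @export
distanceCorrelationScan <- function(coordArr, frames, atomSubset, labels,
                                    selection = c("top_percent", "top_n"),
                                    value = 1, atoms = NULL,
                                    excludeSameResidue = TRUE) {
  selection <- match.arg(selection)
  if (is(coordArr, "EnsembleDataset")) {
    atoms <- atoms %||% atomInfo(coordArr)
    coordArr <- coords(coordArr)
  }
  stopUnless(length(frames) >= 3, "need at least 3 frames")
  stopUnless(length(atomSubset) >= 2, "need at least 2 atoms in the subset")
  stopUnless(length(labels) == length(frames), "one label per frame is required")
  pairs <- t(utils::combn(sort(atomSubset), 2))
  if (excludeSameResidue && !is.null(atoms)) {
    keep <- atoms$resid[pairs[, 1]] != atoms$resid[pairs[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  nEnum <- nrow(pairs)
  d <- pairDistanceMatrix(coordArr, frames, pairs)
  sds <- apply(d, 2, sd)
  ok <- sds > 1e-12 & sd(labels) > 1e-12
  r <- rep(NA_real_, nEnum)
  r[ok] <- as.vector(cor(d[, ok, drop = FALSE], labels))
  ranked <- order(abs(r), decreasing = TRUE, na.last = NA)
  nOk <- sum(ok)
  nSel <- if (selection == "top_percent") {
    max(1L, as.integer(ceiling(value / 100 * nOk)))
  } else {
    min(as.integer(value), nOk)
  }
  df <- data.frame(
    atomI = pairs[ranked, 1],
    atomJ = pairs[ranked, 2],
    r = r[ranked],
    direction = ifelse(r[ranked] < 0, "contracting", "expanding"),
    selected = seq_along(ranked) <= nSel
  )
  if (!is.null(atoms)) {
    df$residI <- atoms$resid[df$atomI]; df$nameI <- atoms$name[df$atomI]
    df$residJ <- atoms$resid[df$atomJ]; df$nameJ <- atoms$name[df$atomJ]
  }
  new("DistanceCorrelationReport",
      pairs = df,
      selection = list(type = selection, value = value, nSelected = nSel,
                       denominator = nOk),
      nEnumerated = as.integer(nEnum),
      nSkipped = as.integer(nEnum - nOk))
}

setMethod("show", "DistanceCorrelationReport", function(object) {
  cat(sprintf("DistanceCorrelationReport: %d pairs enumerated, %d skipped, %d selected (%s = %s)\n",
              object@nEnumerated, object@nSkipped, object@selection$nSelected,
              object@selection$type, object@selection$value))
  print(head(object@pairs, 5))
})

#' Selected (top-ranked) pairs of a distance-correlation report
#' @param report a [DistanceCorrelationReport-class]
#' @return data.frame of the selected pairs, ranked by `|r|`
#' @export
topPairs <- function(report) report@pairs[report@pairs$selected, , drop = FALSE]

#' Rank of an atom pair in a distance-correlation report
#' @param report a [DistanceCorrelationReport-class]
#' @param pair integer length 2, atom indices (order-insensitive)
#' @return integer rank by `|r|` (1 = most correlated), or NA if skipped
#' @export
pairRank <- function(report, pair) {
  p <- sort(pair)
  hit <- which(report@pairs$atomI == p[1] & report@pairs$atomJ == p[2])
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Mean distance as a function of the model output label
#'
#' Bins the labels into `nBins` equal-width bins over `[0, 1]` (last bin
#' right-closed) and reports the per-bin mean distance with its standard
#' error. Empty bins are reported as missing, not zero.
#'
#' @param labels numeric per-frame labels in `[0, 1]`.
#' @param distances numeric per-frame distances.
#' @param nBins number of bins (default 10).
#' @return data.frame: bin, lower, upper, n, mean, se
#' @export
labelBinnedProfile <- function(labels, distances, nBins = 10L) {
  stopUnless(all(labels >= 0 & labels <= 1), "labels must lie in [0, 1]")
  stopUnless(length(labels) == length(distances),
             "labels and distances must have equal length")
  breaks <- seq(0, 1, length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(labels, breaks, rightmost.closed = TRUE), 1L), nBins)
  out <- data.frame(bin = seq_len(nBins),
                    lower = breaks[-length(breaks)], upper = breaks[-1],
                    n = 0L, mean = NA_real_, se = NA_real_)
  for (b in seq_len(nBins)) {
    v <- distances[bin == b]
    out$n[b] <- length(v)
    if (length(v) > 0) {
      out$mean[b] <- mean(v)
      out$se[b] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    }
  }
  out
}

# frames x pairs matrix of pairwise distances (nm)
pairDistanceMatrix <- function(coordArr, frames, pairs) {
  sub <- coordArr[frames, , , drop = FALSE]
  d <- sqrt((sub[, pairs[, 1], 1] - sub[, pairs[, 2], 1])^2 +
            (sub[, pairs[, 1], 2] - sub[, pairs[, 2], 2])^2 +
            (sub[, pairs[, 1], 3] - sub[, pairs[, 2], 3])^2)
  if (is.null(dim(d))) d <- matrix(d, nrow = length(frames))
  d
}

#' Per-frame feature-pair distances
#' @param dataset an [EnsembleDataset-class] (or frames x atoms x 3 array)
#' @param pair integer length 2 atom indices
#' @return numeric vector of distances (nm)
#' @export
pairDistances <- function(dataset, pair) {
  arr <- if (is(dataset, "EnsembleDataset")) coords(dataset) else dataset
  sqrt(rowSums((arr[, pair[1], ] - arr[, pair[2], ])^2))
}

#' Predict per-frame labels for a new variant ensemble
#'
#' Applies a trained model (a `diffnetFit` or a checkpoint written with
#' training metadata) to an unseen ensemble: frames are aligned to the
#' stored training reference, whitened with the stored transform and passed
#' through the network. Frames whose whitened features fall outside the
#' training range are flagged as extrapolating (autoencoders are unreliable
#' outside the training distribution); if every frame extrapolates, the
#' summary carries a dominant warning.
#'
#' @param fit a `diffnetFit` from [trainDiffNet()], or a checkpoint path
#'   written by [saveFitCheckpoint()].
#' @param newDataset an [EnsembleDataset-class] sharing the training atom
#'   set.
#' @return list: `labels` (per-frame model output), `extrapolating`
#'   (logical per frame), `summary` (mean, sd, histogram, fraction
#'   extrapolating, warning)
#' @export
predictNewVariant <- function(fit, newDataset) {
  if (is.character(fit)) {
    cp <- loadCheckpoint(fit)
    model <- cp$model
    reference <- cp$extra$reference
    trainRange <- cp$extra$trainRange
  } else {
    model <- fit$model
    reference <- referenceCoords(fit$dataset)
    trainRange <- fit$trainRange
  }
  refAtoms <- length(model@featureOrder) / 3L
  if (nAtoms(newDataset) != refAtoms)
    stop("atom mismatch: model expects ", refAtoms, " atoms, dataset has ",
         nAtoms(newDataset), call. = FALSE)
  aligned <- alignToReference(initialize(newDataset, reference = reference))
  Xw <- whitenInput(model, flattenCoords(coords(aligned)))
  enc <- encodeWhitened(model, Xw)
  labels <- sigmoid(classifierLogit(model, enc$latent))
  extrapolating <- rep(FALSE, nrow(Xw))
  if (!is.null(trainRange)) {
    lo <- sweep(Xw, 2, trainRange["min", ], FUN = "<")
    hi <- sweep(Xw, 2, trainRange["max", ], FUN = ">")
    extrapolating <- rowSums(lo | hi) > 0
  }
  frac <- mean(extrapolating)
  warningMsg <- if (frac == 1) {
    "all frames fall outside the training feature range; predictions are extrapolations"
  } else NA_character_
  list(
    labels = labels,
    extrapolating = extrapolating,
    summary = list(mean = mean(labels), sd = sd(labels),
                   histogram = labelHistogramTable(labels,
                                                   rep(0L, length(labels)))[, c("lower", "upper", "class0")],
                   fractionExtrapolating = frac,
                   warning = warningMsg)
  )
}

#' Save a trained fit as a self-sufficient checkpoint
#'
#' Bundles the selected model with the training reference coordinates,
#' whitened-feature ranges and final labels so [predictNewVariant()] can run
#' from the file alone.
#'
#' @param fit a `diffnetFit`
#' @param path output file
#' @return invisibly, `path`
#' @export
saveFitCheckpoint <- function(fit, path) {
  saveCheckpoint(fit$model, path, extra = list(
    reference = referenceCoords(fit$dataset),
    trainRange = fit$trainRange,
    finalLabels = fit$finalLabels@labels,
    selected = fit$selected
  ))
}

#' Write a distance-correlation report as CSV
#' @param report a [DistanceCorrelationReport-class]
#' @param path output CSV
#' @return invisibly, `path`
#' @export
writeDistanceReport <- function(report, path) {
  utils::write.csv(report@pairs, path, row.names = FALSE)
  invisible(path)
}

#' Write a PDB flagging the atoms of the selected distance pairs
#'
#' Writes the dataset's reference structure with occupancy 1 for atoms that
#' participate in at least one selected pair and 0 elsewhere, for display in
#' a molecular viewer.
#'
#' @param dataset an [EnsembleDataset-class]
#' @param report a [DistanceCorrelationReport-class]
#' @param path output PDB path
#' @return invisibly, `path`
#' @export
writeTopPairPdb <- function(dataset, report, path) {
  at <- atomInfo(dataset)
  top <- topPairs(report)
  flagged <- unique(c(top$atomI, top$atomJ))
  occ <- as.numeric(seq_len(nrow(at)) %in% flagged)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(referenceCoords(dataset) * 10)),
    resno = at$resid, resid = at$resname, elety = at$name,
    chain = rep("A", nrow(at)), o = occ
  )
  invisible(path)
}

#' Write ROC curves and the per-fold AUC table as CSV
#' @param roc a `rocResult`
#' @param curvesPath,aucPath output CSV paths
#' @return invisibly, a list of the two paths
#' @export
writeRocResult <- function(roc, curvesPath, aucPath) {
  utils::write.csv(roc$curves, curvesPath, row.names = FALSE)
  utils::write.csv(data.frame(fold = seq_len(roc$nFolds), auc = roc$auc),
                   aucPath, row.names = FALSE)
  invisible(list(curves = curvesPath, auc = aucPath))
}
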