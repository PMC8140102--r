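# Expectation-maximization label refinement. The M-step is ordinary DiffNet
# training against the current labels; the E-step below replaces each
# frame's label by its conditional expectation given per-class bounds on how
# many frames in its batch are "positive", with the batch count treated as a
# Poisson-binomial variable parameterized by the classifier outputs.

#' Construct per-class EM bounds
#'
#' Defaults mirror the stability setting: 0-30% of negative-class
#' (less stable) frames and 60-90% of positive-class (more stable) frames
#' are allowed to be positive. For the duty-ratio setting use
#' `emBounds(negative = c(0.10, 0.40))`.
#'
#' @param negative numeric (lower, upper) fraction for class-0 frames.
#' @param positive numeric (lower, upper) fraction for class-1 frames.
#' @return an [EMBounds-class]
#' @export
emBounds <- function(negative = c(0, 0.30), positive = c(0.60, 0.90)) {
  new("EMBounds", negative = as.numeric(negative), positive = as.numeric(positive))
}

setMethod("show", "EMBounds", function(object) {
  cat(sprintf("EMBounds: negative class %.0f-%.0f%%, positive class %.0f-%.0f%%\n",
              100 * object@negative[1], 100 * object@negative[2],
              100 * object@positive[1], 100 * object@positive[2]))
})

#' Initial label state for a dataset
#'
#' Labels start as the binary class of each frame's variant (all 1s for
#' positive-class variants, all 0s for negative-class variants).
#'
#' @param dataset an [EnsembleDataset-class]
#' @param frames optional integer subset of frames (default all)
#' @return a [LabelState-class]
#' @export
labelState <- function(dataset, frames = seq_len(nFrames(dataset))) {
  v <- variantOf(dataset)[frames]
  new("LabelState",
    labels = as.numeric(classLabels(dataset)[as.character(v)]),
    variant = v,
    iteration = 0L)
}

setMethod("show", "LabelState", function(object) {
  cat(sprintf("LabelState: %d frames, %d E-steps applied, labels in [%.3f, %.3f]\n",
              length(object@labels), object@iteration,
              min(object@labels), max(object@labels)))
})

#' Poisson-binomial count distribution
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with the given probabilities, computed by sequential convolution.
#'
#' @param probabilities numeric vector in `[0, 1]`
#' @return numeric vector of length `n + 1`: `P(count = 0), ..., P(count = n)`
#' @export
countDistribution <- function(probabilities) {
  n <- length(probabilities)
  if (n == 0) stop("empty probability vector", call. = FALSE)
  stopUnless(all(probabilities >= 0 & probabilities <= 1),
             "probabilities must lie in [0, 1]")
  f <- c(1, rep(0, n))
  for (p in probabilities) {
    f <- f * (1 - p) + c(0, f[-(n + 1)]) * p
  }
  f
}

#' Conditional-expectation label update for one batch
#'
#' Treats the batch's classifier outputs as independent Bernoulli
#' probabilities and returns, for each frame, the conditional expectation of
#' its Bernoulli indicator given that the batch's total count lies in
#' `[SL, SU]`:
#' `y_i = yhat_i * P(SL-1 <= X_{-i} <= SU-1) / P(SL <= X <= SU)`,
#' with the leave-one-out count law computed exactly by recomputation
#' without frame `i`. The updated labels always satisfy
#' `sum(y) = E[X | SL <= X <= SU]`, which lies in `[SL, SU]`.
#'
#' @param yhat classifier outputs in `[0, 1]`
#' @param SL,SU integer lower/upper count bounds, `0 <= SL <= SU <= n`
#' @return updated labels in `[0, 1]`
#' @export
expectationUpdate <- function(yhat, SL, SU) {
  n <- length(yhat)
  stopUnless(n >= 1, "empty batch")
  stopUnless(all(yhat >= 0 & yhat <= 1), "classifier outputs must lie in [0, 1]")
  SL <- as.integer(SL); SU <- as.integer(SU)
  stopUnless(SL >= 0 && SL <= SU && SU <= n,
             "count bounds must satisfy 0 <= SL <= SU <= n")
  .pbExpectationUpdate(as.numeric(yhat), SL, SU)
}

fractionToCounts <- function(bounds, n) {
  SL <- as.integer(ceiling(bounds[1] * n))
  SU <- as.integer(floor(bounds[2] * n))
  SL <- min(SL, SU)
  c(SL, SU)
}

#' One expectation step over all frames
#'
#' Frames are grouped by their variant's class; within each class they are
#' shuffled (seeded) and partitioned into batches of `emBatchSize`
#' (a trailing batch smaller than 2 is merged into the previous one). Per
#' batch the class's fractional bounds are converted to counts
#' (`SL = ceiling(lower * n)`, `SU = floor(upper * n)`) and
#' [expectationUpdate()] is applied; the resulting labels replace the
#' previous ones. Classifier outputs are clamped to `[1e-7, 1 - 1e-7]`
#' before the Poisson-binomial computation.
#'
#' @param labels a [LabelState-class]
#' @param classifierOutputs numeric per-frame model outputs in `(0, 1)`
#' @param frameClass integer 0/1 per frame (the variant's class)
#' @param bounds an [EMBounds-class]
#' @param emBatchSize batch size for the E-step grouping (default 32, the
#'   training batch size)
#' @param seed integer seed for the per-class shuffles
#' @return the updated [LabelState-class]
#' @export
emStep <- function(labels, classifierOutputs, frameClass, bounds,
                   emBatchSize = 32L, seed = 1L) {
  stopUnless(length(classifierOutputs) == length(labels@labels),
             "classifier outputs must cover all frames in the label state")
  stopUnless(length(frameClass) == length(labels@labels),
             "frameClass must cover all frames")
  validObject(bounds)
  yhat <- pmin(pmax(classifierOutputs, 1e-7), 1 - 1e-7)
  newLabels <- labels@labels
  for (cls in c(0L, 1L)) {
    idx <- which(frameClass == cls)
    if (length(idx) == 0) next
    if (length(idx) < 2)
      stop("class ", cls, " has fewer than 2 frames; cannot form an EM batch",
           call. = FALSE)
    fb <- if (cls == 1L) bounds@positive else bounds@negative
    perm <- localSeed(seed + cls, sample(idx))
    starts <- seq(1L, length(perm), by = as.integer(emBatchSize))
    batches <- lapply(seq_along(starts), function(b) {
      perm[starts[b]:min(starts[b] + emBatchSize - 1L, length(perm))]
    })
    if (length(batches) > 1 && length(batches[[length(batches)]]) < 2) {
      nb <- length(batches)
      batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    for (b in seq_along(batches)) {
      members <- batches[[b]]
      counts <- fractionToCounts(fb, length(members))
      y <- tryCatch(
        expectationUpdate(yhat[members], counts[1], counts[2]),
        error = function(e) stop("E-step failed in class ", cls, " batch ", b,
                                 ": ", conditionMessage(e), call. = FALSE)
      )
      newLabels[members] <- y
    }
  }
  initialize(labels, labels = newLabels, iteration = labels@iteration + 1L)
}

#' Histogram summary of labels per class
#'
#' Equal-width bins over `[0, 1]` (last bin right-closed), one count column
#' per class; the delimited-text form of this table is what training writes
#' alongside label snapshots.
#'
#' @param labels numeric labels in `[0, 1]`
#' @param frameClass integer 0/1 per frame
#' @param nBins number of bins (default 20)
#' @return data.frame with bin bounds and per-class counts
#' @export
labelHistogramTable <- function(labels, frameClass, nBins = 20L) {
  breaks <- seq(0, 1, length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(labels, breaks, rightmost.closed = TRUE), 1L), nBins)
  data.frame(
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    class0 = tabulate(bin[frameClass == 0L], nBins),
    class1 = tabulate(bin[frameClass == 1L], nBins)
  )
}
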